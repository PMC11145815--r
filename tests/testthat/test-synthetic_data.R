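test_that("pockets lie on a smooth curve with exact C-alpha spacing", {
  p <- generate_pocket(42, 30)
  expect_equal(nchar(p$sequence), 30L)
  xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(abs(steps - 3.8) < 0.01))
  expect_identical(generate_pocket(42, 30), p)
  expect_error(generate_pocket(1, 1), "length")
})

test_that("ligands respect bond-length and degree constraints", {
  p <- generate_pocket(5, 20)
  l <- generate_ligand(9, 25, p)
  expect_identical(generate_ligand(9, 25, p), l)
  xyz <- as.matrix(l$atoms[, c("x", "y", "z")])
  bl <- sqrt(rowSums((xyz[l$bonds$i, , drop = FALSE] -
                        xyz[l$bonds$j, , drop = FALSE])^2))
  expect_true(all(bl >= 1.2 & bl <= 1.8))
  deg <- tabulate(c(l$bonds$i, l$bonds$j), nbins = 25)
  caps <- c(C = 4, N = 3, O = 2, S = 2)[l$atoms$element]
  expect_true(all(deg <= caps))
  centroid <- colMeans(as.matrix(p$atoms[, c("x", "y", "z")]))
  expect_true(all(sqrt(rowSums(sweep(xyz, 2, centroid)^2)) <= 6 + 1e-9))
})

test_that("planted labels follow the declared affinity function", {
  spec <- tiny_spec(seed = 3)
  p <- generate_pocket(12, 10)
  l <- generate_ligand(13, 6, p)
  # degenerate weights: constant label at the center of the pK range
  spec0 <- synthetic_spec(n_samples = 2, weights = c(0, 0, 0), noise_sd = 0,
                          pocket_length = spec$pocket_length,
                          ligand_size = spec$ligand_size, seed = 1)
  a0 <- planted_affinity(l, p, spec0)
  expect_equal(a0$label, 7)
  # reproducible noise draw
  a1 <- planted_affinity(l, p, spec, noise_seed = 77)
  expect_identical(planted_affinity(l, p, spec, noise_seed = 77), a1)
  expect_true(a1$label >= 2 && a1$label <= 12)
})

test_that("the contact term matches a brute-force pair count", {
  spec <- tiny_spec(seed = 6)
  for (k in 1:5) {
    s <- generate_complex(spec, k)$sample
    # the oracle scans directed pairs over the pooled set; restrict to
    # cross-molecule pairs in one direction
    nl <- nrow(s$ligand$atoms)
    cross <- oracle_noncovalent(s$ligand, s$pocket, spec$contact_threshold)
    cross <- cross[cross[, 1] <= nl & cross[, 2] > nl, , drop = FALSE]
    got <- plafusion:::.contact_count(s$ligand, s$pocket, spec$contact_threshold)
    expect_equal(got, nrow(cross))
  }
})

test_that("labels depend on the ligand-pocket geometry when w_int > 0", {
  spec <- synthetic_spec(n_samples = 1, noise_sd = 0, seed = 21,
                         pocket_length = c(10L, 14L), ligand_size = c(6L, 9L))
  s <- generate_complex(spec, 1)$sample
  moved <- s$ligand
  moved$atoms$x <- moved$atoms$x + 50  # push the ligand out of contact
  a_near <- planted_affinity(s$ligand, s$pocket, spec)
  a_far <- planted_affinity(moved, s$pocket, spec)
  expect_false(isTRUE(all.equal(a_near$noiseless, a_far$noiseless)))
})

test_that("datasets are written deterministically with parseable files", {
  spec <- tiny_spec(n = 4, seed = 19)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(spec, dir = d1)
  generate_dataset(spec, dir = d2)
  expect_identical(readLines(file.path(d1, "index.txt")),
                   readLines(file.path(d2, "index.txt")))
  idx <- read_affinity_index(file.path(d1, "index.txt"))
  expect_equal(nrow(idx), 4L)
  for (id in idx$id) {
    expect_silent(lig <- read_ligand_sdf(file.path(d1, paste0(id, "_ligand.sdf"))))
    poc <- read_pocket_pdb(file.path(d1, paste0(id, "_pocket.pdb")))
    expect_gt(nchar(poc$sequence), 0L)
  }
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(length(manifest$noiseless_labels), 4L)
})

test_that("default-condition datasets have contacts and labeled spread", {
  dd <- default_dataset_features()
  labels <- dd$features$labels
  expect_true(all(labels >= 2 & labels <= 12))
  # nearly every complex is in atomic contact with its pocket
  spec <- synthetic_spec(seed = 1L)
  contacts <- vapply(dd$ds$samples, function(s)
    plafusion:::.contact_count(s$ligand, s$pocket, spec$contact_threshold), 0)
  expect_gte(mean(contacts > 0), 0.95)
  # label spread matches the construction scale (3 sd spanning +/- 5 pK)
  expect_gt(sd(labels), 0.8 * 5 / 3)
  expect_lt(sd(labels), 1.2 * 5 / 3 * 1.25)
})
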