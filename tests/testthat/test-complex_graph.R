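test_that("atom features follow the 19-dimensional recipe", {
  f <- atom_features("C", 0, 4, TRUE)
  expect_length(f, 19L)
  expect_equal(f[1], 1)            # element C slot
  expect_equal(f[12 + 4], 1)       # degree-4 slot (offset 11 one-hots + deg0)
  expect_equal(f[19], 1)           # ligand flag
  g <- atom_features("Se", 0, 2, FALSE)
  expect_equal(g[11], 1)           # unknown element maps to "other"
  expect_equal(g[19], 0)
  expect_true(all(vapply(c("C", "N", "O", "H", "Zz"), function(e)
    length(atom_features(e, 1, 7, TRUE)), 0L) == 19L))
})

test_that("non-covalent edges obey the distance threshold", {
  lig <- new_ligand(data.frame(element = "C", x = 0, y = 0, z = 0, charge = 0),
                    data.frame(i = integer(), j = integer(), order = integer()))
  mk_pocket <- function(d)
    new_pocket(data.frame(resid = "ALA", chain = "A", resno = 1),
               data.frame(element = "C", x = d, y = 0, z = 0, res_index = 1))
  close_e <- noncovalent_edges(lig, mk_pocket(3.0), 4.5)
  expect_equal(nrow(close_e), 2L)  # one undirected edge, both directions
  expect_equal(sort(close_e$i), c(1L, 2L))
  expect_close(close_e$distance, c(3, 3))
  expect_equal(nrow(noncovalent_edges(lig, mk_pocket(5.0), 4.5)), 0L)
})

test_that("non-covalent edge sets equal the all-pairs brute-force scan", {
  set.seed(202)
  for (k in 1:10) {
    s <- tiny_dataset(1, seed = 400 + k)$samples[[1]]
    got <- noncovalent_edges(s$ligand, s$pocket, 4.5)
    want <- oracle_noncovalent(s$ligand, s$pocket, 4.5)
    key <- function(i, j, d) paste(i, j, round(d, 9))
    expect_setequal(key(got$i, got$j, got$distance),
                    key(want[, 1], want[, 2], want[, 3]))
  }
})

test_that("edge counts are nondecreasing in the threshold", {
  s <- tiny_dataset(1, seed = 61)$samples[[1]]
  counts <- vapply(c(2, 3, 4.5, 6, 8), function(t)
    nrow(noncovalent_edges(s$ligand, s$pocket, t)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("complex graphs carry typed symmetric edges and the ligand mask", {
  lig <- new_ligand(data.frame(element = c("C", "O"), x = c(0, 1.25), y = 0,
                               z = 0, charge = 0),
                    data.frame(i = 1L, j = 2L, order = 2L))
  poc <- new_pocket(data.frame(resid = "GLY", chain = "A", resno = 1),
                    data.frame(element = "C", x = 3, y = 0, z = 0, res_index = 1))
  g <- build_complex_graph(new_complex_sample(lig, poc, id = "t"))
  expect_equal(nrow(g$node_features), 3L)
  expect_equal(g$ligand_mask, c(TRUE, TRUE, FALSE))
  dbl <- g$edges[g$edges$type == "covalent:double", ]
  expect_equal(nrow(dbl), 2L)  # both directions
  expect_setequal(paste(dbl$i, dbl$j), c("1 2", "2 1"))
  # symmetry of the whole edge list
  e <- g$edges
  expect_setequal(paste(e$i, e$j, e$type, round(e$distance, 9)),
                  paste(e$j, e$i, e$type, round(e$distance, 9)))
  expect_false(any(e$i == e$j))
  expect_true(all(e$distance[e$type == "noncovalent"] <= 4.5))
})

test_that("minimal two-atom complexes yield a single non-covalent contact", {
  lig <- new_ligand(data.frame(element = "C", x = 0, y = 0, z = 0, charge = 0),
                    data.frame(i = integer(), j = integer(), order = integer()))
  poc <- new_pocket(data.frame(resid = "ALA", chain = "A", resno = 1),
                    data.frame(element = "C", x = 3, y = 0, z = 0, res_index = 1))
  g <- build_complex_graph(new_complex_sample(lig, poc, id = "m"))
  expect_equal(nrow(g$edges), 2L)
  expect_true(all(g$edges$type == "noncovalent"))
})

test_that("node counts and edge sets match the oracle on synthetic complexes", {
  set.seed(99)
  for (k in 1:8) {
    s <- tiny_dataset(1, seed = 500 + k)$samples[[1]]
    g <- build_complex_graph(s)
    expect_equal(nrow(g$node_features),
                 nrow(s$ligand$atoms) + nrow(s$pocket$atoms))
    nc <- g$edges[g$edges$type == "noncovalent", ]
    want <- oracle_noncovalent(s$ligand, s$pocket, 4.5)
    # remove pairs claimed by inferred pocket covalent edges
    cov <- g$edges[g$edges$type != "noncovalent", ]
    covkey <- paste(cov$i, cov$j)
    keep <- !(paste(want[, 1], want[, 2]) %in% covkey)
    expect_setequal(paste(nc$i, nc$j), paste(want[keep, 1], want[keep, 2]))
  }
})

test_that("graph dumps are written as node and edge tables", {
  s <- tiny_dataset(1, seed = 8)$samples[[1]]
  g <- build_complex_graph(s)
  path <- withr::local_tempfile()
  write_graph_dump(g, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "#")), 2L)
  expect_equal(length(lines), 2L + nrow(g$node_features) + nrow(g$edges))
})
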