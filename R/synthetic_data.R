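#' @include complex_graph.R
NULL

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# derived per-item seed kept inside the 32-bit integer range
derive_seed <- function(seed, k) as.integer((seed + 7919 * k) %% 2147483647)

#' Synthetic dataset specification
#'
#' Parameters of the toy PDBbind-like generator. Defaults define the study
#' conditions used throughout the package's learnability checks: 500
#' complexes, pockets of 30-60 residues, ligands of 10-30 heavy atoms,
#' planted weights (1, 1, 2) on the ligand-size / pocket-hydrophobicity /
#' contact-count terms, a 4.5 Angstrom contact threshold, and 0.3 pK of
#' Gaussian label noise.
#'
#' @param n_samples number of complexes.
#' @param pocket_length integer range (min, max) of pocket residues.
#' @param ligand_size integer range (min, max) of ligand heavy atoms.
#' @param weights numeric triple `(w_lig, w_poc, w_int)` weighting the three
#'   standardized planted terms.
#' @param contact_threshold contact-count distance cutoff in Angstrom.
#' @param noise_sd label noise standard deviation in pK units.
#' @param seed master seed; every structure and label derives from it.
#' @return A list of class `pla_synth_spec`.
#' @export
synthetic_spec <- function(n_samples = 500L, pocket_length = c(30L, 60L),
                           ligand_size = c(10L, 30L),
                           weights = c(w_lig = 1, w_poc = 1, w_int = 2),
                           contact_threshold = 4.5, noise_sd = 0.3,
                           seed = 1L) {
  stopifnot(n_samples >= 1L, noise_sd >= 0, all(is.finite(weights)),
            length(weights) == 3L, contact_threshold > 0,
            pocket_length[1] >= 2L, ligand_size[1] >= 1L)
  names(weights) <- c("w_lig", "w_poc", "w_int")
  structure(list(n_samples = as.integer(n_samples),
                 pocket_length = as.integer(pocket_length),
                 ligand_size = as.integer(ligand_size),
                 weights = weights, contact_threshold = contact_threshold,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "pla_synth_spec")
}

# amplitude of the Lissajous backbone curve; keeps pockets compact enough
# that a ligand near the centroid is in atomic contact with the pocket
.POCKET_AMPLITUDE <- 8.5
.CA_SPACING <- 3.8

#' Generate a synthetic pocket
#'
#' A random sequence over the 20-letter alphabet with one C-alpha-like carbon
#' per residue, placed along a smooth random Lissajous space curve with exact
#' 3.8 Angstrom spacing between consecutive residues (the C-alpha virtual
#' bond length), so the pocket is compact and writable as a valid PDB.
#'
#' @param seed RNG seed.
#' @param length number of residues (>= 2).
#' @return A `pla_pocket`.
#' @export
generate_pocket <- function(seed, length) {
  if (length < 2L) stop("pocket length must be >= 2")
  with_seed(seed, {
    letters_ <- sample(AA_ALPHABET, length, replace = TRUE)
    freq <- c(1, 2, 3) + runif(3, -0.3, 0.3)
    phase <- runif(3, 0, 2 * pi)
    curve <- function(t)
      .POCKET_AMPLITUDE * sin(freq * t + phase)
    pts <- matrix(0, length, 3)
    t <- 0
    pts[1, ] <- curve(t)
    for (k in 2:length) {
      prev <- pts[k - 1L, ]
      f <- function(tt) sqrt(sum((curve(tt) - prev)^2)) - .CA_SPACING
      lo <- t
      repeat {
        hi <- lo + 0.02
        if (f(hi) >= 0) break
        lo <- hi
      }
      t <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
      pts[k, ] <- curve(t)
    }
    three <- names(RESIDUE_CODES)[match(letters_, RESIDUE_CODES)]
    residues <- data.frame(resid = three, chain = "A", resno = seq_len(length))
    atoms <- data.frame(element = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        res_index = seq_len(length))
    new_pocket(residues, atoms)
  })
}

# per-element degree caps for the cartoon chemistry
.degree_cap <- c(C = 4L, N = 3L, O = 2L, S = 2L)

#' Generate a synthetic ligand
#'
#' A random tree-plus-cycles molecular graph over C/N/O/S with degree caps,
#' bond lengths in 1.2-1.8 Angstrom by construction, and coordinates grown
#' within 6 Angstrom of the pocket centroid so ligand-pocket contacts exist.
#'
#' @param seed RNG seed.
#' @param n_atoms number of heavy atoms (>= 1).
#' @param pocket the `pla_pocket` the ligand is placed against.
#' @return A `pla_ligand`.
#' @export
generate_ligand <- function(seed, n_atoms, pocket) {
  stopifnot(n_atoms >= 1L, inherits(pocket, "pla_pocket"))
  with_seed(seed, {
    centroid <- colMeans(as.matrix(pocket$atoms[, c("x", "y", "z")]))
    elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                       prob = c(0.70, 0.15, 0.10, 0.05))
    xyz <- matrix(0, n_atoms, 3)
    # seed atom within 3 Angstrom of the centroid
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    xyz[1, ] <- centroid + u * runif(1, 0, 3)
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
    deg <- integer(n_atoms)
    cap <- .degree_cap[elements]
    if (n_atoms > 1L) {
      for (k in 2:n_atoms) {
        open <- which(deg[seq_len(k - 1L)] < cap[seq_len(k - 1L)])
        parent <- if (length(open) > 0L) open[sample.int(length(open), 1L)]
                  else sample.int(k - 1L, 1L)
        for (try in 1:60) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          pos <- xyz[parent, ] + u * runif(1, 1.2, 1.8)
          far <- sqrt(sum((pos - centroid)^2)) > 6
          clash <- any(sqrt(rowSums(sweep(xyz[seq_len(k - 1L), , drop = FALSE],
                                          2, pos)^2)) < 1.0)
          if (!far && !clash) break
        }
        xyz[k, ] <- pos
        order <- if (elements[k] %in% c("C", "N", "O") &&
                     elements[parent] %in% c("C", "N", "O") &&
                     deg[parent] < cap[parent] - 1L && runif(1) < 0.15) 2L else 1L
        bonds <- rbind(bonds, data.frame(i = parent, j = k, order = order))
        deg[parent] <- deg[parent] + 1L
        deg[k] <- deg[k] + 1L
      }
      # close a few cycles where geometry already permits a bond
      D <- as.matrix(stats::dist(xyz))
      bonded <- matrix(FALSE, n_atoms, n_atoms)
      bonded[cbind(bonds$i, bonds$j)] <- TRUE
      bonded[cbind(bonds$j, bonds$i)] <- TRUE
      cand <- which(D >= 1.2 & D <= 1.8 & upper.tri(D) & !bonded, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        for (r in seq_len(nrow(cand))) {
          ii <- cand[r, 1]; jj <- cand[r, 2]
          if (deg[ii] < cap[ii] && deg[jj] < cap[jj] && runif(1) < 0.5) {
            bonds <- rbind(bonds, data.frame(i = ii, j = jj, order = 1L))
            deg[ii] <- deg[ii] + 1L
            deg[jj] <- deg[jj] + 1L
          }
        }
      }
    }
    atoms <- data.frame(element = elements, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], charge = 0L)
    new_ligand(atoms, bonds, name = sprintf("synth-%d", seed))
  })
}

# cross-molecule atom pairs within the contact threshold
.contact_count <- function(ligand, pocket, threshold) {
  lx <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  px <- as.matrix(pocket$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(lx^2), rowSums(px^2), `+`) - 2 * lx %*% t(px)
  sum(d2 <= threshold^2 + 1e-12)
}

# Population moments of the three planted terms under a spec's settings.
# Ligand size and pocket hydrophobic fraction have closed forms (uniform
# atom count; i.i.d. uniform letters with 7 of 20 hydrophobic); the contact
# count is calibrated by a short seeded Monte Carlo, memoized per spec.
affinity_calibration <- function(spec, n_draws = 200L) {
  key <- paste0("calib|", paste(unlist(spec[c("pocket_length", "ligand_size",
                                              "contact_threshold")]),
                                collapse = "|"))
  hit <- get0(key, .pla_env)
  if (!is.null(hit)) return(hit)
  lo <- spec$ligand_size[1]; hi <- spec$ligand_size[2]
  m1 <- (lo + hi) / 2
  s1 <- sqrt(((hi - lo + 1)^2 - 1) / 12)
  p <- nchar(CTD_GROUPINGS$hydrophobicity$hydrophobic) / 20
  inv_l <- mean(1 / seq(spec$pocket_length[1], spec$pocket_length[2]))
  m2 <- p
  s2 <- sqrt(p * (1 - p) * inv_l)
  contacts <- vapply(seq_len(n_draws), function(k) {
    sd <- derive_seed(104729L, k)
    pocket <- generate_pocket(sd, sample_range(sd + 1L, spec$pocket_length))
    ligand <- generate_ligand(sd + 2L, sample_range(sd + 3L, spec$ligand_size),
                              pocket)
    .contact_count(ligand, pocket, spec$contact_threshold)
  }, 0)
  out <- list(mean = c(m1, m2, mean(contacts)),
              sd = c(s1, max(s2, 1e-9), max(sd(contacts), 1e-9)))
  assign(key, out, .pla_env)
  out
}

sample_range <- function(seed, range) {
  with_seed(seed, sample(seq(range[1], range[2]), 1L))
}

#' Planted affinity of a synthetic complex
#'
#' The generator's ground-truth label: a weighted sum of three standardized
#' terms - ligand heavy-atom count, hydrophobic-class fraction of the pocket
#' sequence, and the count of ligand-pocket atom pairs within the contact
#' threshold - mapped linearly onto the pK scale (centered at 7, three
#' population standard deviations spanning 7 +/- 5) plus Gaussian noise, then
#' clamped to the realistic [2, 12] pK range. Standardization uses population
#' moments under the spec's settings (closed forms for the first two terms, a
#' frozen seeded Monte Carlo for the contact term), so labels of different
#' samples are independent.
#'
#' @param ligand a `pla_ligand`.
#' @param pocket a `pla_pocket`.
#' @param spec a [synthetic_spec()].
#' @param noise_seed seed for the label noise draw; `NULL` means no noise.
#' @return A list with `label` (pK) and `noiseless` (pK before noise).
#' @export
planted_affinity <- function(ligand, pocket, spec, noise_seed = NULL) {
  calib <- affinity_calibration(spec)
  seq_ <- pocket$sequence
  hydro <- strsplit(CTD_GROUPINGS$hydrophobicity$hydrophobic, "")[[1]]
  frac <- mean(strsplit(seq_, "")[[1]] %in% hydro)
  feats <- c(nrow(ligand$atoms), frac,
             .contact_count(ligand, pocket, spec$contact_threshold))
  z <- (feats - calib$mean) / calib$sd
  w <- spec$weights
  wnorm <- sqrt(sum(w^2))
  signal <- if (wnorm > 0) sum(w * z) / wnorm else 0
  noiseless <- min(12, max(2, 7 + (5 / 3) * signal))
  label <- noiseless
  if (!is.null(noise_seed) && spec$noise_sd > 0)
    label <- min(12, max(2, noiseless +
                           with_seed(noise_seed, stats::rnorm(1, 0, spec$noise_sd))))
  list(label = label, noiseless = noiseless)
}

#' Generate a synthetic PDBbind-like dataset
#'
#' Draws `spec$n_samples` pocket/ligand complexes with planted labels. With
#' `dir` set, writes each complex as `<id>_pocket.pdb` + `<id>_ligand.sdf`, a
#' PDBbind-style index file (`id resolution year pK`), and a JSON manifest
#' recording the spec, the seed and the noiseless labels. Fully deterministic
#' per seed, including index file bytes.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory (created if missing).
#' @return A list with `samples` (list of `pla_complex`) and `manifest`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "pla_synth_spec"))
  samples <- vector("list", spec$n_samples)
  noiseless <- numeric(spec$n_samples)
  for (k in seq_len(spec$n_samples)) {
    s <- generate_complex(spec, k)
    samples[[k]] <- s$sample
    noiseless[k] <- s$noiseless
  }
  ids <- vapply(samples, `[[`, "", "id")
  manifest <- list(spec = unclass(spec), ids = ids, noiseless_labels = noiseless,
                   labels = vapply(samples, `[[`, 0, "label"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in samples) {
      write_pocket_pdb(s$pocket, file.path(dir, paste0(s$id, "_pocket.pdb")))
      write_ligand_sdf(s$ligand, file.path(dir, paste0(s$id, "_ligand.sdf")))
    }
    idx <- c("# synthetic index: id resolution year pK",
             sprintf("%s  2.00  2024  %.4f", ids, manifest$labels))
    writeLines(idx, file.path(dir, "index.txt"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(samples = samples, manifest = manifest)
}

#' Generate one synthetic complex
#'
#' @param spec a [synthetic_spec()].
#' @param k 1-based sample index; all per-sample seeds derive from
#'   `spec$seed` and `k`.
#' @return A list with `sample` (a `pla_complex`) and `noiseless` label.
#' @export
generate_complex <- function(spec, k) {
  base <- derive_seed(spec$seed, 10L * k)
  pocket <- generate_pocket(base, sample_range(base + 1L, spec$pocket_length))
  ligand <- generate_ligand(base + 2L, sample_range(base + 3L, spec$ligand_size),
                            pocket)
  aff <- planted_affinity(ligand, pocket, spec, noise_seed = base + 4L)
  list(sample = new_complex_sample(ligand, pocket, label = aff$label,
                                   id = sprintf("synth%05d", k)),
       noiseless = aff$noiseless)
}
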