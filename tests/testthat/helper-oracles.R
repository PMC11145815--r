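# Independent brute-force oracles used by the unit and acceptance suites.
# These deliberately re-derive every quantity with naive loops so they share
# no code with the implementation under test.

oracle_composition <- function(sequence, grouping) {
  letters_ <- strsplit(sequence, "")[[1]]
  out <- numeric(3)
  for (g in 1:3) {
    members <- strsplit(grouping[[g]], "")[[1]]
    cnt <- 0
    for (ch in letters_) if (ch %in% members) cnt <- cnt + 1
    out[g] <- 100 * cnt / length(letters_)
  }
  out
}

oracle_transition <- function(sequence, grouping) {
  letters_ <- strsplit(sequence, "")[[1]]
  cls <- integer(length(letters_))
  for (g in 1:3) cls[letters_ %in% strsplit(grouping[[g]], "")[[1]]] <- g
  counts <- c(0, 0, 0)  # (1,2), (1,3), (2,3)
  for (k in seq_len(length(cls) - 1L)) {
    pair <- sort(c(cls[k], cls[k + 1L]))
    if (pair[1] == 1 && pair[2] == 2) counts[1] <- counts[1] + 1
    if (pair[1] == 1 && pair[2] == 3) counts[2] <- counts[2] + 1
    if (pair[1] == 2 && pair[2] == 3) counts[3] <- counts[3] + 1
  }
  100 * counts / (length(cls) - 1L)
}

oracle_distribution <- function(sequence, grouping) {
  letters_ <- strsplit(sequence, "")[[1]]
  cls <- integer(length(letters_))
  for (g in 1:3) cls[letters_ %in% strsplit(grouping[[g]], "")[[1]]] <- g
  n <- length(cls)
  out <- numeric(0)
  for (g in 1:3) {
    pos <- which(cls == g)
    if (length(pos) == 0) {
      out <- c(out, rep(0, 5))
    } else {
      ng <- length(pos)
      picks <- c(1, sapply(1:4, function(k) max(1, ceiling(k * ng / 4))))
      out <- c(out, 100 * pos[picks] / n)
    }
  }
  out
}

random_aa_sequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# all-pairs scan for non-covalent edges of a pooled ligand+pocket atom set
oracle_noncovalent <- function(ligand, pocket, threshold) {
  xyz <- rbind(as.matrix(ligand$atoms[, c("x", "y", "z")]),
               as.matrix(pocket$atoms[, c("x", "y", "z")]))
  bonded <- matrix(FALSE, nrow(xyz), nrow(xyz))
  if (nrow(ligand$bonds) > 0) {
    for (r in seq_len(nrow(ligand$bonds))) {
      bonded[ligand$bonds$i[r], ligand$bonds$j[r]] <- TRUE
      bonded[ligand$bonds$j[r], ligand$bonds$i[r]] <- TRUE
    }
  }
  pairs <- NULL
  for (i in seq_len(nrow(xyz))) for (j in seq_len(nrow(xyz))) {
    if (i == j || bonded[i, j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= threshold) pairs <- rbind(pairs, c(i, j, d))
  }
  pairs
}

oracle_metrics <- function(pred, true) {
  n <- length(pred)
  mp <- sum(pred) / n; mt <- sum(true) / n
  list(pcc = sum((pred - mp) * (true - mt)) /
         sqrt(sum((pred - mp)^2) * sum((true - mt)^2)),
       mae = sum(abs(pred - true)) / n,
       rmse = sqrt(sum((pred - true)^2) / n))
}

# memoized default-condition dataset shared by the expensive suites
default_dataset_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(synthetic_spec(seed = 1L))
      f <- featurize_samples(ds$samples)
      cache <<- list(ds = ds, features = f)
    }
    cache
  }
})
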