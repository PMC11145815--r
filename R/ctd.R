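#' @include structure_io.R
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# The canonical three-class partitions of the 20 amino acids used by CTD
# sequence descriptors, one per physicochemical property. Each row of classes
# is a disjoint cover of the 20-letter alphabet.
CTD_GROUPINGS <- list(
  hydrophobicity = list(polar = "RKEDQN", neutral = "GASTPHY",
                        hydrophobic = "CLVIMFW"),
  normwaalsvolume = list(low = "GASTPDC", medium = "NVEQIL", high = "MHKFRYW"),
  polarity = list(low = "LIFWCMVY", medium = "PATGS", high = "HQRKNED"),
  polarizability = list(low = "GASDT", medium = "CPNVEQIL", high = "KMHFRYW"),
  charge = list(positive = "KR", neutral = "ANCQGHILMFPSTWYV", negative = "DE"),
  secondarystruct = list(helix = "EALMQKRH", strand = "VIYCWFT", coil = "GNPSD"),
  solventaccess = list(buried = "ALFCGIVW", exposed = "RKQEND",
                       intermediate = "MSPTHY"))

POCKET_REGISTRY_VERSION <- "plafusion-ctd-1.0"

#' CTD property groupings
#'
#' The seven three-class amino-acid partitions (hydrophobicity, normalized
#' van der Waals volume, polarity, polarizability, charge, secondary
#' structure, solvent accessibility) underlying the 147 pocket CTD
#' descriptors. Each grouping partitions the 20 standard amino acids into
#' three disjoint classes.
#'
#' @param name optional grouping name; omit for the full list.
#' @return A named list of class-letter strings, or the list of all seven.
#' @export
ctd_groupings <- function(name = NULL) {
  if (is.null(name)) return(CTD_GROUPINGS)
  if (!name %in% names(CTD_GROUPINGS))
    stop(sprintf("unknown CTD property '%s'", name))
  CTD_GROUPINGS[[name]]
}

# map a sequence to per-residue class indices 1..3 under one grouping
.ctd_classes <- function(sequence, grouping) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a nonempty string")
  letters_ <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters_, AA_ALPHABET)
  if (length(bad) > 0L)
    stop(sprintf("sequence contains letters outside the 20-letter alphabet: %s",
                 paste(unique(bad), collapse = ", ")))
  cls <- integer(length(letters_))
  for (g in 1:3) {
    members <- strsplit(grouping[[g]], "")[[1]]
    cls[letters_ %in% members] <- g
  }
  cls
}

#' CTD composition
#'
#' Percent of residues falling in each of the grouping's three classes:
#' `C_g = 100 n_g / N`.
#'
#' @param sequence one-letter amino-acid string.
#' @param grouping a three-class grouping from [ctd_groupings()].
#' @return Numeric 3-vector of percents summing to 100.
#' @export
ctd_composition <- function(sequence, grouping) {
  cls <- .ctd_classes(sequence, grouping)
  100 * tabulate(cls, nbins = 3L) / length(cls)
}

#' CTD transition
#'
#' Percent of adjacent residue pairs that cross between two classes:
#' `T_gh = 100 (n_gh + n_hg) / (N - 1)`, reported in the order
#' (T12, T13, T23).
#'
#' @inheritParams ctd_composition
#' @return Numeric 3-vector of percents.
#' @export
ctd_transition <- function(sequence, grouping) {
  cls <- .ctd_classes(sequence, grouping)
  n <- length(cls)
  if (n < 2L) stop("transition requires a sequence of length >= 2")
  a <- cls[-n]; b <- cls[-1]
  lo <- pmin(a, b); hi <- pmax(a, b)
  counts <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
              sum(lo == 2 & hi == 3))
  100 * counts / (n - 1)
}

#' CTD distribution
#'
#' For each class, the sequence positions (as percent of the length) at which
#' the first and the 25/50/75/100% occurrences of the class are found; the
#' k-quartile position is the 1-based index of the `ceiling(k n_g / 4)`-th
#' occurrence. Classes absent from the sequence yield five zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric 15-vector (class-major: first, p25, p50, p75, p100 per
#'   class).
#' @export
ctd_distribution <- function(sequence, grouping) {
  cls <- .ctd_classes(sequence, grouping)
  n <- length(cls)
  out <- numeric(0)
  for (g in 1:3) {
    pos <- which(cls == g)
    if (length(pos) == 0L) {
      out <- c(out, rep(0, 5))
    } else {
      ng <- length(pos)
      idx <- c(1L, pmax(1L, ceiling((1:4) * ng / 4)))
      out <- c(out, 100 * pos[idx] / n)
    }
  }
  out
}

#' Pocket CTD descriptor vector
#'
#' The 147-element CTD vector of a pocket sequence: for each of the seven
#' property groupings, 3 composition + 3 transition + 15 distribution values
#' (property-major order).
#'
#' @param sequence one-letter amino-acid string (length >= 2).
#' @return Named numeric vector of length 147 with attribute
#'   `registry_version`.
#' @export
pocket_ctd <- function(sequence) {
  vals <- numeric(0)
  nms <- character(0)
  dist_tags <- as.vector(t(outer(paste0("D", 1:3),
                                 c("first", "p25", "p50", "p75", "p100"),
                                 paste, sep = ".")))
  for (prop in names(CTD_GROUPINGS)) {
    grouping <- CTD_GROUPINGS[[prop]]
    vals <- c(vals, ctd_composition(sequence, grouping),
              ctd_transition(sequence, grouping),
              ctd_distribution(sequence, grouping))
    nms <- c(nms, paste(prop, c(paste0("C", 1:3), c("T12", "T13", "T23"),
                                dist_tags), sep = "."))
  }
  structure(setNames(vals, nms), registry_version = POCKET_REGISTRY_VERSION)
}
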