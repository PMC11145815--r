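#' @include ligand_descriptors.R
NULL

GRAPH_RECIPE_ID <- "plafusion-atom19-1.0"

EDGE_TYPES <- c("covalent:single", "covalent:double", "covalent:triple",
                "covalent:aromatic", "noncovalent")

.bond_edge_type <- c(`1` = "covalent:single", `2` = "covalent:double",
                     `3` = "covalent:triple", `4` = "covalent:aromatic")

FEATURE_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "H", "other")

# single-bond covalent radii (Angstrom) for pocket covalent-edge inference
.covalent_radii <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                     F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, H = 0.31,
                     B = 0.84, Si = 1.11, other = 1.10)

#' Graph construction configuration
#'
#' @param distance_threshold non-covalent edge cutoff in Angstrom (pairs at
#'   or below this interatomic distance are connected). Default 4.5, the
#'   convention of staged gated-graph interaction networks.
#' @param include_pocket_covalent infer pocket-internal covalent edges by the
#'   covalent-radius rule `d <= r_i + r_j + 0.4` (pocket PDB files carry no
#'   connectivity records).
#' @param include_hydrogens keep hydrogen atoms as graph nodes (default
#'   drop; pocket structures usually lack them, and keeping ligand-only
#'   hydrogens would bias the ligand mask).
#' @return A list of class `pla_graph_config`.
#' @export
graph_config <- function(distance_threshold = 4.5,
                         include_pocket_covalent = TRUE,
                         include_hydrogens = FALSE) {
  stopifnot(is.numeric(distance_threshold), distance_threshold > 0)
  structure(list(distance_threshold = distance_threshold,
                 include_pocket_covalent = include_pocket_covalent,
                 include_hydrogens = include_hydrogens,
                 recipe_id = GRAPH_RECIPE_ID),
            class = "pla_graph_config")
}

#' Per-atom node features
#'
#' The frozen 19-dimensional node feature recipe: one-hot element over
#' (C, N, O, S, P, F, Cl, Br, I, H, other), one-hot covalent degree 0-5
#' (capped at 5), formal charge, and a ligand-membership flag.
#'
#' @param element element symbol (unknown symbols map to "other").
#' @param charge formal charge.
#' @param degree covalent degree.
#' @param is_ligand logical ligand-membership flag.
#' @return Numeric vector of length 19.
#' @export
atom_features <- function(element, charge, degree, is_ligand) {
  el <- match(element, FEATURE_ELEMENTS)
  if (is.na(el)) el <- length(FEATURE_ELEMENTS)
  one_el <- numeric(length(FEATURE_ELEMENTS)); one_el[el] <- 1
  one_deg <- numeric(6); one_deg[min(degree, 5L) + 1L] <- 1
  c(one_el, one_deg, charge, as.numeric(is_ligand))
}

.complex_coords <- function(ligand, pocket) {
  rbind(as.matrix(ligand$atoms[, c("x", "y", "z")]),
        as.matrix(pocket$atoms[, c("x", "y", "z")]))
}

#' Non-covalent edges of a complex
#'
#' All atom pairs of the pooled ligand + pocket atom set (ligand atoms first)
#' whose Euclidean distance is at or below the threshold, excluding
#' self-pairs and pairs already covalently bonded. Both edge directions are
#' returned.
#'
#' @param ligand a `pla_ligand`.
#' @param pocket a `pla_pocket`.
#' @param threshold distance cutoff in Angstrom.
#' @param exclude optional 2-column matrix of covalently bonded pairs (pooled
#'   indices) to exclude; defaults to the ligand's bonds.
#' @return data.frame with columns `i`, `j`, `distance` (each undirected pair
#'   appears in both directions).
#' @export
noncovalent_edges <- function(ligand, pocket, threshold,
                              exclude = NULL) {
  stopifnot(threshold > 0)
  xyz <- .complex_coords(ligand, pocket)
  D <- as.matrix(stats::dist(xyz))
  sel <- D <= threshold & upper.tri(D)
  if (is.null(exclude))
    exclude <- cbind(ligand$bonds$i, ligand$bonds$j)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    lo <- pmin(exclude[, 1], exclude[, 2])
    hi <- pmax(exclude[, 1], exclude[, 2])
    sel[cbind(lo, hi)] <- FALSE
  }
  idx <- which(sel, arr.ind = TRUE)
  data.frame(i = c(idx[, 1], idx[, 2]), j = c(idx[, 2], idx[, 1]),
             distance = rep(D[idx], 2L))
}

#' Build the spatial interaction graph of a complex
#'
#' Nodes are the pooled heavy atoms (ligand first, then pocket; hydrogens
#' dropped unless configured otherwise) carrying the 19-dimensional
#' [atom_features()] recipe. Covalent edges come from the ligand's bond
#' table, typed by bond order, and (optionally) from the covalent-radius rule
#' within the pocket; non-covalent edges connect every remaining atom pair
#' within the distance threshold. Every edge is stored in both directions.
#'
#' @param sample a `pla_complex`.
#' @param config a [graph_config()].
#' @return An object of class `pla_graph` with fields `node_features`
#'   (n x 19 matrix), `edges` (data.frame `i`, `j`, `type`, `distance`),
#'   `ligand_mask`, `recipe_id`.
#' @export
build_complex_graph <- function(sample, config = graph_config()) {
  stopifnot(inherits(sample, "pla_complex"), inherits(config, "pla_graph_config"))
  ligand <- sample$ligand
  pocket <- sample$pocket
  if (!config$include_hydrogens) {
    keep_l <- which(ligand$atoms$element != "H")
    if (length(keep_l) == 0L) stop("graph construction: ligand has no heavy atoms")
    if (length(keep_l) < nrow(ligand$atoms)) {
      remap <- match(seq_len(nrow(ligand$atoms)), keep_l)
      b <- ligand$bonds
      b <- b[!is.na(remap[b$i]) & !is.na(remap[b$j]), , drop = FALSE]
      b$i <- remap[b$i]; b$j <- remap[b$j]
      ligand <- new_ligand(ligand$atoms[keep_l, , drop = FALSE], b, ligand$name)
    }
    keep_p <- pocket$atoms$element != "H"
    if (!any(keep_p)) stop("graph construction: pocket has no heavy atoms")
    pocket <- structure(list(residues = pocket$residues,
                             atoms = pocket$atoms[keep_p, , drop = FALSE],
                             sequence = pocket$sequence), class = "pla_pocket")
  }
  nl <- nrow(ligand$atoms)
  np <- nrow(pocket$atoms)
  n <- nl + np
  elements <- c(ligand$atoms$element, pocket$atoms$element)
  charges <- c(ligand$atoms$charge, rep(0, np))

  cov <- data.frame(i = integer(), j = integer(), type = character(),
                    distance = numeric())
  xyz <- .complex_coords(ligand, pocket)
  if (nrow(ligand$bonds) > 0L) {
    b <- ligand$bonds
    d <- sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
    cov <- data.frame(i = b$i, j = b$j,
                      type = unname(.bond_edge_type[as.character(b$order)]),
                      distance = d)
  }
  if (config$include_pocket_covalent && np > 1L) {
    pxyz <- xyz[nl + seq_len(np), , drop = FALSE]
    Dp <- as.matrix(stats::dist(pxyz))
    r <- .covalent_radii[pocket$atoms$element]
    r[is.na(r)] <- .covalent_radii[["other"]]
    lim <- outer(r, r, `+`) + 0.4
    sel <- Dp <= lim & upper.tri(Dp)
    idx <- which(sel, arr.ind = TRUE)
    if (nrow(idx) > 0L)
      cov <- rbind(cov, data.frame(i = nl + idx[, 1], j = nl + idx[, 2],
                                   type = "covalent:single",
                                   distance = Dp[idx]))
  }
  ncov <- noncovalent_edges(ligand, pocket, config$distance_threshold,
                            exclude = as.matrix(cov[, c("i", "j")]))
  edges <- rbind(
    data.frame(i = c(cov$i, cov$j), j = c(cov$j, cov$i),
               type = rep(cov$type, 2L), distance = rep(cov$distance, 2L)),
    data.frame(i = ncov$i, j = ncov$j, type = rep("noncovalent", nrow(ncov)),
               distance = ncov$distance))
  deg <- tabulate(c(cov$i, cov$j), nbins = n)
  feats <- t(vapply(seq_len(n), function(k)
    atom_features(elements[k], charges[k], deg[k], k <= nl), numeric(19)))
  structure(list(node_features = feats, edges = edges,
                 ligand_mask = seq_len(n) <= nl,
                 distance_threshold = config$distance_threshold,
                 recipe_id = config$recipe_id),
            class = "pla_graph")
}

#' @export
print.pla_graph <- function(x, ...) {
  cat(sprintf("<pla_graph> %d nodes (%d ligand), %d directed edges (%d noncovalent)\n",
              nrow(x$node_features), sum(x$ligand_mask), nrow(x$edges),
              sum(x$edges$type == "noncovalent")))
  invisible(x)
}

#' Dump a graph as node and edge tables
#'
#' Writes a plain-text debugging dump: a `# nodes` table (index, ligand flag,
#' feature vector) and a `# edges` table (i, j, type, distance).
#'
#' @param graph a `pla_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph_dump <- function(graph, path) {
  stopifnot(inherits(graph, "pla_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nodes: index ligand features...", con)
  feats <- apply(graph$node_features, 1, paste, collapse = " ")
  writeLines(sprintf("%d %d %s", seq_along(feats),
                     as.integer(graph$ligand_mask), feats), con)
  writeLines("# edges: i j type distance", con)
  e <- graph$edges
  writeLines(sprintf("%d %d %s %.4f", e$i, e$j, e$type, e$distance), con)
  invisible(path)
}
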