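#' @include ctd.R
NULL

LIGAND_REGISTRY_VERSION <- "plafusion-ld-1.0"

# atomic property tables over the supported heavy elements; "other" is the
# fallback row for anything else
DESCRIPTOR_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si")

.atomic_table <- local({
  el <- c(DESCRIPTOR_ELEMENTS, "other")
  mass <- c(12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45, 79.904,
            126.904, 10.81, 28.085, 50)
  en <- c(2.55, 3.04, 3.44, 2.58, 2.19, 3.98, 3.16, 2.96, 2.66, 2.04, 1.90, 2.2)
  rvdw <- c(1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98, 1.92, 2.10, 2.0)
  pol <- c(1.76, 1.10, 0.80, 2.90, 3.63, 0.56, 2.18, 3.05, 5.35, 3.03, 5.38, 3.0)
  period <- c(2, 2, 2, 3, 3, 2, 3, 4, 5, 2, 3, 3)
  valence_e <- c(4, 5, 6, 6, 5, 7, 7, 7, 7, 3, 4, 4)
  default_valence <- c(4, 3, 2, 2, 3, 1, 1, 1, 1, 3, 4, 4)
  logp <- c(0.20, -0.70, -0.60, 0.25, -0.40, 0.20, 0.60, 0.85, 1.10, 0.20, 0.30, 0)
  psa <- c(0, 11.68, 20.23, 25.30, 13.59, 0, 0, 0, 0, 0, 0, 0)
  data.frame(element = el, mass = mass, en = en,
             vol = 4 / 3 * pi * rvdw^3, pol = pol, period = period,
             valence_e = valence_e, default_valence = default_valence,
             logp = logp, psa = psa)
})

.elem_row <- function(elements) {
  idx <- match(elements, .atomic_table$element)
  idx[is.na(idx)] <- nrow(.atomic_table)  # "other"
  idx
}

# warn once per descriptor name per session when imputing non-finite values
.pla_env <- new.env(parent = emptyenv())
.impute_nonfinite <- function(v) {
  bad <- !is.finite(v)
  if (any(bad)) {
    fresh <- setdiff(names(v)[bad], get0("warned", .pla_env, ifnotfound = character()))
    if (length(fresh) > 0L) {
      warning(sprintf("imputing 0 for non-finite descriptor(s): %s",
                      paste(fresh, collapse = ", ")), call. = FALSE)
      assign("warned", c(get0("warned", .pla_env, ifnotfound = character()), fresh),
             .pla_env)
    }
    v[bad] <- 0
  }
  v
}

# enumerate counts of simple paths with 2..4 edges (each path counted once)
.path_counts <- function(adj, n) {
  counts <- c(p2 = 0, p3 = 0, p4 = 0)
  sums <- c(p2 = 0, p3 = 0, p4 = 0)  # sum over paths of prod(1/sqrt(deg))
  deg <- lengths(adj)
  isd <- 1 / sqrt(pmax(deg, 1))
  walk <- function(path, weight) {
    len <- length(path) - 1L
    if (len >= 2L) {
      key <- paste0("p", len)
      # each undirected path is visited from both ends; count half
      counts[[key]] <<- counts[[key]] + 0.5
      sums[[key]] <<- sums[[key]] + 0.5 * weight
    }
    if (len == 4L) return()
    for (nb in adj[[path[length(path)]]]) {
      if (!(nb %in% path)) walk(c(path, nb), weight * isd[nb])
    }
  }
  for (v in seq_len(n)) walk(v, isd[v])
  list(counts = counts, chi_sums = sums)
}

.ligand_graph <- function(ligand) {
  n <- nrow(ligand$atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ligand$bonds) > 0L)
    g <- igraph::add_edges(g, rbind(ligand$bonds$i, ligand$bonds$j))
  g
}

#' Ligand descriptor vector
#'
#' Computes the frozen 196-element registry of named 2D
#' physicochemical/topological descriptors from the ligand's molecular graph:
#' element counts and fractions, size/ring/bond-order counts, formal-charge
#' and mass summaries, degree distribution, hydrogen-bond donor/acceptor
#' counts (N/O with free valence count as donors; hydrogens are implicit),
#' classical topological indices (Wiener, Zagreb, Randic, Platt, Balaban J,
#' eccentricity shape measures), connectivity (chi) and kappa shape indices,
#' electrotopological-state sums, Moreau-Broto autocorrelations (raw and
#' centered) of atomic mass/electronegativity/van der Waals volume/
#' polarizability at topological lags 1-8, bond-composition counts, and
#' crude additive logP / molar-refractivity / polar-surface-area estimates.
#' All descriptors are functions of the unlabeled molecular graph, so the
#' vector is invariant to atom and bond input order. Non-finite values
#' (possible on degenerate graphs) are imputed to 0 with a once-per-name
#' warning.
#'
#' @param ligand a `pla_ligand`.
#' @return Named numeric vector of length 196 with attribute
#'   `registry_version`.
#' @export
ligand_descriptors <- function(ligand) {
  stopifnot(inherits(ligand, "pla_ligand"))
  a <- ligand$atoms
  b <- ligand$bonds
  n <- nrow(a)
  if (n == 0L) stop("empty molecule")
  row <- .elem_row(a$element)
  tab <- .atomic_table[row, ]
  elem_label <- .atomic_table$element[row]

  g <- .ligand_graph(ligand)
  deg <- igraph::degree(g)
  D <- igraph::distances(g)
  finite_pairs <- is.finite(D) & upper.tri(D)
  comp <- igraph::components(g)

  halogens <- c("F", "Cl", "Br", "I")
  out <- c()
  add <- function(...) out <<- c(out, c(...))

  # element composition
  ecount <- vapply(DESCRIPTOR_ELEMENTS, function(e) sum(elem_label == e), 0)
  add(setNames(ecount, paste0("count_", DESCRIPTOR_ELEMENTS)),
      count_other = sum(elem_label == "other"))
  add(setNames(ecount / n, paste0("frac_", DESCRIPTOR_ELEMENTS)),
      frac_other = sum(elem_label == "other") / n)

  # sizes and rings (heavy-atom graph; cyclomatic ring count)
  nb <- nrow(b)
  bridges <- if (nb > 0L) length(igraph::bridges(g)) else 0L
  ring_bonds <- nb - bridges
  ring_atoms <- if (ring_bonds > 0L) {
    br <- igraph::bridges(g)
    keep <- setdiff(seq_len(nb), as.integer(br))
    length(unique(c(b$i[keep], b$j[keep])))
  } else 0L
  add(n_atoms = n, n_bonds = nb,
      n_rings = nb - n + comp$no,
      n_heteroatoms = sum(!elem_label %in% c("C")),
      n_halogens = sum(elem_label %in% halogens),
      n_components = comp$no,
      n_ring_atoms = ring_atoms, n_ring_bonds = ring_bonds)

  # bond orders
  bo <- if (nb > 0L) b$order else integer()
  bcount <- c(sum(bo == 1L), sum(bo == 2L), sum(bo == 3L), sum(bo == AROMATIC_BOND))
  add(setNames(bcount, c("n_bond_single", "n_bond_double", "n_bond_triple",
                         "n_bond_aromatic")))
  add(setNames(if (nb > 0L) bcount / nb else rep(0, 4),
               c("frac_bond_single", "frac_bond_double", "frac_bond_triple",
                 "frac_bond_aromatic")))

  # formal charges
  add(charge_total = sum(a$charge), charge_abs_sum = sum(abs(a$charge)),
      n_charge_pos = sum(a$charge > 0), n_charge_neg = sum(a$charge < 0))

  # mass
  add(mol_weight = sum(tab$mass), mass_mean = mean(tab$mass),
      mass_max = max(tab$mass), mass_min = min(tab$mass))

  # degree distribution
  add(setNames(vapply(1:5, function(d) sum(deg == d), 0), paste0("n_deg", 1:5)),
      degree_mean = mean(deg), degree_max = max(deg),
      degree_var = if (n > 1L) stats::var(deg) else 0)

  # hydrogen-bond counts: acceptors are N/O; donors are N/O with spare
  # valence for an implicit hydrogen
  bond_order_sum <- numeric(n)
  if (nb > 0L) {
    w <- ifelse(bo == AROMATIC_BOND, 1.5, bo)
    for (k in seq_len(nb)) {
      bond_order_sum[b$i[k]] <- bond_order_sum[b$i[k]] + w[k]
      bond_order_sum[b$j[k]] <- bond_order_sum[b$j[k]] + w[k]
    }
  }
  implicit_h <- pmax(0, tab$default_valence - bond_order_sum + a$charge *
                       (elem_label == "N"))
  is_no <- elem_label %in% c("N", "O")
  hbd <- sum(is_no & implicit_h > 0)
  hba <- sum(is_no)
  add(n_hbd = hbd, n_hba = hba, frac_hbd = hbd / n, frac_hba = hba / n)

  # classical topological indices (finite distances only on disconnected
  # graphs)
  dfin <- D[finite_pairs]
  wiener <- sum(dfin)
  ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
  radius <- min(ecc); diam <- max(ecc)
  zg1 <- sum(deg^2)
  zg2 <- if (nb > 0L) sum(deg[b$i] * deg[b$j]) else 0
  randic <- if (nb > 0L) sum(1 / sqrt(deg[b$i] * deg[b$j])) else 0
  platt <- if (nb > 0L) sum(deg[b$i] + deg[b$j] - 2) else 0
  s <- rowSums(ifelse(is.finite(D), D, 0))
  gamma <- nb - n + comp$no
  balaban <- if (nb > 0L) nb / (gamma + 1) * sum(1 / sqrt(s[b$i] * s[b$j])) else 0
  add(wiener = wiener,
      distance_mean = if (length(dfin) > 0L) mean(dfin) else 0,
      zagreb_m1 = zg1, zagreb_m2 = zg2, randic = randic, platt = platt,
      radius = radius, diameter = diam, ecc_mean = mean(ecc),
      petitjean = if (radius > 0) (diam - radius) / radius else 0,
      graph_density = if (n > 1L) 2 * nb / (n * (n - 1)) else 0,
      balaban_j = balaban)

  # connectivity (chi) and kappa shape indices
  adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  pc <- .path_counts(adj, n)
  dv <- pmax(tab$valence_e - implicit_h, 1)
  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  chi1v <- if (nb > 0L) sum(1 / sqrt(dv[b$i] * dv[b$j])) else 0
  add(chi0 = chi0, chi1v = chi1v,
      chi2 = pc$chi_sums[["p2"]], chi3 = pc$chi_sums[["p3"]],
      chi4 = pc$chi_sums[["p4"]])
  p1 <- nb; p2 <- pc$counts[["p2"]]; p3 <- pc$counts[["p3"]]
  kap1 <- if (p1 > 0) n * (n - 1)^2 / p1^2 else 0
  kap2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  kap3 <- if (p3 > 0) {
    if (n %% 2 == 1) (n - 1) * (n - 3)^2 / p3^2 else (n - 3) * (n - 2)^2 / p3^2
  } else 0
  add(kappa1 = kap1, kappa2 = kap2, kappa3 = kap3)

  # electrotopological-state sums: intrinsic state from period, valence
  # electrons and degree; perturbation decays with squared topological
  # distance
  istate <- ((2 / tab$period)^2 * dv + 1) / pmax(deg, 1)
  pert <- numeric(n)
  if (n > 1L) {
    Dp <- D; diag(Dp) <- Inf
    W <- 1 / (Dp + 1)^2
    W[!is.finite(Dp)] <- 0
    pert <- rowSums(W * outer(istate, istate, `-`))
  }
  estate <- istate + pert
  eclass <- ifelse(elem_label %in% halogens, "halogen",
                   ifelse(elem_label %in% c("C", "N", "O", "S", "P"),
                          elem_label, "other"))
  add(estate_sum_C = sum(estate[eclass == "C"]),
      estate_sum_N = sum(estate[eclass == "N"]),
      estate_sum_O = sum(estate[eclass == "O"]),
      estate_sum_S = sum(estate[eclass == "S"]),
      estate_sum_P = sum(estate[eclass == "P"]),
      estate_sum_halogen = sum(estate[eclass == "halogen"]),
      estate_sum_other = sum(estate[eclass == "other"]),
      estate_total = sum(estate))
  add(estate_max = max(estate), estate_min = min(estate),
      estate_mean = mean(estate), estate_range = max(estate) - min(estate))

  # Moreau-Broto autocorrelations at topological lags 1-8, raw and centered
  props <- list(mass = tab$mass, en = tab$en, vol = tab$vol, pol = tab$pol)
  for (centered in c(FALSE, TRUE)) {
    for (pn in names(props)) {
      p <- props[[pn]]
      if (centered) p <- p - mean(p)
      for (lag in 1:8) {
        sel <- finite_pairs & D == lag
        val <- if (any(sel)) {
          idx <- which(sel, arr.ind = TRUE)
          sum(p[idx[, 1]] * p[idx[, 2]])
        } else 0
        add(setNames(val, sprintf("%s_%s_lag%d",
                                  if (centered) "atsc" else "ats", pn, lag)))
      }
    }
  }

  # bond-composition counts over {C,N,O,S}
  pair_name <- function(e1, e2) paste(sort(c(e1, e2)), collapse = "")
  pairs <- c("CC", "CN", "CO", "CS", "NN", "NO", "NS", "OO", "OS", "SS")
  pcounts <- setNames(numeric(length(pairs)), paste0("pair_", pairs))
  dbl <- c(double_CC = 0, double_CO = 0, double_CN = 0)
  trp <- c(triple_CC = 0, triple_CN = 0)
  nar <- 0
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      e1 <- elem_label[b$i[k]]; e2 <- elem_label[b$j[k]]
      nm <- paste0("pair_", pair_name(e1, e2))
      if (nm %in% names(pcounts)) pcounts[nm] <- pcounts[nm] + 1
      key <- pair_name(e1, e2)
      if (bo[k] == 2L && key %in% c("CC", "CO", "CN"))
        dbl[paste0("double_", key)] <- dbl[paste0("double_", key)] + 1
      if (bo[k] == 3L && key %in% c("CC", "CN"))
        trp[paste0("triple_", key)] <- trp[paste0("triple_", key)] + 1
      if (bo[k] == AROMATIC_BOND) nar <- nar + 1
    }
  }
  add(pcounts, dbl, trp, n_aromatic_pairs = nar)

  # distance-shape extras
  add(ecc_var = if (n > 1L) stats::var(ecc) else 0,
      wiener_polarity = sum(dfin == 3),
      n_pairs_dist2 = sum(dfin == 2), n_pairs_dist4 = sum(dfin == 4))

  # atomic property summaries
  for (pn in c("en", "vol", "pol")) {
    p <- props[[pn]]
    add(setNames(c(sum(p), mean(p), max(p), min(p)),
                 paste0(pn, c("_sum", "_mean", "_max", "_min"))))
  }

  # crude additive estimates
  aromatic_atoms <- if (nb > 0L)
    unique(c(b$i[bo == AROMATIC_BOND], b$j[bo == AROMATIC_BOND])) else integer()
  logp <- sum(tab$logp) + 0.1 * length(aromatic_atoms)
  add(logp_est = logp,
      mr_est = 2.52 * sum(tab$pol) + 0.5 * nb,
      tpsa_est = sum(tab$psa),
      frac_aromatic_atoms = length(aromatic_atoms) / n)

  add(n_branch_atoms = sum(deg >= 3), n_terminal_atoms = sum(deg == 1),
      frac_ring_bonds = if (nb > 0L) ring_bonds / nb else 0,
      bond_order_mean = if (nb > 0L) mean(ifelse(bo == AROMATIC_BOND, 1.5, bo)) else 0)

  out <- .impute_nonfinite(out)
  stopifnot(length(out) == 196L, !anyDuplicated(names(out)))
  structure(out, registry_version = LIGAND_REGISTRY_VERSION)
}

#' The ligand descriptor registry
#'
#' The frozen, ordered list of the 196 ligand descriptor names together with
#' the registry version string stamped into every trained model. The names
#' (and their order) are pinned: two calls always return the identical list.
#'
#' @return A list with elements `names` (character, length 196) and
#'   `version`.
#' @export
descriptor_registry <- function() {
  nms <- get0("registry_names", .pla_env)
  if (is.null(nms)) {
    ref <- new_ligand(
      atoms = data.frame(element = c(rep("C", 6), "O"),
                         x = c(cos(0:5 * pi / 3), 2.5),
                         y = c(sin(0:5 * pi / 3), 0), z = 0,
                         charge = c(rep(0, 6), 0)),
      bonds = data.frame(i = c(1:6, 1), j = c(2:6, 1, 7),
                         order = c(rep(AROMATIC_BOND, 6), 1L)),
      name = "registry-reference")
    nms <- names(ligand_descriptors(ref))
    assign("registry_names", nms, .pla_env)
  }
  list(names = nms, version = LIGAND_REGISTRY_VERSION)
}
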