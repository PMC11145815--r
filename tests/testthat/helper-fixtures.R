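# Shared fixtures: tiny synthetic complexes and hand-built molecules used
# across the suite. Everything is generated in code; no stored data files.

tiny_spec <- function(n = 5L, seed = 11L) {
  synthetic_spec(n_samples = n, pocket_length = c(8L, 14L),
                 ligand_size = c(4L, 9L), seed = seed)
}

tiny_dataset <- function(n = 5L, seed = 11L) generate_dataset(tiny_spec(n, seed))

# a fixed two-ring test molecule with charges and mixed bond orders
benzamidine_like <- function() {
  new_ligand(
    atoms = data.frame(
      element = c(rep("C", 6), "C", "N", "N"),
      x = c(cos(0:5 * pi / 3) * 1.4, 2.9, 3.6, 3.6),
      y = c(sin(0:5 * pi / 3) * 1.4, 0, 1.1, -1.1),
      z = 0,
      charge = c(rep(0, 8), 1)),
    bonds = data.frame(i = c(1:6, 1, 7, 7), j = c(2:6, 1, 7, 8, 9),
                       order = c(rep(4L, 6), 1L, 2L, 1L)),
    name = "benzamidine-like")
}

# subset a pla_features object by sample index
features_subset <- function(f, idx) {
  structure(list(lig = f$lig[idx, , drop = FALSE],
                 poc = f$poc[idx, , drop = FALSE],
                 graphs = f$graphs[idx], labels = f$labels[idx],
                 ids = f$ids[idx], graph_config = f$graph_config),
            class = "pla_features")
}

# a small trained-ish model (random init + identity norm) for forward tests
tiny_model <- function(variant = "LIP", seed = 7L) {
  init_model(model_config(variant = variant,
                          tower_channels = c(4L, 6L, 8L),
                          graph_hidden = 6L, gather_dim = 8L,
                          token_dim = 8L, head_dims = c(10L, 5L),
                          dropout = 0), seed = seed)
}

expect_close <- function(a, b, tol = 1e-8) expect_lt(max(abs(a - b)), tol)
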