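# forward-pass semantics, invariances and gradient correctness of the
# fusion network

test_that("a zeroed descriptor tower maps zero input to a zero token", {
  m <- tiny_model()
  zero <- function(p) rapply(p, function(x) x * 0, how = "replace")
  m$params$lig_tower <- zero(m$params$lig_tower)
  out <- descriptor_tower_forward(numeric(196), m, "ligand")
  expect_close(out, numeric(length(out)), 1e-12)
  expect_error(descriptor_tower_forward(numeric(10), m, "ligand"), "length-196")
  expect_error(descriptor_tower_forward(numeric(196), tiny_model("IP"), "ligand"),
               "no ligand tower")
})

test_that("descriptor towers are deterministic in inference mode", {
  m <- tiny_model()
  v <- rnorm(147)
  expect_identical(descriptor_tower_forward(v, m, "pocket"),
                   descriptor_tower_forward(v, m, "pocket"))
})

test_that("one conv block matches a hand-computed convolution", {
  # length-4 single-channel input, kernel (0, 1, 0) -> identity convolution
  p <- list(W = matrix(c(0, 1, 0), 3, 1), b = 0.5)
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  out <- plafusion:::conv1d_fwd(X, n = 1L, L = 4L, p, k = 3L)
  expect_close(as.numeric(out$Y), c(1, 2, 3, 4) + 0.5, 1e-12)
  # kernel (1, 0, 0) shifts left with zero padding at the boundary
  p2 <- list(W = matrix(c(1, 0, 0), 3, 1), b = 0)
  out2 <- plafusion:::conv1d_fwd(X, n = 1L, L = 4L, p2, k = 3L)
  expect_close(as.numeric(out2$Y), c(0, 1, 2, 3), 1e-12)
})

test_that("a gated step with no edges reduces to a gated update of zero message", {
  h <- 4L
  gru <- with_seed(3, plafusion:::gru_init(h))
  lig <- new_ligand(data.frame(element = c("C", "C"), x = c(0, 20), y = 0, z = 0,
                               charge = 0),
                    data.frame(i = integer(), j = integer(), order = integer()))
  poc <- new_pocket(data.frame(resid = "ALA", chain = "A", resno = 1),
                    data.frame(element = "C", x = 50, y = 0, z = 0, res_index = 1))
  g <- build_complex_graph(new_complex_sample(lig, poc, id = "far"))
  expect_equal(nrow(g$edges), 0L)
  H <- matrix(rnorm(3 * h), 3, h)
  out <- gated_graph_step(g, H, list(), gru)
  want <- plafusion:::gru_fwd(H, matrix(0, 3, h), gru)$Y
  expect_close(out, want, 1e-12)
})

test_that("gated steps are equivariant to node relabeling", {
  s <- tiny_dataset(1, seed = 71)$samples[[1]]
  g <- build_complex_graph(s)
  n <- nrow(g$node_features)
  h <- 5L
  W <- setNames(lapply(plafusion:::EDGE_TYPES, function(t)
    with_seed(match(t, plafusion:::EDGE_TYPES), matrix(rnorm(h * h), h, h))),
    plafusion:::EDGE_TYPES)
  gru <- with_seed(9, plafusion:::gru_init(h))
  H <- matrix(rnorm(n * h), n, h)
  out <- gated_graph_step(g, H, W, gru)
  perm <- with_seed(4, sample(n))
  g2 <- g
  inv <- order(perm)
  g2$node_features <- g$node_features[perm, , drop = FALSE]
  g2$edges$i <- inv[g$edges$i]
  g2$edges$j <- inv[g$edges$j]
  g2$ligand_mask <- g$ligand_mask[perm]
  out2 <- gated_graph_step(g2, H[perm, , drop = FALSE], W, gru)
  expect_close(out2, out[perm, , drop = FALSE], 1e-10)
  expect_error(gated_graph_step(g, H, W, gru, active_types = "wat"), "unknown")
})

test_that("a scalar-width gated step matches a hand computation on a path", {
  # 3-node path 1-2-3, hidden width 1, all weights set by hand
  lig <- new_ligand(data.frame(element = c("C", "C", "C"),
                               x = c(0, 1.5, 3), y = 0, z = 0, charge = 0),
                    data.frame(i = c(1L, 2L), j = c(2L, 3L), order = 1L))
  poc <- new_pocket(data.frame(resid = "ALA", chain = "A", resno = 1),
                    data.frame(element = "C", x = 40, y = 0, z = 0, res_index = 1))
  g <- build_complex_graph(new_complex_sample(lig, poc, id = "path"))
  W <- list("covalent:single" = matrix(2, 1, 1))
  gru <- list(Wz = matrix(0.5, 1, 1), Uz = matrix(0.1, 1, 1), bz = 0,
              Wr = matrix(0.3, 1, 1), Ur = matrix(0.2, 1, 1), br = 0,
              Wc = matrix(1.0, 1, 1), Uc = matrix(0.4, 1, 1), bc = 0)
  H <- matrix(c(1, -1, 0.5, 0), 4, 1)
  out <- gated_graph_step(g, H, W, gru, active_types = "covalent:single")
  # hand: messages m = 2 * sum of neighbor states over the path edges
  m <- c(2 * (-1), 2 * (1 + 0.5), 2 * (-1), 0)
  z <- 1 / (1 + exp(-(0.5 * m + 0.1 * H[, 1])))
  r <- 1 / (1 + exp(-(0.3 * m + 0.2 * H[, 1])))
  cc <- tanh(1.0 * m + 0.4 * (r * H[, 1]))
  expect_close(out[, 1], (1 - z) * H[, 1] + z * cc, 1e-12)
})

test_that("the staged graph network is invariant to atom input order", {
  m <- tiny_model()
  s <- tiny_dataset(1, seed = 81)$samples[[1]]
  g <- build_complex_graph(s)
  out <- potentialnet_forward(g, m)
  expect_length(out, m$config$token_dim)
  # shuffle ligand atoms in the sample and rebuild
  lig <- s$ligand
  perm <- with_seed(2, sample(nrow(lig$atoms)))
  inv <- order(perm)
  lig2 <- new_ligand(lig$atoms[perm, , drop = FALSE],
                     data.frame(i = inv[lig$bonds$i], j = inv[lig$bonds$j],
                                order = lig$bonds$order), lig$name)
  g2 <- build_complex_graph(new_complex_sample(lig2, s$pocket, id = s$id))
  expect_close(potentialnet_forward(g2, m), out, 1e-5)
})

test_that("a graph without ligand nodes is rejected by the gather readout", {
  m <- tiny_model()
  s <- tiny_dataset(1, seed = 82)$samples[[1]]
  g <- build_complex_graph(s)
  g$ligand_mask[] <- FALSE
  expect_error(potentialnet_forward(g, m), "ligand mask")
})

test_that("self-attention weights are softmax rows over modality tokens", {
  m <- tiny_model()
  d <- m$config$token_dim
  tok <- matrix(rnorm(3 * d), 3)
  # identical tokens: every attention row is uniform
  fz <- attention_fusion(tok, tok, tok, model = m)
  for (h in fz$weights) expect_close(as.numeric(h), rep(1 / 3, length(h)), 1e-9)
  # random tokens: rows sum to 1
  fz2 <- attention_fusion(matrix(rnorm(3 * d), 3), matrix(rnorm(3 * d), 3),
                          matrix(rnorm(3 * d), 3), model = m)
  for (h in fz2$weights)
    for (j in 1:3) expect_close(rowSums(matrix(h[, j, ], 3)), rep(1, 3), 1e-6)
  expect_equal(ncol(fz$fused), 3L * d)
  expect_error(attention_fusion(tok, model = m), "at least two")
})

test_that("attention with identity projections matches a hand computation", {
  m <- tiny_model()
  m$config$token_dim <- 2L
  m$params$fusion <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2))
  t1 <- matrix(c(1, 0), 1)
  t2 <- matrix(c(0, 1), 1)
  t3 <- matrix(c(1, 1), 1)
  fz <- attention_fusion(t1, t2, t3, model = m)
  toks <- rbind(t1, t2, t3)
  S <- toks %*% t(toks) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  want <- A %*% toks
  expect_close(fz$fused, matrix(t(want), nrow = 1), 1e-10)
})

test_that("full forward passes are deterministic and order-invariant", {
  m <- tiny_model()
  s <- tiny_dataset(1, seed = 91)$samples[[1]]
  p1 <- fusion_forward(s, m)
  expect_length(p1, 1L)
  expect_true(is.finite(p1))
  expect_identical(fusion_forward(s, m), p1)
  lig <- s$ligand
  perm <- with_seed(5, sample(nrow(lig$atoms)))
  inv <- order(perm)
  lig2 <- new_ligand(lig$atoms[perm, , drop = FALSE],
                     data.frame(i = inv[lig$bonds$i], j = inv[lig$bonds$j],
                                order = lig$bonds$order), lig$name)
  s2 <- new_complex_sample(lig2, s$pocket, label = s$label, id = s$id)
  expect_close(fusion_forward(s2, m), p1, 1e-5)
  expect_error(fusion_forward(s, tiny_model("LP")), "LIP")
})

test_that("ablation variants ignore exactly the removed modality", {
  s <- tiny_dataset(1, seed = 92)$samples[[1]]
  # LP: jittering every coordinate cannot change the prediction
  mlp <- tiny_model("LP")
  base <- ablation_forward("LP", s, mlp)
  jit <- s
  jit$ligand$atoms$x <- jit$ligand$atoms$x + rnorm(nrow(jit$ligand$atoms), 0, 0.2)
  jit$pocket$atoms$y <- jit$pocket$atoms$y + 0.3
  expect_equal(ablation_forward("LP", jit, mlp), base)
  # LI: mutating the pocket sequence with coordinates fixed changes nothing
  mli <- tiny_model("LI")
  base_li <- ablation_forward("LI", s, mli)
  mut <- s
  mut$pocket$residues$resid <- rev(mut$pocket$residues$resid)
  mut$pocket$sequence <- plafusion:::residues_to_sequence(mut$pocket$residues$resid)
  expect_close(ablation_forward("LI", mut, mli), base_li, 1e-9)
  expect_error(ablation_forward("IP", s, mlp), "variant")
})

test_that("ablations are strict parameter subsets of the full model", {
  full <- count_parameters(tiny_model("LIP"))
  for (v in c("LI", "IP", "LP"))
    expect_lt(count_parameters(tiny_model(v)), full)
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(variant = "LIP", tower_channels = c(3L, 4L, 5L),
                      graph_hidden = 4L, gather_dim = 6L, token_dim = 6L,
                      head_dims = c(8L, 4L), dropout = 0)
  m <- init_model(cfg, seed = 13)
  ds <- tiny_dataset(4, seed = 14)
  f <- featurize_samples(ds$samples)
  b <- plafusion:::make_batch(f, m)
  # random smooth inputs avoid pooling ties at kink points
  set.seed(15)
  b$lig <- matrix(rnorm(length(b$lig)), nrow(b$lig))
  b$poc <- matrix(rnorm(length(b$poc)), nrow(b$poc))
  b$y <- rnorm(4, 7, 2)
  fw <- plafusion:::model_forward(m, b, training = TRUE)
  g <- plafusion:::model_backward(m, b, fw$caches,
                                  plafusion:::.smooth_l1_grad(fw$pred, b$y, 1))
  fp <- unlist(m$params)
  fg <- unlist(g)
  expect_length(fg, length(fp))
  lay <- plafusion:::param_layout(m$params)
  loss_at <- function(v) {
    mm <- m
    mm$params <- plafusion:::unflatten_params(v, m$params, lay)
    smooth_l1_loss(plafusion:::model_forward(mm, b, training = TRUE)$pred, b$y, 1)
  }
  idx <- with_seed(16, sample(length(fp), 60))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    up <- fp; up[i] <- up[i] + eps
    dn <- fp; dn[i] <- dn[i] - eps
    (loss_at(up) - loss_at(dn)) / (2 * eps)
  }, 0)
  rel <- abs(num - fg[idx]) / pmax(1e-4, abs(num) + abs(fg[idx]))
  expect_lt(max(rel), 1e-3)
})

test_that("models survive a save/load round trip bit-for-bit in behavior", {
  m <- tiny_model()
  ds <- tiny_dataset(3, seed = 44)
  pred <- predict_affinity(m, ds$samples)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_close(predict_affinity(m2, ds$samples), pred, 1e-6)
  expect_equal(m2$config, m$config)
  expect_equal(m2$registry_version, m$registry_version)
})
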