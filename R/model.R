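#' @include nn.R
NULL

COVALENT_TYPES <- EDGE_TYPES[1:4]

MODEL_VARIANTS <- c("LIP", "LI", "IP", "LP")

# which modality towers each variant carries (L = ligand descriptor tower,
# I = interaction graph network, P = pocket descriptor tower)
variant_modalities <- function(variant) {
  switch(variant,
         LIP = c("L", "I", "P"),
         LI = c("L", "I"),
         IP = c("I", "P"),
         LP = c("L", "P"),
         stop(sprintf("unknown variant '%s'", variant)))
}

#' Model configuration
#'
#' Hyperparameters of the fusion network. The full variant `"LIP"` carries a
#' ligand descriptor tower, an interaction graph network, and a pocket
#' descriptor tower; the ablation variants `"LI"`, `"IP"`, `"LP"` drop the
#' pocket tower, the ligand tower, and the graph respectively, and the
#' self-attention fusion then operates over the two remaining modality
#' tokens.
#'
#' @param variant one of `"LIP"`, `"LI"`, `"IP"`, `"LP"`.
#' @param tower_channels channels of the three conv blocks of each
#'   descriptor tower.
#' @param tower_kernels odd kernel sizes of the three conv blocks.
#' @param graph_hidden hidden width of the gated graph network.
#' @param steps_covalent number of covalent-only gated steps (stage 1).
#' @param steps_full number of all-edge gated steps (stage 2).
#' @param gather_dim output width of the ligand-only gather readout.
#' @param token_dim common width of the modality tokens fed to attention.
#' @param n_heads attention heads (must divide `token_dim`).
#' @param head_dims hidden sizes of the fully connected affinity head.
#' @param dropout dropout rate in the head (training mode only).
#' @param readout `"sum"` (default) or `"mean"` over ligand nodes.
#' @return A list of class `pla_model_config`.
#' @export
model_config <- function(variant = "LIP",
                         tower_channels = c(16L, 32L, 64L),
                         tower_kernels = c(3L, 3L, 3L),
                         graph_hidden = 24L,
                         steps_covalent = 1L, steps_full = 2L,
                         gather_dim = 48L,
                         token_dim = 64L, n_heads = 1L,
                         head_dims = c(128L, 32L), dropout = 0.1,
                         readout = "sum") {
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(length(tower_channels) == 3L, all(tower_channels > 0),
            length(tower_kernels) == 3L, all(tower_kernels %% 2 == 1),
            graph_hidden > 0, steps_covalent >= 1L, steps_full >= 1L,
            gather_dim > 0, token_dim > 0, token_dim %% n_heads == 0,
            length(head_dims) >= 1L, dropout >= 0, dropout < 1,
            readout %in% c("sum", "mean"))
  structure(list(variant = variant,
                 tower_channels = as.integer(tower_channels),
                 tower_kernels = as.integer(tower_kernels),
                 graph_hidden = as.integer(graph_hidden),
                 steps_covalent = as.integer(steps_covalent),
                 steps_full = as.integer(steps_full),
                 gather_dim = as.integer(gather_dim),
                 token_dim = as.integer(token_dim),
                 n_heads = as.integer(n_heads),
                 head_dims = as.integer(head_dims),
                 dropout = dropout, readout = readout),
            class = "pla_model_config")
}

LIG_DIM <- 196L
POC_DIM <- 147L
NODE_DIM <- 19L

.tower_init <- function(input_len, cfg) {
  ch <- cfg$tower_channels
  ks <- cfg$tower_kernels
  cin <- c(1L, ch[1], ch[2])
  p <- list()
  for (b in 1:3) {
    p[[paste0("conv", b)]] <- conv1d_init(cin[b], ch[b], ks[b])
    p[[paste0("bn", b)]] <- batchnorm_init(ch[b])
    p[[paste0("prelu", b)]] <- prelu_init(ch[b])
  }
  p$proj <- linear_init(ch[3], cfg$token_dim)
  p
}

.tower_state_init <- function(cfg) {
  ch <- cfg$tower_channels
  list(bn1 = batchnorm_state_init(ch[1]), bn2 = batchnorm_state_init(ch[2]),
       bn3 = batchnorm_state_init(ch[3]))
}

.graph_init <- function(cfg) {
  h <- cfg$graph_hidden
  msg1 <- setNames(lapply(COVALENT_TYPES, function(t) glorot(h, h)), COVALENT_TYPES)
  msg2 <- setNames(lapply(EDGE_TYPES, function(t) glorot(h, h)), EDGE_TYPES)
  list(embed = linear_init(NODE_DIM, h),
       stage1 = list(msg = msg1, gru = gru_init(h)),
       stage2 = list(msg = msg2, gru = gru_init(h)),
       gather = list(Wi = glorot(2L * h, h), bi = numeric(h),
                     Wj = glorot(h, h), bj = numeric(h),
                     proj = linear_init(h, cfg$gather_dim)),
       token_proj = linear_init(cfg$gather_dim, cfg$token_dim))
}

#' Initialize an untrained model
#'
#' Allocates seeded Glorot-initialized parameters for the configured variant
#' and identity normalization statistics (replaced by training-set statistics
#' in [train_model()]).
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the parameter draw.
#' @return An object of class `pla_model`.
#' @export
init_model <- function(config = model_config(), seed = 0L) {
  stopifnot(inherits(config, "pla_model_config"))
  mods <- variant_modalities(config$variant)
  with_seed(seed, {
    params <- list()
    bn_state <- list()
    if ("L" %in% mods) {
      params$lig_tower <- .tower_init(LIG_DIM, config)
      bn_state$lig_tower <- .tower_state_init(config)
    }
    if ("P" %in% mods) {
      params$poc_tower <- .tower_init(POC_DIM, config)
      bn_state$poc_tower <- .tower_state_init(config)
    }
    if ("I" %in% mods) params$graph <- .graph_init(config)
    params$fusion <- attention_init(config$token_dim)
    m <- length(mods)
    dims <- c(m * config$token_dim, config$head_dims)
    head <- list()
    for (k in seq_along(config$head_dims)) {
      head[[paste0("lin", k)]] <- linear_init(dims[k], dims[k + 1])
      head[[paste0("prelu", k)]] <- prelu_init(dims[k + 1])
    }
    head$out <- linear_init(dims[length(dims)], 1L)
    params$head <- head
    structure(list(config = config, params = params, bn_state = bn_state,
                   norm = list(lig = list(mean = numeric(LIG_DIM), sd = rep(1, LIG_DIM)),
                               poc = list(mean = numeric(POC_DIM), sd = rep(1, POC_DIM))),
                   registry_version = LIGAND_REGISTRY_VERSION,
                   pocket_registry_version = POCKET_REGISTRY_VERSION,
                   graph_recipe_id = GRAPH_RECIPE_ID,
                   seed = as.integer(seed)),
              class = "pla_model")
  })
}

#' @export
print.pla_model <- function(x, ...) {
  cat(sprintf("<pla_model> variant %s, %d parameters, registry %s\n",
              x$config$variant, count_parameters(x), x$registry_version))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a `pla_model`.
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  length(unlist(model$params, use.names = FALSE))
}

# ---- featurization ---------------------------------------------------------

#' Featurize complex samples for the model
#'
#' Computes the 196-element ligand and 147-element pocket descriptor
#' matrices and the per-sample spatial graphs.
#'
#' @param samples list of `pla_complex`.
#' @param config a [graph_config()].
#' @param with_graphs build spatial graphs (skippable for the graph-free
#'   variant).
#' @return A list of class `pla_features` with fields `lig`, `poc`,
#'   `graphs`, `labels`, `ids`.
#' @export
featurize_samples <- function(samples, config = graph_config(),
                              with_graphs = TRUE) {
  n <- length(samples)
  lig <- matrix(0, n, LIG_DIM)
  poc <- matrix(0, n, POC_DIM)
  graphs <- vector("list", n)
  labels <- rep(NA_real_, n)
  ids <- character(n)
  for (k in seq_len(n)) {
    s <- samples[[k]]
    lig[k, ] <- as.numeric(ligand_descriptors(s$ligand))
    poc[k, ] <- as.numeric(pocket_ctd(pocket_sequence(s$pocket)))
    if (with_graphs) graphs[[k]] <- build_complex_graph(s, config)
    if (!is.null(s$label)) labels[k] <- s$label
    ids[k] <- s$id
  }
  colnames(lig) <- descriptor_registry()$names
  colnames(poc) <- names(pocket_ctd("AR"))
  structure(list(lig = lig, poc = poc, graphs = graphs, labels = labels,
                 ids = ids, graph_config = config),
            class = "pla_features")
}

# pool per-sample graphs into one block-diagonal batch: per-edge-type sparse
# adjacency over the pooled node set plus a sparse ligand-readout selector
batch_graphs <- function(graphs, readout = "sum") {
  sizes <- vapply(graphs, function(g) nrow(g$node_features), 0L)
  offs <- cumsum(c(0L, sizes))
  N <- sum(sizes)
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  adj <- list()
  for (t in EDGE_TYPES) {
    ii <- integer(0); jj <- integer(0)
    for (k in seq_along(graphs)) {
      e <- graphs[[k]]$edges
      sel <- e$type == t
      if (any(sel)) {
        ii <- c(ii, e$i[sel] + offs[k])
        jj <- c(jj, e$j[sel] + offs[k])
      }
    }
    adj[[t]] <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, N))
  }
  li <- integer(0); ls <- integer(0)
  for (k in seq_along(graphs)) {
    lig_nodes <- which(graphs[[k]]$ligand_mask)
    li <- c(li, lig_nodes + offs[k])
    ls <- c(ls, rep(k, length(lig_nodes)))
  }
  w <- if (readout == "mean") {
    cnt <- table(factor(ls, levels = seq_along(graphs)))
    1 / as.numeric(cnt)[ls]
  } else rep(1, length(ls))
  S <- Matrix::sparseMatrix(i = ls, j = li, x = w,
                            dims = c(length(graphs), N))
  list(X = X, adj = adj, S = S, n_graphs = length(graphs), n_nodes = N)
}

# ---- forward / backward ----------------------------------------------------

.tower_forward <- function(X, p, st, cfg, training) {
  n <- nrow(X)
  L <- ncol(X)
  ks <- cfg$tower_kernels
  cur <- matrix(as.vector(t(X)), ncol = 1L)
  cache <- list(n = n, L0 = L)
  new_st <- st
  for (b in 1:3) {
    cv <- conv1d_fwd(cur, n, L, p[[paste0("conv", b)]], ks[b])
    bn <- batchnorm_fwd(cv$Y, p[[paste0("bn", b)]], st[[paste0("bn", b)]], training)
    pr <- prelu_fwd(bn$Y, p[[paste0("prelu", b)]])
    mp <- maxpool2_fwd(pr$Y, n, L)
    cache[[paste0("conv", b)]] <- cv$cache
    cache[[paste0("bn", b)]] <- bn$cache
    cache[[paste0("prelu", b)]] <- pr$cache
    cache[[paste0("pool", b)]] <- mp$cache
    cache[[paste0("L", b)]] <- L
    new_st[[paste0("bn", b)]] <- bn$new_state
    cur <- mp$Y
    L <- mp$Lout
  }
  gp <- meanpool_fwd(cur, n, L)
  pj <- linear_fwd(gp$Y, p$proj)
  cache$gpool <- gp$cache
  cache$proj <- pj$cache
  list(Y = pj$Y, cache = cache, new_state = new_st)
}

.tower_backward <- function(dY, p, cfg, cache) {
  ks <- cfg$tower_kernels
  grads <- list()
  pj <- linear_bwd(dY, p$proj, cache$proj)
  grads$proj <- pj$grads
  cur <- meanpool_bwd(pj$dX, cache$gpool)
  for (b in 3:1) {
    cur <- maxpool2_bwd(cur, cache[[paste0("pool", b)]])
    pr <- prelu_bwd(cur, p[[paste0("prelu", b)]], cache[[paste0("prelu", b)]])
    bn <- batchnorm_bwd(pr$dX, p[[paste0("bn", b)]], cache[[paste0("bn", b)]])
    cv <- conv1d_bwd(bn$dX, p[[paste0("conv", b)]], cache[[paste0("conv", b)]], ks[b])
    grads[[paste0("prelu", b)]] <- pr$grads
    grads[[paste0("bn", b)]] <- bn$grads
    grads[[paste0("conv", b)]] <- cv$grads
    cur <- cv$dX
  }
  grads[order(match(names(grads), names(p)))]
}

# one gated message-passing stage over the pooled batch graph
.stage_forward <- function(H, adj, stage_p, active_types, steps) {
  caches <- vector("list", steps)
  for (s in seq_len(steps)) {
    M <- NULL
    for (t in active_types) {
      Mt <- adj[[t]] %*% (H %*% stage_p$msg[[t]])
      M <- if (is.null(M)) Mt else M + Mt
    }
    M <- as.matrix(M)
    g <- gru_fwd(H, M, stage_p$gru)
    caches[[s]] <- list(H_in = H, gru = g$cache)
    H <- g$Y
  }
  list(H = H, caches = caches)
}

.stage_backward <- function(dH, adj, stage_p, active_types, caches) {
  msg_g <- lapply(stage_p$msg, function(W) W * 0)
  gru_g <- grad_zero(stage_p$gru)
  for (s in rev(seq_along(caches))) {
    cc <- caches[[s]]
    gb <- gru_bwd(dH, stage_p$gru, cc$gru)
    gru_g <- grad_add(gru_g, gb$grads)
    dM <- gb$dM
    dH <- gb$dH
    for (t in active_types) {
      dP <- as.matrix(Matrix::crossprod(adj[[t]], dM))
      dH <- dH + dP %*% t(stage_p$msg[[t]])
      msg_g[[t]] <- msg_g[[t]] + crossprod(cc$H_in, dP)
    }
  }
  list(dH = dH, grads = list(msg = msg_g, gru = gru_g))
}

.graph_forward <- function(batch, p, cfg) {
  emb <- linear_fwd(batch$X, p$embed)
  H0 <- tanh(emb$Y)
  s1 <- .stage_forward(H0, batch$adj, p$stage1, COVALENT_TYPES, cfg$steps_covalent)
  s2 <- .stage_forward(s1$H, batch$adj, p$stage2, EDGE_TYPES, cfg$steps_full)
  HK <- s2$H
  gin <- cbind(HK, H0)
  Araw <- cpp_addrow(gin %*% p$gather$Wi, p$gather$bi)
  A <- sigmoid(Araw)
  Braw <- cpp_addrow(HK %*% p$gather$Wj, p$gather$bj)
  B <- tanh(Braw)
  U <- A * B
  R <- as.matrix(batch$S %*% U)
  pj <- linear_fwd(R, p$gather$proj)
  G <- tanh(pj$Y)
  tk <- linear_fwd(G, p$token_proj)
  list(Y = tk$Y,
       cache = list(emb = emb$cache, H0 = H0, s1 = s1, s2 = s2, HK = HK,
                    gin = gin, A = A, B = B, U = U, R = R, pj = pj$cache,
                    G = G, tk = tk$cache))
}

.graph_backward <- function(dY, batch, p, cfg, cache) {
  tk <- linear_bwd(dY, p$token_proj, cache$tk)
  dG <- tk$dX * (1 - cache$G^2)
  pj <- linear_bwd(dG, p$gather$proj, cache$pj)
  dU <- as.matrix(Matrix::t(batch$S) %*% pj$dX)
  dA <- dU * cache$B
  dB <- dU * cache$A
  dAraw <- dA * cache$A * (1 - cache$A)
  dBraw <- dB * (1 - cache$B^2)
  dgin <- dAraw %*% t(p$gather$Wi)
  dHK <- dBraw %*% t(p$gather$Wj) + dgin[, seq_len(cfg$graph_hidden), drop = FALSE]
  dH0_gather <- dgin[, cfg$graph_hidden + seq_len(cfg$graph_hidden), drop = FALSE]
  gather_g <- list(Wi = crossprod(cache$gin, dAraw), bi = colSums(dAraw),
                   Wj = crossprod(cache$HK, dBraw), bj = colSums(dBraw),
                   proj = pj$grads)
  s2 <- .stage_backward(dHK, batch$adj, p$stage2, EDGE_TYPES, cache$s2$caches)
  s1 <- .stage_backward(s2$dH, batch$adj, p$stage1, COVALENT_TYPES,
                        cache$s1$caches)
  dH0 <- s1$dH + dH0_gather
  demb <- dH0 * (1 - cache$H0^2)
  emb <- linear_bwd(demb, p$embed, cache$emb)
  list(grads = list(embed = emb$grads, stage1 = s1$grads, stage2 = s2$grads,
                    gather = gather_g, token_proj = tk$grads))
}

# full forward over a prepared batch; returns predictions, caches and
# updated batch-norm state
model_forward <- function(model, batch, training = FALSE) {
  cfg <- model$config
  p <- model$params
  mods <- variant_modalities(cfg$variant)
  tokens <- list()
  caches <- list()
  new_bn <- model$bn_state
  if ("L" %in% mods) {
    tw <- .tower_forward(batch$lig, p$lig_tower, model$bn_state$lig_tower,
                         cfg, training)
    tokens$L <- tw$Y
    caches$lig_tower <- tw$cache
    new_bn$lig_tower <- tw$new_state
  }
  if ("I" %in% mods) {
    gf <- .graph_forward(batch$graph, p$graph, cfg)
    tokens$I <- gf$Y
    caches$graph <- gf$cache
  }
  if ("P" %in% mods) {
    tw <- .tower_forward(batch$poc, p$poc_tower, model$bn_state$poc_tower,
                         cfg, training)
    tokens$P <- tw$Y
    caches$poc_tower <- tw$cache
    new_bn$poc_tower <- tw$new_state
  }
  tokens <- tokens[mods]
  att <- attention_fwd(tokens, p$fusion, cfg$n_heads)
  fused <- do.call(cbind, att$O)
  caches$att <- att$cache
  cur <- fused
  caches$fused <- fused
  hc <- list()
  for (k in seq_along(cfg$head_dims)) {
    ln <- linear_fwd(cur, p$head[[paste0("lin", k)]])
    pr <- prelu_fwd(ln$Y, p$head[[paste0("prelu", k)]])
    dp <- dropout_fwd(pr$Y, cfg$dropout, training)
    hc[[paste0("lin", k)]] <- ln$cache
    hc[[paste0("prelu", k)]] <- pr$cache
    hc[[paste0("drop", k)]] <- dp$cache
    cur <- dp$Y
  }
  out <- linear_fwd(cur, p$head$out)
  hc$out <- out$cache
  caches$head <- hc
  list(pred = as.numeric(out$Y), caches = caches, new_bn_state = new_bn,
       fused = fused, attention = att$A)
}

model_backward <- function(model, batch, caches, dpred) {
  cfg <- model$config
  p <- model$params
  mods <- variant_modalities(cfg$variant)
  grads <- list()
  cur <- matrix(dpred, ncol = 1L)
  hg <- list()
  out <- linear_bwd(cur, p$head$out, caches$head$out)
  cur <- out$dX
  for (k in rev(seq_along(cfg$head_dims))) {
    cur <- dropout_bwd(cur, caches$head[[paste0("drop", k)]])
    pr <- prelu_bwd(cur, p$head[[paste0("prelu", k)]],
                    caches$head[[paste0("prelu", k)]])
    ln <- linear_bwd(pr$dX, p$head[[paste0("lin", k)]],
                     caches$head[[paste0("lin", k)]])
    hg[[paste0("prelu", k)]] <- pr$grads
    hg[[paste0("lin", k)]] <- ln$grads
    cur <- ln$dX
  }
  hg$out <- out$grads
  grads$head <- hg[order(match(names(hg), names(p$head)))]
  d <- cfg$token_dim
  m <- length(mods)
  dO <- lapply(seq_len(m), function(j)
    cur[, (j - 1L) * d + seq_len(d), drop = FALSE])
  att <- attention_bwd(dO, p$fusion, caches$att)
  grads$fusion <- att$grads
  dT <- setNames(att$dT, mods)
  if ("L" %in% mods)
    grads$lig_tower <- .tower_backward(dT$L, p$lig_tower, cfg, caches$lig_tower)
  if ("P" %in% mods)
    grads$poc_tower <- .tower_backward(dT$P, p$poc_tower, cfg, caches$poc_tower)
  if ("I" %in% mods)
    grads$graph <- .graph_backward(dT$I, batch$graph, p$graph, cfg,
                                   caches$graph)$grads
  grads[order(match(names(grads), names(p)))]
}

# ---- batch preparation -----------------------------------------------------

.apply_norm <- function(X, nm) sweep(sweep(X, 2, nm$mean), 2, nm$sd, `/`)

# assemble a normalized forward-ready batch from featurized samples
make_batch <- function(features, model, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(features$lig))
  mods <- variant_modalities(model$config$variant)
  b <- list(idx = idx, y = features$labels[idx])
  if ("L" %in% mods) b$lig <- .apply_norm(features$lig[idx, , drop = FALSE],
                                          model$norm$lig)
  if ("P" %in% mods) b$poc <- .apply_norm(features$poc[idx, , drop = FALSE],
                                          model$norm$poc)
  if ("I" %in% mods) b$graph <- batch_graphs(features$graphs[idx],
                                             model$config$readout)
  b
}

# ---- prediction and the operation surface ----------------------------------

#' Predict binding affinity
#'
#' Runs the trained model in inference mode (dropout off, batch-norm on its
#' running statistics) over complex samples or precomputed features.
#'
#' @param model a `pla_model`.
#' @param samples list of `pla_complex`, or a `pla_features` object.
#' @return Numeric vector of predicted pK values.
#' @export
predict_affinity <- function(model, samples) {
  stopifnot(inherits(model, "pla_model"))
  features <- if (inherits(samples, "pla_features")) samples
              else featurize_samples(samples,
                                     with_graphs = "I" %in% variant_modalities(model$config$variant))
  batch <- make_batch(features, model)
  model_forward(model, batch, training = FALSE)$pred
}

#' Forward pass of the full fusion model on one sample
#'
#' @param sample a `pla_complex`.
#' @param model a `pla_model` with variant `"LIP"`.
#' @return Predicted pK (single finite scalar).
#' @export
fusion_forward <- function(sample, model) {
  stopifnot(model$config$variant == "LIP")
  predict_affinity(model, list(sample))
}

#' Forward pass of an ablation variant on one sample
#'
#' @param variant `"LI"` (no pocket tower), `"IP"` (no ligand tower) or
#'   `"LP"` (no interaction graph).
#' @param sample a `pla_complex`.
#' @param model a `pla_model` whose config matches `variant`.
#' @return Predicted pK.
#' @export
ablation_forward <- function(variant, sample, model) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (model$config$variant != variant)
    stop(sprintf("model variant is '%s' but '%s' requested",
                 model$config$variant, variant))
  predict_affinity(model, list(sample))
}

#' Descriptor tower forward pass
#'
#' Encodes one normalized descriptor vector through the three
#' conv/batch-norm/PReLU blocks (each followed by width-2 max pooling), mean
#' pooling and the token projection of the given tower. Inference mode.
#'
#' @param vector numeric descriptor vector (length 196 for `"ligand"`, 147
#'   for `"pocket"`).
#' @param model a `pla_model` carrying the requested tower.
#' @param which `"ligand"` or `"pocket"`.
#' @return Numeric token vector of length `token_dim`.
#' @export
descriptor_tower_forward <- function(vector, model, which = c("ligand", "pocket")) {
  which <- match.arg(which)
  tower <- if (which == "ligand") "lig_tower" else "poc_tower"
  want <- if (which == "ligand") LIG_DIM else POC_DIM
  if (length(vector) != want)
    stop(sprintf("expected a length-%d descriptor vector, got %d",
                 want, length(vector)))
  if (is.null(model$params[[tower]]))
    stop(sprintf("model variant '%s' has no %s tower", model$config$variant, which))
  X <- matrix(as.numeric(vector), 1L)
  as.numeric(.tower_forward(X, model$params[[tower]], model$bn_state[[tower]],
                            model$config, training = FALSE)$Y)
}

#' One gated graph message-passing step
#'
#' Aggregates, for every node, the messages `W_t h_j` over its neighbors `j`
#' through the active edge types `t`, then applies a GRU-style gated update.
#' Nodes with no active edges receive a zero message and still pass through
#' the gate.
#'
#' @param graph a `pla_graph`.
#' @param node_states numeric matrix (nodes x hidden).
#' @param edge_type_params named list of hidden x hidden message matrices,
#'   one per active edge type.
#' @param gru_params a GRU parameter list (`Wz`, `Uz`, `bz`, `Wr`, `Ur`,
#'   `br`, `Wc`, `Uc`, `bc`).
#' @param active_types character vector of edge types to propagate.
#' @return Updated node-state matrix.
#' @export
gated_graph_step <- function(graph, node_states, edge_type_params, gru_params,
                             active_types = EDGE_TYPES) {
  stopifnot(inherits(graph, "pla_graph"))
  unknown <- setdiff(active_types, EDGE_TYPES)
  if (length(unknown) > 0L)
    stop(sprintf("unknown edge type(s): %s", paste(unknown, collapse = ", ")))
  missing <- setdiff(intersect(active_types, unique(graph$edges$type)),
                     names(edge_type_params))
  if (length(missing) > 0L)
    stop(sprintf("no message parameters for edge type(s): %s",
                 paste(missing, collapse = ", ")))
  n <- nrow(node_states)
  M <- matrix(0, n, ncol(node_states))
  for (t in intersect(active_types, unique(graph$edges$type))) {
    e <- graph$edges[graph$edges$type == t, , drop = FALSE]
    A <- Matrix::sparseMatrix(i = e$i, j = e$j, x = 1, dims = c(n, n))
    M <- M + as.matrix(A %*% (node_states %*% edge_type_params[[t]]))
  }
  gru_fwd(node_states, M, gru_params)$Y
}

#' Staged gated-graph interaction features of one complex
#'
#' Stage 1 runs covalent-only gated steps, stage 2 runs gated steps over all
#' edge types (covalent + non-covalent), stage 3 gathers a learned per-node
#' embedding summed over the ligand-masked nodes and projects it to the
#' declared output width. Inference mode.
#'
#' @param graph a `pla_graph` with at least one ligand node.
#' @param model a `pla_model` carrying the graph network.
#' @return Numeric interaction token of length `token_dim`.
#' @export
potentialnet_forward <- function(graph, model) {
  stopifnot(inherits(graph, "pla_graph"))
  if (!any(graph$ligand_mask))
    stop("ligand mask is empty: graph has no ligand nodes")
  if (is.null(model$params$graph))
    stop(sprintf("model variant '%s' has no graph network", model$config$variant))
  batch <- batch_graphs(list(graph), model$config$readout)
  as.numeric(.graph_forward(batch, model$params$graph, model$config)$Y)
}

#' Self-attention fusion of modality features
#'
#' Treats the local feature vectors as tokens, applies scaled dot-product
#' self-attention over them and returns the flattened attended tokens (the
#' global feature fed to the affinity head) together with the attention
#' weights (rows sum to 1).
#'
#' @param ligand_feat,pocket_feat,interaction_feat numeric token vectors (or
#'   matrices with one row per sample) of the model's token width; pass
#'   `NULL` for modalities absent from the variant.
#' @param model a `pla_model` (its fusion parameters are used).
#' @return A list with `fused` (matrix, samples x m*token_dim) and `weights`
#'   (per head, samples x m x m arrays).
#' @export
attention_fusion <- function(ligand_feat = NULL, interaction_feat = NULL,
                             pocket_feat = NULL, model) {
  feats <- list(L = ligand_feat, I = interaction_feat, P = pocket_feat)
  feats <- feats[!vapply(feats, is.null, TRUE)]
  if (length(feats) < 2L) stop("attention fusion needs at least two tokens")
  tokens <- lapply(feats, function(f) {
    f <- if (is.matrix(f)) f else matrix(f, 1L)
    if (ncol(f) != model$config$token_dim)
      stop(sprintf("token width %d does not match model token_dim %d",
                   ncol(f), model$config$token_dim))
    f
  })
  att <- attention_fwd(tokens, model$params$fusion, model$config$n_heads)
  list(fused = do.call(cbind, att$O), weights = att$A)
}

#' Extract fused global features
#'
#' Returns the post-attention flattened token matrix (the model's global
#' features, as visualized by 2D projection) for a set of samples.
#'
#' @param model a `pla_model`.
#' @param samples list of `pla_complex` or a `pla_features`.
#' @return Matrix (samples x m*token_dim).
#' @export
extract_global_features <- function(model, samples) {
  features <- if (inherits(samples, "pla_features")) samples
              else featurize_samples(samples,
                                     with_graphs = "I" %in% variant_modalities(model$config$variant))
  batch <- make_batch(features, model)
  model_forward(model, batch, training = FALSE)$fused
}

# ---- serialization ---------------------------------------------------------

.listify <- function(x) {
  if (is.list(x)) return(lapply(x, .listify))
  if (is.matrix(x)) return(list(.dim = dim(x), .data = as.numeric(x)))
  x
}

.unlistify <- function(x) {
  if (is.list(x)) {
    if (!is.null(x$.dim))
      return(matrix(as.numeric(x$.data), x$.dim[1], x$.dim[2]))
    return(lapply(x, .unlistify))
  }
  x
}

#' Save a model to a JSON archive
#'
#' Serializes config, parameters, normalization statistics, batch-norm
#' running statistics and registry/recipe versions at full precision;
#' [load_model()] restores a model whose predictions match to 1e-6.
#'
#' @param model a `pla_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pla_model"))
  obj <- list(format = "plafusion-model-1", config = unclass(model$config),
              params = .listify(model$params), bn_state = .listify(model$bn_state),
              norm = model$norm, registry_version = model$registry_version,
              pocket_registry_version = model$pocket_registry_version,
              graph_recipe_id = model$graph_recipe_id, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model archive
#'
#' @param path path written by [save_model()].
#' @return A `pla_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(obj$format) || obj$format != "plafusion-model-1")
    stop("not a plafusion model archive")
  cfg <- obj$config
  config <- model_config(variant = cfg$variant, tower_channels = cfg$tower_channels,
                         tower_kernels = cfg$tower_kernels,
                         graph_hidden = cfg$graph_hidden,
                         steps_covalent = cfg$steps_covalent,
                         steps_full = cfg$steps_full, gather_dim = cfg$gather_dim,
                         token_dim = cfg$token_dim, n_heads = cfg$n_heads,
                         head_dims = cfg$head_dims, dropout = cfg$dropout,
                         readout = cfg$readout)
  if (obj$registry_version != LIGAND_REGISTRY_VERSION)
    warning(sprintf("model was trained with descriptor registry %s; this build uses %s",
                    obj$registry_version, LIGAND_REGISTRY_VERSION))
  structure(list(config = config, params = .unlistify(obj$params),
                 bn_state = .unlistify(obj$bn_state),
                 norm = lapply(obj$norm, function(nm)
                   list(mean = as.numeric(nm$mean), sd = as.numeric(nm$sd))),
                 registry_version = obj$registry_version,
                 pocket_registry_version = obj$pocket_registry_version,
                 graph_recipe_id = obj$graph_recipe_id,
                 seed = as.integer(obj$seed)),
            class = "pla_model")
}
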