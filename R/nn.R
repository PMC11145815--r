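#' @include synthetic_data.R
NULL

# Minimal dense neural-network primitives with hand-written reverse-mode
# gradients, sized for desk-scale models. Sequence tensors use a
# sample-major flat layout: a (n_samples * seq_len) x channels matrix whose
# row (i-1)*L + l holds sample i, position l. All forwards return a cache
# consumed by the matching backward.

sigmoid <- function(x) 1 / (1 + exp(-x))

# fast row-broadcast: add / multiply a length-ncol vector into every row
addrow <- function(X, v) X + rep(v, each = nrow(X))
mulrow <- function(X, v) X * rep(v, each = nrow(X))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# ---- linear ----------------------------------------------------------------

linear_init <- function(nin, nout) list(W = glorot(nin, nout), b = numeric(nout))

linear_fwd <- function(X, p) {
  list(Y = cpp_addrow(X %*% p$W, p$b), cache = list(X = X))
}

linear_bwd <- function(dY, p, cache) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

# ---- 1D convolution (odd kernel, stride 1, zero 'same' padding) ------------

conv1d_init <- function(cin, cout, k) {
  lim <- sqrt(6 / (k * cin + cout))
  list(W = matrix(runif(k * cin * cout, -lim, lim), k * cin, cout),
       b = numeric(cout))
}

# row-index map for kernel offset `rel`: source row feeding each output row,
# NA where the receptive field falls off the sequence
.conv_index <- function(n, L, rel) {
  l <- rep(seq_len(L), times = n) + rel
  base <- rep((seq_len(n) - 1L) * L, each = L)
  src <- base + l
  src[l < 1L | l > L] <- NA_integer_
  src
}

conv1d_fwd <- function(X, n, L, p, k) {
  cin <- ncol(X)
  half <- (k - 1L) %/% 2L
  key <- sprintf("conv|%d|%d|%d", n, L, k)
  idx <- get0(key, .pla_env)
  if (is.null(idx)) {
    # 1-based source row per (output row, kernel offset); 0 marks padding
    idx <- vapply(seq_len(k), function(o) {
      src <- .conv_index(n, L, o - 1L - half)
      src[is.na(src)] <- 0L
      src
    }, integer(n * L))
    assign(key, idx, .pla_env)
  }
  Xcol <- cpp_im2col(X, idx)
  Y <- cpp_addrow(Xcol %*% p$W, p$b)
  list(Y = Y, cache = list(Xcol = Xcol, idx = idx, cin = cin, nrow_X = nrow(X)))
}

conv1d_bwd <- function(dY, p, cache, k) {
  dXcol <- dY %*% t(p$W)
  list(dX = cpp_col2im(dXcol, cache$idx, cache$nrow_X, cache$cin),
       grads = list(W = crossprod(cache$Xcol, dY), b = colSums(dY)))
}

# ---- batch normalization (per channel over all rows) -----------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

batchnorm_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# running statistics are model state, not trainable parameters
batchnorm_state_init <- function(c) list(mean = numeric(c), var = rep(1, c))

batchnorm_fwd <- function(X, p, state, training) {
  f <- cpp_bn_fwd(X, p$gamma, p$beta, state$mean, state$var, training, BN_EPS)
  new_state <- state
  if (training)
    new_state <- list(mean = (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * f$mu,
                      var = (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * f$va)
  list(Y = f$Y, cache = list(Xhat = f$Xhat, inv = f$inv, training = training),
       new_state = new_state)
}

batchnorm_bwd <- function(dY, p, cache) {
  b <- cpp_bn_bwd(dY, p$gamma, cache$Xhat, cache$inv, cache$training)
  list(dX = b$dX, grads = list(gamma = b$dgamma, beta = b$dbeta))
}

# ---- PReLU (learnable per-channel negative slope) --------------------------

prelu_init <- function(c) list(a = rep(0.25, c))

prelu_fwd <- function(X, p) {
  list(Y = cpp_prelu_fwd(X, p$a), cache = list(X = X))
}

prelu_bwd <- function(dY, p, cache) {
  b <- cpp_prelu_bwd(dY, cache$X, p$a)
  list(dX = b$dX, grads = list(a = b$da))
}

# ---- max pooling, width/stride 2 -------------------------------------------

maxpool2_fwd <- function(X, n, L) {
  Lout <- (L + 1L) %/% 2L
  pos1 <- 2L * seq_len(Lout) - 1L
  pos2 <- pmin(pos1 + 1L, L)
  base_in <- rep((seq_len(n) - 1L) * L, each = Lout)
  r1 <- base_in + rep(pos1, times = n)
  r2 <- base_in + rep(pos2, times = n)
  f <- cpp_maxpool_fwd(X, r1, r2)
  list(Y = f$Y, Lout = Lout,
       cache = list(r1 = r1, r2 = r2, take1 = f$take1, nrow_X = nrow(X)))
}

maxpool2_bwd <- function(dY, cache) {
  cpp_maxpool_bwd(dY, cache$take1, cache$r1, cache$r2, cache$nrow_X)
}

# ---- mean pooling over all positions ---------------------------------------

meanpool_fwd <- function(X, n, L) {
  grp <- rep(seq_len(n), each = L)
  list(Y = rowsum(X, grp) / L, cache = list(n = n, L = L))
}

meanpool_bwd <- function(dY, cache) {
  dY[rep(seq_len(cache$n), each = cache$L), , drop = FALSE] / cache$L
}

# ---- dropout ---------------------------------------------------------------

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, cache = NULL))
  mask <- matrix(runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(Y = X * mask, cache = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# ---- GRU-style gated update ------------------------------------------------

gru_init <- function(h) {
  list(Wz = glorot(h, h), Uz = glorot(h, h), bz = numeric(h),
       Wr = glorot(h, h), Ur = glorot(h, h), br = numeric(h),
       Wc = glorot(h, h), Uc = glorot(h, h), bc = numeric(h))
}

gru_fwd <- function(H, M, p) {
  g <- cpp_gru_gates(M %*% p$Wz + H %*% p$Uz, M %*% p$Wr + H %*% p$Ur,
                     p$bz, p$br, H)
  o <- cpp_gru_out(M %*% p$Wc + g$RH %*% p$Uc, p$bc, H, g$Z)
  list(Y = o$Hn, cache = list(H = H, M = M, Z = g$Z, R = g$R, RH = g$RH,
                              C = o$C))
}

gru_bwd <- function(dHn, p, cache) {
  H <- cache$H; M <- cache$M
  b1 <- cpp_gru_bwd1(dHn, H, cache$Z, cache$C)
  dGc <- b1$dGc; dGz <- b1$dGz
  dRH <- dGc %*% t(p$Uc)
  b2 <- cpp_gru_bwd2(dRH, H, cache$R)
  dGr <- b2$dGr
  dM <- dGc %*% t(p$Wc) + dGr %*% t(p$Wr) + dGz %*% t(p$Wz)
  dH <- b1$dH + b2$dH2 + dGr %*% t(p$Ur) + dGz %*% t(p$Uz)
  list(dH = dH, dM = dM,
       grads = list(Wz = crossprod(M, dGz), Uz = crossprod(H, dGz), bz = colSums(dGz),
                    Wr = crossprod(M, dGr), Ur = crossprod(H, dGr), br = colSums(dGr),
                    Wc = crossprod(M, dGc), Uc = crossprod(cache$RH, dGc),
                    bc = colSums(dGc)))
}

# ---- scaled dot-product self-attention over modality tokens ----------------

attention_init <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d))
}

# tokens: list of m matrices (n x d); returns list O of m attended tokens and
# the attention weights (list over query token of n x m matrices)
attention_fwd <- function(tokens, p, n_heads = 1L) {
  m <- length(tokens)
  d <- ncol(tokens[[1]])
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  Q <- lapply(tokens, function(t) t %*% p$Wq)
  K <- lapply(tokens, function(t) t %*% p$Wk)
  V <- lapply(tokens, function(t) t %*% p$Wv)
  n <- nrow(tokens[[1]])
  O <- lapply(seq_len(m), function(j) matrix(0, n, d))
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- array(0, c(n, m, m))
    for (j in seq_len(m)) for (k in seq_len(m))
      S[, j, k] <- rowSums(Q[[j]][, cols, drop = FALSE] *
                             K[[k]][, cols, drop = FALSE]) / sqrt(dh)
    Ah <- array(0, c(n, m, m))
    for (j in seq_len(m)) {
      e <- exp(S[, j, , drop = FALSE] - apply(S[, j, , drop = FALSE], 1, max))
      Ah[, j, ] <- e / rowSums(matrix(e, n, m))
    }
    for (j in seq_len(m)) for (k in seq_len(m))
      O[[j]][, cols] <- O[[j]][, cols, drop = FALSE] +
        Ah[, j, k] * V[[k]][, cols, drop = FALSE]
    A[[h]] <- Ah
  }
  list(O = O, A = A,
       cache = list(tokens = tokens, Q = Q, K = K, V = V, A = A, m = m, d = d,
                    dh = dh, n_heads = n_heads, n = n))
}

attention_bwd <- function(dO, p, cache) {
  m <- cache$m; dh <- cache$dh; n <- cache$n
  Q <- cache$Q; K <- cache$K; V <- cache$V
  A <- cache$A
  dQ <- lapply(seq_len(m), function(j) matrix(0, n, cache$d))
  dK <- dQ; dV <- dQ
  for (h in seq_len(cache$n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- A[[h]]
    dA <- array(0, c(n, m, m))
    for (j in seq_len(m)) for (k in seq_len(m)) {
      dV[[k]][, cols] <- dV[[k]][, cols, drop = FALSE] +
        Ah[, j, k] * dO[[j]][, cols, drop = FALSE]
      dA[, j, k] <- rowSums(dO[[j]][, cols, drop = FALSE] *
                              V[[k]][, cols, drop = FALSE])
    }
    for (j in seq_len(m)) {
      Aj <- matrix(Ah[, j, ], n, m)
      dAj <- matrix(dA[, j, ], n, m)
      dS <- Aj * (dAj - rowSums(Aj * dAj))
      for (k in seq_len(m)) {
        dQ[[j]][, cols] <- dQ[[j]][, cols, drop = FALSE] +
          dS[, k] * K[[k]][, cols, drop = FALSE] / sqrt(dh)
        dK[[k]][, cols] <- dK[[k]][, cols, drop = FALSE] +
          dS[, k] * Q[[j]][, cols, drop = FALSE] / sqrt(dh)
      }
    }
  }
  dW <- list(Wq = 0, Wk = 0, Wv = 0)
  dT <- vector("list", m)
  for (j in seq_len(m)) {
    t_j <- cache$tokens[[j]]
    dW$Wq <- dW$Wq + crossprod(t_j, dQ[[j]])
    dW$Wk <- dW$Wk + crossprod(t_j, dK[[j]])
    dW$Wv <- dW$Wv + crossprod(t_j, dV[[j]])
    dT[[j]] <- dQ[[j]] %*% t(p$Wq) + dK[[j]] %*% t(p$Wk) + dV[[j]] %*% t(p$Wv)
  }
  list(dT = dT, grads = dW)
}

# ---- parameter-tree utilities ----------------------------------------------

# recursively add two parameter trees (NULL treated as zero)
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    out <- a
    for (nm in names(b)) out[[nm]] <- grad_add(a[[nm]], b[[nm]])
    return(out)
  }
  a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, grad_scale, s = s))
  a * s
}

# zero tree with the same shapes
grad_zero <- function(p) grad_scale(p, 0)

# precompute the leaf layout of a parameter tree so flatten/unflatten are
# cheap loops instead of recursive relist() calls
param_layout <- function(params) {
  leaves <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], c(path, nm))
    } else {
      leaves[[length(leaves) + 1L]] <<- list(path = path, dim = dim(x),
                                             len = length(x))
    }
  }
  walk(params, character())
  off <- cumsum(c(0L, vapply(leaves, `[[`, 0L, "len")))
  list(leaves = leaves, offsets = off, total = off[length(off)])
}

flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(vec, skeleton, layout) {
  out <- skeleton
  for (k in seq_along(layout$leaves)) {
    lf <- layout$leaves[[k]]
    v <- vec[(layout$offsets[k] + 1L):layout$offsets[k + 1L]]
    if (!is.null(lf$dim)) dim(v) <- lf$dim
    out[[lf$path]] <- v
  }
  out
}

adam_init <- function(params) {
  n <- length(flatten_params(params))
  list(m = numeric(n), v = numeric(n), t = 0L,
       layout = param_layout(params))
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- cpp_adam(flatten_params(params), flatten_params(grads),
                  state$m, state$v, state$t, lr, beta1, beta2, eps)
  state$m <- upd$m
  state$v <- upd$v
  list(params = unflatten_params(upd$p, params, state$layout), state = state)
}
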