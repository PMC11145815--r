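#' @include model.R
NULL

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr_decay multiplicative per-epoch learning-rate decay factor.
#' @param clip_norm global gradient-norm clip (Inf disables).
#' @param beta smooth L1 transition point (pK units).
#' @param seed seed controlling initialization, batching and dropout.
#' @param val_fraction validation fraction used by [split_train_val()].
#' @return A list of class `pla_train_config`.
#' @export
train_config <- function(learning_rate = 2e-3, batch_size = 100L,
                         max_epochs = 100L, patience = 25L, lr_decay = 0.98,
                         clip_norm = 5, beta = 1, seed = 0L,
                         val_fraction = 0.2) {
  stopifnot(learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
            patience >= 1L, beta > 0, val_fraction > 0, val_fraction < 1,
            lr_decay > 0, lr_decay <= 1, clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr_decay = lr_decay,
                 clip_norm = clip_norm, beta = beta, seed = as.integer(seed),
                 val_fraction = val_fraction),
            class = "pla_train_config")
}

#' Smooth L1 loss
#'
#' Mean over elements of `0.5 d^2 / beta` for `|d| < beta` and
#' `|d| - 0.5 beta` otherwise, where `d = predicted - true`. Quadratic near
#' zero, linear in the tails, so single badly mispredicted complexes do not
#' dominate the gradient.
#'
#' @param predicted,true equal-length numeric vectors (pK units).
#' @param beta transition point (> 0).
#' @return Scalar loss.
#' @export
smooth_l1_loss <- function(predicted, true, beta = 1) {
  if (length(predicted) == 0L) stop("smooth L1 loss of empty vectors")
  if (length(predicted) != length(true))
    stop("predicted and true must have equal length")
  stopifnot(beta > 0)
  d <- predicted - true
  mean(ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta))
}

# gradient of the mean smooth L1 loss w.r.t. predictions
.smooth_l1_grad <- function(predicted, true, beta) {
  d <- predicted - true
  ifelse(abs(d) < beta, d / beta, sign(d)) / length(d)
}

#' Split samples into training and validation sets
#'
#' Draws `floor(fraction * N)` validation items uniformly at random,
#' reproducibly per seed; the split is disjoint and exhaustive.
#'
#' @param samples list (or vector) of samples.
#' @param fraction validation fraction in (0, 1).
#' @param seed RNG seed.
#' @return A list with `train` and `val` subsets.
#' @export
split_train_val <- function(samples, fraction = 0.2, seed = 0L) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to split")
  stopifnot(fraction > 0, fraction < 1)
  n_val <- floor(fraction * n)
  val_idx <- with_seed(seed, sample.int(n, n_val))
  list(train = samples[setdiff(seq_len(n), val_idx)],
       val = samples[sort(val_idx)])
}

.as_features <- function(x, need_graphs) {
  if (inherits(x, "pla_features")) x
  else featurize_samples(x, with_graphs = need_graphs)
}

#' Train a fusion model
#'
#' Adam optimization of the smooth L1 loss over seeded minibatches, with
#' per-epoch validation and early stopping. Descriptor normalization
#' statistics (z-score mean/sd) are computed from the training set and
#' stored in the model. The returned model carries the parameter snapshot
#' with the minimum validation loss, not the final epoch.
#'
#' @param train_samples,val_samples lists of labeled `pla_complex`, or
#'   `pla_features` objects.
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @param verbose print per-epoch losses.
#' @return A list of class `pla_fit` with fields `model` (best snapshot),
#'   `history` (epoch, train_loss, val_loss), `best_epoch`, `best_val_loss`.
#' @export
train_model <- function(train_samples, val_samples, config = model_config(),
                        tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pla_model_config"),
            inherits(tc, "pla_train_config"))
  need_graphs <- "I" %in% variant_modalities(config$variant)
  ftr <- .as_features(train_samples, need_graphs)
  fva <- .as_features(val_samples, need_graphs)
  if (anyNA(ftr$labels) || anyNA(fva$labels))
    stop("all training and validation samples must be labeled")

  model <- init_model(config, seed = tc$seed)
  model$norm <- list(lig = .norm_stats(ftr$lig), poc = .norm_stats(ftr$poc))

  n <- nrow(ftr$lig)
  with_seed(tc$seed + 1L, {
    ord <- sample.int(n)
    splits <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    batches <- lapply(splits, function(idx) make_batch(ftr, model, idx))
    val_batch <- make_batch(fva, model)

    opt <- adam_init(model$params)
    best <- list(val = Inf, params = model$params, bn = model$bn_state,
                 epoch = 0L)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    stall <- 0L
    lr <- tc$learning_rate
    for (epoch in seq_len(tc$max_epochs)) {
      epoch_loss <- 0
      for (b in sample.int(length(batches))) {
        batch <- batches[[b]]
        fw <- model_forward(model, batch, training = TRUE)
        model$bn_state <- fw$new_bn_state
        loss <- smooth_l1_loss(fw$pred, batch$y, tc$beta)
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        epoch_loss <- epoch_loss + loss * length(batch$y)
        grads <- model_backward(model, batch, fw$caches,
                                .smooth_l1_grad(fw$pred, batch$y, tc$beta))
        if (is.finite(tc$clip_norm)) {
          gnorm <- sqrt(sum(unlist(grads, use.names = FALSE)^2))
          if (gnorm > tc$clip_norm)
            grads <- grad_scale(grads, tc$clip_norm / gnorm)
        }
        step <- adam_step(model$params, grads, opt, lr = lr)
        model$params <- step$params
        opt <- step$state
      }
      lr <- lr * tc$lr_decay
      val_pred <- model_forward(model, val_batch, training = FALSE)$pred
      val_loss <- smooth_l1_loss(val_pred, val_batch$y, tc$beta)
      if (!is.finite(val_loss))
        stop(sprintf("training diverged (non-finite validation loss) at epoch %d",
                     epoch))
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = epoch_loss / n,
                                           val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        epoch_loss / n, val_loss))
      if (val_loss < best$val) {
        best <- list(val = val_loss, params = model$params,
                     bn = model$bn_state, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$patience) break
      }
    }
    model$params <- best$params
    model$bn_state <- best$bn
    structure(list(model = model, history = history, best_epoch = best$epoch,
                   best_val_loss = best$val),
              class = "pla_fit")
  })
}

.norm_stats <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1  # constant descriptors pass through unscaled
  list(mean = mu, sd = s)
}

#' @export
print.pla_fit <- function(x, ...) {
  cat(sprintf("<pla_fit> %s: best epoch %d (val loss %.4f), %d epochs run\n",
              x$model$config$variant, x$best_epoch, x$best_val_loss,
              nrow(x$history)))
  invisible(x)
}

#' Repeat the training experiment across seeds
#'
#' Trains one model per seed, evaluates each on the held-out test set, and
#' aggregates PCC/MAE/RMSE as mean and standard deviation. The row with the
#' minimum validation loss is flagged as `best` (the selection rule used to
#' pick the model for downstream screening).
#'
#' @param train_samples,val_samples,test_samples labeled samples or
#'   `pla_features`.
#' @param config a [model_config()].
#' @param tc a [train_config()]; run `s` uses seed `tc$seed + s - 1`.
#' @param n_seeds number of repeats (default 10).
#' @return A list of class `pla_experiments`: `table` (seed, pcc, mae, rmse,
#'   val_loss, best), `aggregate` (mean/sd per metric), `fits` (list of
#'   `pla_fit`).
#' @export
repeat_experiments <- function(train_samples, val_samples, test_samples,
                               config = model_config(), tc = train_config(),
                               n_seeds = 10L) {
  stopifnot(n_seeds >= 1L)
  need_graphs <- "I" %in% variant_modalities(config$variant)
  ftr <- .as_features(train_samples, need_graphs)
  fva <- .as_features(val_samples, need_graphs)
  fte <- .as_features(test_samples, need_graphs)
  rows <- NULL
  fits <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    tcs <- tc
    tcs$seed <- tc$seed + s - 1L
    fit <- tryCatch(train_model(ftr, fva, config, tcs), error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("seed %d failed: %s", tcs$seed, conditionMessage(fit)))
      rows <- rbind(rows, data.frame(seed = tcs$seed, pcc = NA, mae = NA,
                                     rmse = NA, val_loss = NA))
      next
    }
    fits[[s]] <- fit
    pred <- predict_affinity(fit$model, fte)
    met <- compute_metrics(pred, fte$labels)
    rows <- rbind(rows, data.frame(seed = tcs$seed, pcc = met$pcc,
                                   mae = met$mae, rmse = met$rmse,
                                   val_loss = fit$best_val_loss))
  }
  rows$best <- !is.na(rows$val_loss) &
    rows$val_loss == min(rows$val_loss, na.rm = TRUE)
  ok <- !is.na(rows$pcc)
  aggregate <- data.frame(
    metric = c("pcc", "mae", "rmse"),
    mean = c(mean(rows$pcc[ok]), mean(rows$mae[ok]), mean(rows$rmse[ok])),
    sd = if (sum(ok) > 1L)
      c(stats::sd(rows$pcc[ok]), stats::sd(rows$mae[ok]), stats::sd(rows$rmse[ok]))
    else rep(NA_real_, 3))
  structure(list(table = rows, aggregate = aggregate, fits = fits),
            class = "pla_experiments")
}

#' @export
print.pla_experiments <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("aggregate:\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Seeded random hyperparameter search
#'
#' Draws `n_trials` configurations uniformly from the declared space, trains
#' each on the training set, and returns the configuration with the minimum
#' validation loss. The trial sequence is fully determined by the seed.
#'
#' @param train_samples,val_samples labeled samples or `pla_features`.
#' @param space named list; each entry is a list/vector of admissible values
#'   for the matching [model_config()] argument (entries whose values are
#'   themselves vectors, e.g. `tower_channels`, use a list of candidate
#'   vectors).
#' @param n_trials number of random draws (>= 1).
#' @param tc a [train_config()] shared by all trials.
#' @param seed seed of the trial sequence.
#' @return A list of class `pla_search`: `best_config`, `best_val_loss`,
#'   `log` (one row per trial with the drawn values and its loss).
#' @export
hyperparameter_search <- function(train_samples, val_samples, space,
                                  n_trials = 10L, tc = train_config(),
                                  seed = 0L) {
  stopifnot(n_trials >= 1L, length(space) >= 1L, !is.null(names(space)))
  need_graphs <- TRUE
  ftr <- .as_features(train_samples, need_graphs)
  fva <- .as_features(val_samples, need_graphs)
  draws <- with_seed(seed, lapply(seq_len(n_trials), function(k)
    lapply(space, function(choices)
      choices[[sample.int(length(choices), 1L)]])))
  log <- NULL
  best <- list(val = Inf, config = NULL, trial = NA_integer_)
  errors <- character(0)
  for (k in seq_len(n_trials)) {
    cfg <- do.call(model_config, draws[[k]])
    fit <- tryCatch(train_model(ftr, fva, cfg, tc), error = function(e) e)
    val <- if (inherits(fit, "error")) NA_real_ else fit$best_val_loss
    if (inherits(fit, "error"))
      errors <- c(errors, sprintf("trial %d: %s", k, conditionMessage(fit)))
    log <- rbind(log, data.frame(
      trial = k,
      config = paste(vapply(names(draws[[k]]), function(nm)
        sprintf("%s=%s", nm, paste(draws[[k]][[nm]], collapse = "/")), ""),
        collapse = ", "),
      val_loss = val))
    if (!is.na(val) && val < best$val)
      best <- list(val = val, config = cfg, trial = k)
  }
  if (is.null(best$config))
    stop(paste(c("all trials failed:", errors), collapse = "\n"))
  structure(list(best_config = best$config, best_val_loss = best$val,
                 best_trial = best$trial, log = log),
            class = "pla_search")
}
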