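test_that("smooth L1 matches its closed form", {
  expect_equal(smooth_l1_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(smooth_l1_loss(0.5, 0, beta = 1), 0.125)
  expect_equal(smooth_l1_loss(3, 0, beta = 1), 2.5)
  for (beta in c(0.5, 1, 2)) {
    d <- seq(-4, 4, by = 0.25)
    want <- mean(ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta))
    expect_equal(smooth_l1_loss(d, numeric(length(d)), beta), want)
  }
  expect_error(smooth_l1_loss(numeric(0), numeric(0)), "empty")
  expect_error(smooth_l1_loss(1:3, 1:2), "equal length")
})

test_that("the validation split matches the benchmark protocol arithmetic", {
  pool <- seq_len(3772)
  sets <- split_train_val(pool, 0.2, seed = 1)
  expect_length(sets$val, 754L)
  expect_length(sets$train, 3018L)
  expect_setequal(c(sets$train, sets$val), pool)
  expect_length(intersect(sets$train, sets$val), 0L)
})

test_that("splits are seed-reproducible and exhaustive for any size", {
  set.seed(31)
  for (n in c(10, 57, 200)) {
    a <- split_train_val(seq_len(n), 0.2, seed = 9)
    b <- split_train_val(seq_len(n), 0.2, seed = 9)
    expect_identical(a, b)
    expect_length(a$val, floor(0.2 * n))
    expect_setequal(c(a$train, a$val), seq_len(n))
  }
  expect_error(split_train_val(list(1), 0.2, 1), "at least 2")
})

tiny_cfg <- function(variant = "LIP")
  model_config(variant = variant, tower_channels = c(3L, 4L, 6L),
               graph_hidden = 5L, gather_dim = 6L, token_dim = 6L,
               head_dims = c(8L), dropout = 0)

test_that("training returns the minimum-validation snapshot, reproducibly", {
  ds <- tiny_dataset(12, seed = 200)
  sets <- split_train_val(ds$samples, 0.25, seed = 3)
  tc <- train_config(max_epochs = 8L, patience = 8L, batch_size = 4L, seed = 5)
  fit <- train_model(sets$train, sets$val, tiny_cfg(), tc)
  expect_s3_class(fit, "pla_fit")
  expect_equal(nrow(fit$history), 8L)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  fit2 <- train_model(sets$train, sets$val, tiny_cfg(), tc)
  expect_identical(fit2$history, fit$history)
  expect_identical(unlist(fit2$model$params), unlist(fit$model$params))
  # normalization statistics come from the training set
  ftr <- featurize_samples(sets$train)
  expect_close(fit$model$norm$lig$mean, colMeans(ftr$lig), 1e-9)
})

test_that("repeat experiments aggregate per-seed metrics", {
  ds <- tiny_dataset(14, seed = 300)
  sets <- split_train_val(ds$samples, 0.25, seed = 1)
  test_set <- tiny_dataset(6, seed = 301)$samples
  tc <- train_config(max_epochs = 4L, patience = 4L, batch_size = 5L, seed = 0)
  ex <- repeat_experiments(sets$train, sets$val, test_set, tiny_cfg(), tc,
                           n_seeds = 2L)
  expect_equal(nrow(ex$table), 2L)
  expect_equal(ex$table$seed, c(0L, 1L))
  expect_equal(ex$aggregate$mean[ex$aggregate$metric == "pcc"],
               mean(ex$table$pcc))
  expect_equal(sum(ex$table$best), 1L)
  expect_equal(ex$table$val_loss[ex$table$best], min(ex$table$val_loss))
  ex1 <- repeat_experiments(sets$train, sets$val, test_set, tiny_cfg(), tc,
                            n_seeds = 1L)
  expect_true(is.na(ex1$aggregate$sd[1]))
})

test_that("random hyperparameter search replays per seed and selects the argmin", {
  ds <- tiny_dataset(12, seed = 310)
  sets <- split_train_val(ds$samples, 0.25, seed = 1)
  tc <- train_config(max_epochs = 3L, patience = 3L, batch_size = 5L, seed = 2)
  space <- list(graph_hidden = list(4L, 6L),
                token_dim = list(4L, 8L),
                tower_channels = list(c(2L, 3L, 4L), c(3L, 4L, 6L)),
                head_dims = list(c(6L)), dropout = list(0),
                gather_dim = list(5L))
  s1 <- hyperparameter_search(sets$train, sets$val, space, n_trials = 3L,
                              tc = tc, seed = 42)
  s2 <- hyperparameter_search(sets$train, sets$val, space, n_trials = 3L,
                              tc = tc, seed = 42)
  expect_identical(s1$log, s2$log)
  expect_equal(s1$best_val_loss, min(s1$log$val_loss))
  expect_s3_class(s1$best_config, "pla_model_config")
  one <- hyperparameter_search(sets$train, sets$val, space, n_trials = 1L,
                               tc = tc, seed = 7)
  expect_equal(one$best_trial, 1L)
})

test_that("unlabeled samples are rejected by training", {
  ds <- tiny_dataset(4, seed = 320)
  unlabeled <- lapply(ds$samples, function(s) { s$label <- NULL; s })
  expect_error(train_model(unlabeled, ds$samples, tiny_cfg(), train_config()),
               "labeled")
})
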