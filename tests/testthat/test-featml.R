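bench_ds <- function(n = 120, p = 30, k = min(5, p), sigma = 0.05, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, dimnames = list(NULL, sprintf("f%03d", 1:p)))
  g <- make_growth_truth(X, n_informative = k, mu_sat = 5, sigma = sigma,
                         seed = seed)
  list(ds = ml_dataset(X, g$y), truth = g$truth)
}

test_that("metrics match hand-computed values and identities", {
  y <- c(0, 1, 2); p <- c(0, 1, 1)
  m <- compute_metrics(y, p)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r2, 0.5)

  perf <- compute_metrics(1:10, 1:10)
  expect_equal(perf$r2, 1); expect_equal(perf$rmse, 0)
  expect_equal(perf$evs, 1); expect_equal(perf$mae, 0)

  # mean predictor has R2 = 0
  expect_equal(compute_metrics(1:10, rep(mean(1:10), 10))$r2, 0)

  # zero-variance truth flagged degenerate
  dg <- compute_metrics(rep(1, 5), 1:5)
  expect_true(dg$degenerate); expect_true(is.na(dg$r2))

  # RMSE >= MAE always
  set.seed(4)
  for (i in 1:20) {
    yy <- rnorm(30); pp <- rnorm(30)
    mm <- compute_metrics(yy, pp)
    expect_gte(mm$rmse, mm$mae)
  }
})

test_that("splits are reproducible, disjoint and exhaustive", {
  ds <- bench_ds(n = 10, p = 3)$ds
  sp <- split_dataset(ds, 0.8, seed = 1)
  expect_equal(nrow(sp$train$X), 8L)
  expect_equal(nrow(sp$test$X), 2L)
  sp2 <- split_dataset(ds, 0.8, seed = 1)
  expect_identical(sp$train$X, sp2$train$X)

  big <- bench_ds(n = 100, p = 3)$ds
  a <- split_dataset(big, 0.8, seed = 0)
  b <- split_dataset(big, 0.8, seed = 1)
  expect_false(identical(rownames(a$train$X), rownames(b$train$X)) &&
                 identical(a$train$y, b$train$y))
  expect_error(split_dataset(ds, 1.2), "train_frac")
})

test_that("scenario matrix is 17 per view, 34 total, KNN limited to 2 searches", {
  sc <- enumerate_scenarios()
  expect_equal(nrow(sc), 34L)
  expect_equal(sum(sc$view == "transcription"), 17L)
  knn_opt <- unique(sc$optimizer[sc$kind == "knn"])
  expect_setequal(knn_opt, c("grid", "random"))
  expect_setequal(unique(sc$optimizer[sc$kind == "lstm"]),
                  c("grid", "random", "aco", "hho", "bayes"))
})

test_that("model families fit their canonical signals", {
  # knn k = 1 returns the exact label of a duplicated point
  tr <- list(X = matrix(c(0, 1, 2, 3), 4, 1), y = c(10, 11, 12, 13))
  te <- list(X = matrix(2, 1, 1), y = 12)
  expect_equal(train_predict("knn", list(k = 1), tr, te), 12)

  # linear-kernel SVR on a linear signal
  set.seed(2)
  n <- 80
  x <- matrix(runif(n), n, 1)
  y <- 3 * x[, 1] + 0.5
  tr <- list(X = x[1:60, , drop = FALSE], y = y[1:60])
  te <- list(X = x[61:n, , drop = FALSE], y = y[61:n])
  pred <- train_predict("svr", list(kernel = "linear", cost = 10,
                                    epsilon = 0.01), tr, te)
  expect_gt(compute_metrics(te$y, pred)$r2, 0.99)

  # config outside the declared space errors
  expect_error(train_predict("knn", list(k = 99), tr, te), "outside")
})

test_that("CNN and LSTM training reduces the loss on a planted signal", {
  b <- bench_ds(n = 80, p = 24, k = 4, sigma = 0.02, seed = 3)
  sp <- split_dataset(b$ds, 0.8, seed = 0)
  fitc <- cnn_fit(sp$train$X, sp$train$y, filters = 3, kernel = 5,
                  lr = 0.01, epochs = 15, seed = 0)
  expect_lt(fitc$loss[15], fitc$loss[1])
  fitl <- lstm_fit(sp$train$X, sp$train$y, hidden = 6, chunk = 6,
                   lr = 0.02, epochs = 15, seed = 0)
  expect_lt(fitl$loss[15], fitl$loss[1])
  # deterministic per seed
  fitc2 <- cnn_fit(sp$train$X, sp$train$y, filters = 3, kernel = 5,
                   lr = 0.01, epochs = 15, seed = 0)
  expect_identical(fitc$params, fitc2$params)
  expect_equal(length(cnn_predict(fitc, sp$test$X)), nrow(sp$test$X))
  expect_equal(length(lstm_predict(fitl, sp$test$X)), nrow(sp$test$X))
})

test_that("repeated evaluation tracks the planted signal over a null", {
  b <- bench_ds(n = 100, p = 10, k = 3, sigma = 0.05, seed = 5)
  ev <- repeated_evaluation("knn", list(k = 5), b$ds, n_repeats = 10,
                            seed0 = 0)
  expect_equal(nrow(ev$metrics), 10L)
  # permutation null
  null_ds <- b$ds
  null_ds$y <- with_seed(1, sample(null_ds$y))
  ev0 <- repeated_evaluation("knn", list(k = 5), null_ds, n_repeats = 10,
                             seed0 = 0)
  expect_gt(ev$mean[["r2"]], ev0$mean[["r2"]])
  # single repeat -> distribution of size 1
  ev1 <- repeated_evaluation("knn", list(k = 5), b$ds, n_repeats = 1)
  expect_equal(nrow(ev1$metrics), 1L)
})

test_that("repeated evaluation of a memorizable design has zero R2 spread", {
  # every x value occurs 5 times; 1-NN prediction is exact on any split
  X <- matrix(rep(seq(0, 1, length.out = 20), each = 5), ncol = 1)
  y <- as.numeric(3 * X[, 1] + 1)
  ds <- ml_dataset(X, y)
  ev <- repeated_evaluation("knn", list(k = 1), ds, n_repeats = 10,
                            seed0 = 3)
  expect_equal(stats::sd(ev$metrics$r2), 0)
  expect_equal(ev$mean[["r2"]], 1)
})

test_that("HDMPPK retains planted features and is deterministic", {
  set.seed(6)
  n <- 150; p <- 100; k <- 10
  X <- matrix(runif(n * p), n, dimnames = list(NULL, sprintf("f%03d", 1:p)))
  g <- make_growth_truth(X, n_informative = k, mu_sat = 10, sigma = 0.05,
                         seed = 6)
  ds <- ml_dataset(X, g$y)
  cfg <- list(top_m = 30L, pso_particles = 10, pso_iters = 10)
  res <- hdmppk(ds, cfg, seed = 0)
  recall <- mean(g$truth$informative %in% res$report$selected_features)
  expect_gte(recall, 0.8)
  res2 <- hdmppk(ds, cfg, seed = 0)
  expect_identical(res$report, res2$report)
  expect_identical(res$dataset$X, res2$dataset$X)
  expect_equal(res$report$stage_order[1], "hgbr_importance")
  expect_s3_class(res$dataset, "ml_dataset")

  # all-noise features give fitness inside the permutation-null band
  y_null <- with_seed(9, rnorm(n))
  ds_null <- ml_dataset(X, y_null)
  res_null <- hdmppk(ds_null, cfg, seed = 0)
  null_fit <- replicate(20, omegrow:::knn_cv_r2(
    res_null$dataset$X, with_seed(sample.int(1e6, 1), sample(res_null$dataset$y)),
    k = 5, folds = 5))
  expect_lt(res_null$report$cv_fitness,
            max(null_fit) + 3 * stats::sd(null_fit) + 0.1)
})

test_that("sparse group lasso selects the planted group across the path", {
  set.seed(7)
  n <- 120; p <- 20
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  groups <- rep(c("gA", "gB", "gC", "gD"), each = 5)
  beta <- numeric(p); beta[1:5] <- c(1.5, 1.2, -1, 0.8, 1.1)  # group gA
  y <- X %*% beta + rnorm(n, sd = 0.3)
  ds <- list(X = X, y = as.numeric(y))

  all_in <- sgl_select(ds, groups, lambda = 0)
  expect_equal(length(all_in$selected), p)
  none <- sgl_select(ds, groups, lambda = 1e4)
  expect_equal(length(none$selected), 0L)
  mid <- sgl_select(ds, groups, lambda = 0.15, alpha_mix = 0.5)
  expect_true(all(sprintf("f%02d", 1:5) %in% mid$selected))
  sel_groups <- unique(groups[match(mid$selected, colnames(X))])
  expect_lte(length(sel_groups), 2L)
  expect_error(sgl_select(ds, groups, lambda = -1), "lambda")
})
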