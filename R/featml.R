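# Machine-learning harness for growth-rate prediction: datasets, splits,
# the four performance metrics, the four model families, HDMPPK feature
# engineering, scenario enumeration and repeated evaluation.

#' Construct an ML dataset
#'
#' @param X array x feature numeric matrix, no missing values.
#' @param y growth rate per array (1/h).
#' @param view `"transcription"` or `"translation"`.
#' @param origin per-array origin flag, `"experimental"` or `"simulated"`
#'   (default all experimental).
#' @return object of class `ml_dataset`.
#' @export
ml_dataset <- function(X, y, view = c("transcription", "translation"),
                       origin = NULL) {
  X <- as.matrix(X)
  view <- match.arg(view)
  if (anyNA(X) || anyNA(y)) stopf("ml_dataset: missing values not allowed")
  if (nrow(X) != length(y)) stopf("X rows (%d) != length(y) (%d)",
                                  nrow(X), length(y))
  origin <- origin %||% rep("experimental", nrow(X))
  if (!all(origin %in% c("experimental", "simulated")))
    stopf("origin flags must be 'experimental' or 'simulated'")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  structure(list(X = X, y = as.numeric(y), view = view, origin = origin),
            class = "ml_dataset")
}

#' @export
print.ml_dataset <- function(x, ...) {
  cat(sprintf("ML dataset (%s view): %d arrays x %d features (%d simulated)\n",
              x$view, nrow(x$X), ncol(x$X), sum(x$origin == "simulated")))
  invisible(x)
}

subset_ds <- function(ds, idx) {
  structure(list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx],
                 view = ds$view, origin = ds$origin[idx]),
            class = "ml_dataset")
}

#' Random train/test split
#'
#' @param ds an [ml_dataset()].
#' @param train_frac training fraction in (0, 1) (default 0.8).
#' @param seed RNG seed.
#' @return list with `train` and `test` datasets (disjoint, exhaustive).
#' @export
split_dataset <- function(ds, train_frac = 0.8, seed = 0) {
  n <- nrow(ds$X)
  if (n < 5) stopf("need at least 5 arrays to split")
  if (train_frac <= 0 || train_frac >= 1)
    stopf("train_frac must be inside (0, 1)")
  idx <- with_seed(seed, sample.int(n, size = round(train_frac * n)))
  list(train = subset_ds(ds, sort(idx)),
       test = subset_ds(ds, setdiff(seq_len(n), idx)))
}

#' Regression performance metrics
#'
#' Coefficient of determination, root mean square error, explained variance
#' score, and mean absolute error.
#'
#' @param y_true observed values.
#' @param y_pred predicted values.
#' @return list of class `ml_metrics` with `r2`, `rmse`, `evs`, `mae`, `n`
#'   and a `degenerate` flag (TRUE when `y_true` has zero variance, in which
#'   case `r2`/`evs` are `NA`).
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  n <- length(y_true)
  if (n < 2) stopf("need at least 2 observations")
  e <- y_true - y_pred
  ss_tot <- sum((y_true - mean(y_true))^2)
  degen <- ss_tot == 0
  structure(list(
    r2 = if (degen) NA_real_ else 1 - sum(e^2) / ss_tot,
    rmse = sqrt(mean(e^2)),
    evs = if (degen) NA_real_ else 1 - stats::var(e) / stats::var(y_true),
    mae = mean(abs(e)),
    n = n, degenerate = degen), class = "ml_metrics")
}

#' @export
print.ml_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f  RMSE = %.4f  EVS = %.4f  MAE = %.4f  (n = %d)\n",
              x$r2, x$rmse, x$evs, x$mae, x$n))
  invisible(x)
}

#' Default hyperparameter space per model family
#'
#' @param kind one of `"knn"`, `"svr"`, `"cnn"`, `"lstm"`.
#' @return list of parameter specifications (name, type, bounds, log flag).
#' @export
hp_space <- function(kind = c("knn", "svr", "cnn", "lstm")) {
  kind <- match.arg(kind)
  switch(kind,
    knn = list(list(name = "k", type = "int", lower = 1, upper = 15)),
    svr = list(
      list(name = "cost", type = "real", lower = 0.1, upper = 100, log = TRUE),
      list(name = "gamma", type = "real", lower = 1e-4, upper = 1, log = TRUE),
      list(name = "epsilon", type = "real", lower = 0.01, upper = 0.5)),
    cnn = list(
      list(name = "filters", type = "int", lower = 2, upper = 8),
      list(name = "kernel", type = "int", lower = 3, upper = 9),
      list(name = "lr", type = "real", lower = 1e-3, upper = 3e-2, log = TRUE),
      list(name = "epochs", type = "int", lower = 10, upper = 40)),
    lstm = list(
      list(name = "hidden", type = "int", lower = 4, upper = 16),
      list(name = "chunk", type = "int", lower = 4, upper = 20),
      list(name = "lr", type = "real", lower = 1e-3, upper = 3e-2, log = TRUE),
      list(name = "epochs", type = "int", lower = 10, upper = 40)))
}

default_config <- function(kind) {
  switch(kind,
         knn = list(k = 5),
         svr = list(cost = 10, gamma = NULL, epsilon = 0.1),
         cnn = list(filters = 4, kernel = 7, lr = 0.01, epochs = 30),
         lstm = list(hidden = 8, chunk = 10, lr = 0.02, epochs = 40))
}

check_config <- function(kind, config) {
  space <- hp_space(kind)
  for (p in space) {
    v <- config[[p$name]]
    if (is.null(v)) next
    if (p$type %in% c("int", "real") &&
        (v < p$lower - 1e-9 || v > p$upper + 1e-9))
      stopf("config '%s' = %s outside [%s, %s] for %s",
            p$name, format(v), format(p$lower), format(p$upper), kind)
  }
  invisible(TRUE)
}

#' Train a model family and predict on a test set
#'
#' Model families: k-nearest-neighbour regression (`knn`), support vector
#' regression with radial kernel (`svr`), a 1-D convolutional network
#' (`cnn`) and an LSTM over chunked feature subsequences (`lstm`); feature
#' vectors feed the sequence models in column (genome-coordinate) order.
#' Deterministic given `seed`.
#'
#' @param kind model family.
#' @param config named list of hyperparameters (missing entries take
#'   defaults; values outside [hp_space()] raise an error).
#' @param train,test [ml_dataset()]s (or lists with `X`, `y`).
#' @param seed RNG seed (network initialization).
#' @return numeric predictions for `test`.
#' @export
train_predict <- function(kind = c("knn", "svr", "cnn", "lstm"),
                          config = list(), train, test, seed = 0) {
  fit <- ml_fit(kind, config, train$X, train$y, seed = seed)
  ml_predict(fit, test$X)
}

#' Fit a model family (persistent form)
#'
#' Like [train_predict()] but returns a reusable fitted object for
#' [ml_predict()]; the ensemble combiner relies on this.
#'
#' @inheritParams train_predict
#' @param X,y training matrix and targets.
#' @return object of class `ml_fit`.
#' @export
ml_fit <- function(kind = c("knn", "svr", "cnn", "lstm"), config = list(),
                   X, y, seed = 0) {
  kind <- match.arg(kind)
  cfg <- utils::modifyList(default_config(kind), config)
  check_config(kind, cfg)
  fit <- switch(kind,
    knn = list(X = X, y = y, k = min(cfg$k, nrow(X))),
    svr = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = cfg$kernel %||% "radial", cost = cfg$cost,
                     gamma = cfg$gamma %||% (1 / ncol(X)),
                     epsilon = cfg$epsilon, scale = ncol(X) > 1),
    cnn = cnn_fit(X, y, filters = cfg$filters, kernel = cfg$kernel,
                  lr = cfg$lr, epochs = cfg$epochs, seed = seed),
    lstm = lstm_fit(X, y, hidden = cfg$hidden, chunk = cfg$chunk,
                    lr = cfg$lr, epochs = cfg$epochs, seed = seed))
  structure(list(kind = kind, config = cfg, fit = fit,
                 features = colnames(X),
                 feature_means = colMeans(X)), class = "ml_fit")
}

#' Predict from a fitted model family
#' @param object an [ml_fit()]. @param X feature matrix.
#' @return numeric predictions.
#' @export
ml_predict <- function(object, X) {
  switch(object$kind,
    knn = as.numeric(FNN::knn.reg(train = object$fit$X, test = X,
                                  y = object$fit$y, k = object$fit$k)$pred),
    svr = as.numeric(stats::predict(object$fit, X)),
    cnn = cnn_predict(object$fit, X),
    lstm = lstm_predict(object$fit, X))
}

#' Enumerate the scenario matrix
#'
#' Per view (transcription, translation): KNN with grid and random search,
#' and each of SVR, CNN, LSTM with all five optimizers — 17 scenarios per
#' view, 34 in total.
#'
#' @return data.frame with columns `view`, `kind`, `optimizer`.
#' @export
enumerate_scenarios <- function() {
  one_view <- rbind(
    expand.grid(kind = "knn", optimizer = c("grid", "random"),
                stringsAsFactors = FALSE),
    expand.grid(kind = c("svr", "cnn", "lstm"),
                optimizer = c("grid", "random", "aco", "hho", "bayes"),
                stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(c("transcription", "translation"), function(v)
    cbind(view = v, one_view, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Repeated train/test evaluation
#'
#' Runs `n_repeats` independent split/train/test cycles (seeds
#' `seed0 .. seed0 + n - 1`) and collects the metric distribution.  Up to
#' 5\% per-repeat failures are tolerated and logged.
#'
#' @param kind model family.
#' @param config hyperparameter list.
#' @param ds an [ml_dataset()].
#' @param n_repeats repetitions (default 100).
#' @param seed0 base seed.
#' @param train_frac training fraction (default 0.8).
#' @return list with `metrics` (per-repeat data.frame), `mean`, `sd`,
#'   `n_failures`.
#' @export
repeated_evaluation <- function(kind, config = list(), ds, n_repeats = 100,
                                seed0 = 0, train_frac = 0.8) {
  rows <- vector("list", n_repeats)
  fails <- 0L
  for (i in seq_len(n_repeats)) {
    seed <- seed0 + i - 1L
    res <- tryCatch({
      sp <- split_dataset(ds, train_frac = train_frac, seed = seed)
      pred <- train_predict(kind, config, sp$train, sp$test, seed = seed)
      m <- compute_metrics(sp$test$y, pred)
      data.frame(seed = seed, r2 = m$r2, rmse = m$rmse, evs = m$evs,
                 mae = m$mae)
    }, error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1L else rows[[i]] <- res
  }
  if (fails > 0.05 * n_repeats)
    stopf("repeated_evaluation: %d of %d repeats failed", fails, n_repeats)
  met <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(metrics = met,
       mean = colMeans(met[, c("r2", "rmse", "evs", "mae")]),
       sd = apply(met[, c("r2", "rmse", "evs", "mae")], 2, stats::sd),
       n_failures = fails)
}

# --- HDMPPK ----------------------------------------------------------------

# density-based spatial clustering; returns cluster labels, 0 = noise
dbscan_labels <- function(X, eps, min_pts = 5) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' HDMPPK feature engineering
#'
#' Six stages in acronym order: (1) histogram gradient-boosted tree
#' importance ranking keeps the top `top_m` features; (2) density-based
#' spatial clustering flags outlier arrays (noise points removed);
#' (3) per-feature min-max rescaling; (4) principal-component projection
#' keeping a variance fraction `var_frac`; (5) binary particle-swarm search
#' over component inclusion with 5-fold cross-validated k-nearest-neighbour
#' R-squared as fitness; (6) the final fitness is recorded.
#'
#' @param ds an [ml_dataset()].
#' @param config list overriding defaults: `top_m` (min(200, p)),
#'   `dbscan_minpts` (5), `dbscan_eps` (0.9-quantile of 5-NN distances),
#'   `var_frac` (0.95), `pso_particles` (30), `pso_iters` (50),
#'   `inertia` (0.72), `c_cog`/`c_soc` (1.49), `knn_k` (5), `cv_folds` (5).
#' @param seed RNG seed; the whole chain is deterministic per seed.
#' @return list with `dataset` (transformed [ml_dataset()]: selected
#'   components as features) and `report` (selected original features,
#'   removed arrays, per-stage bookkeeping, final CV fitness).
#' @export
hdmppk <- function(ds, config = list(), seed = 0) {
  p <- ncol(ds$X)
  cfg <- utils::modifyList(list(
    top_m = min(200L, p), hgbr_nrounds = 500, dbscan_minpts = 5,
    dbscan_eps = NULL,
    var_frac = 0.95, pso_particles = 30, pso_iters = 50,
    inertia = 0.72, c_cog = 1.49, c_soc = 1.49, knn_k = 5, cv_folds = 5),
    config)
  with_seed(seed, {
    # (1) importance ranking
    if (p <= cfg$top_m) {
      if (p < cfg$top_m)
        warnf("fewer features (%d) than top_m (%d): importance stage skipped",
              p, cfg$top_m)
      kept <- colnames(ds$X)
    } else {
      # many shallow, feature-subsampled rounds so weak but real signal
      # features still accumulate importance
      bst <- xgboost::xgb.train(
        params = list(max_depth = 2, eta = 0.05, colsample_bytree = 0.2,
                      subsample = 0.8, tree_method = "hist", nthread = 1,
                      objective = "reg:squarederror"),
        data = xgboost::xgb.DMatrix(ds$X, label = ds$y, nthread = 1),
        nrounds = cfg$hgbr_nrounds, verbose = 0)
      imp <- xgboost::xgb.importance(model = bst)
      ranked <- c(imp$Feature, setdiff(colnames(ds$X), imp$Feature))
      kept <- ranked[seq_len(cfg$top_m)]
      kept <- colnames(ds$X)[colnames(ds$X) %in% kept]   # original order
    }
    X1 <- ds$X[, kept, drop = FALSE]

    # (2) density-based array-outlier removal
    Xs <- scale(X1)
    Xs[is.na(Xs)] <- 0
    D <- as.matrix(stats::dist(Xs))
    kdist <- apply(D, 1, function(r) sort(r)[min(6, nrow(D))])
    eps <- cfg$dbscan_eps %||% stats::quantile(kdist, 0.9)
    labels <- dbscan_labels(Xs, eps = eps, min_pts = cfg$dbscan_minpts)
    keep_arr <- labels != 0L
    if (sum(keep_arr) < max(10, 0.5 * nrow(X1))) keep_arr[] <- TRUE
    X2 <- X1[keep_arr, , drop = FALSE]
    y2 <- ds$y[keep_arr]

    # (3) min-max rescaling per feature
    X3 <- t(minmax_rescale(t(X2)))
    X3 <- unclass_matrix(X3)

    # (4) PCA keeping var_frac of variance
    pc <- stats::prcomp(X3, center = TRUE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_comp <- max(1L, which(cum >= cfg$var_frac)[1])
    scores <- pc$x[, seq_len(n_comp), drop = FALSE]

    # (5) binary PSO over component inclusion, k-NN CV fitness
    fitness <- function(bits) {
      if (!any(bits)) return(-Inf)
      knn_cv_r2(scores[, bits, drop = FALSE], y2, k = cfg$knn_k,
                folds = cfg$cv_folds)
    }
    pso <- binary_pso(n_comp, fitness, n_particles = cfg$pso_particles,
                      n_iters = cfg$pso_iters, inertia = cfg$inertia,
                      c_cog = cfg$c_cog, c_soc = cfg$c_soc)
    sel <- pso$best_bits

    out_ds <- ml_dataset(scores[, sel, drop = FALSE], y2, view = ds$view,
                         origin = ds$origin[keep_arr])
    report <- list(
      selected_features = kept,
      n_features_in = p, n_features_kept = length(kept),
      removed_arrays = (rownames(ds$X) %||%
                          as.character(seq_len(nrow(ds$X))))[!keep_arr],
      n_components = n_comp,
      selected_components = which(sel),
      cv_fitness = pso$best_fit,
      dbscan_eps = unname(eps),
      stage_order = c("hgbr_importance", "dbscan_outliers", "minmax",
                      "pca", "pso_subset", "knn_fitness"))
    list(dataset = out_ds, report = report)
  })
}

knn_cv_r2 <- function(X, y, k = 5, folds = 5) {
  n <- nrow(X)
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    kk <- min(k, sum(!te))
    pred[te] <- FNN::knn.reg(train = X[!te, , drop = FALSE],
                             test = X[te, , drop = FALSE],
                             y = y[!te], k = kk)$pred
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

binary_pso <- function(d, fitness, n_particles = 30, n_iters = 50,
                       inertia = 0.72, c_cog = 1.49, c_soc = 1.49) {
  pos <- matrix(stats::runif(n_particles * d) > 0.5, n_particles)
  vel <- matrix(stats::rnorm(n_particles * d, sd = 0.5), n_particles)
  pbest <- pos
  pfit <- apply(pos, 1, fitness)
  gi <- which.max(pfit)
  gbest <- pos[gi, ]; gfit <- pfit[gi]
  for (it in seq_len(n_iters)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles)
    r2 <- matrix(stats::runif(n_particles * d), n_particles)
    vel <- inertia * vel +
      c_cog * r1 * (pbest - pos) +
      c_soc * r2 * (matrix(gbest, n_particles, d, byrow = TRUE) - pos)
    prob <- 1 / (1 + exp(-vel))
    pos <- matrix(stats::runif(n_particles * d), n_particles) < prob
    fit <- apply(pos, 1, fitness)
    upd <- fit > pfit
    pbest[upd, ] <- pos[upd, , drop = FALSE]
    pfit[upd] <- fit[upd]
    if (max(pfit) > gfit) {
      gi <- which.max(pfit)
      gbest <- pbest[gi, ]; gfit <- pfit[gi]
    }
  }
  list(best_bits = gbest, best_fit = gfit)
}
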