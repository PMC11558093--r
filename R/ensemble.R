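# Two-view ensembles: one member model per omics view (transcription,
# translation), combined by ordinary least squares fitted strictly on
# out-of-fold member predictions.  The concatenated-feature SVR serves as
# the single-model baseline.

#' Declare an ensemble specification
#'
#' The field's pairings: `AB` combines an ant-colony-optimized CNN on the
#' translation view with a Bayesian-optimized LSTM on the transcription
#' view; `BB` uses the LSTM on both views, `AA` the CNN on both; the
#' `SVR-baseline` fits one support-vector regression on the concatenated
#' views.
#'
#' @param label `"AB"`, `"BB"`, `"AA"` or `"SVR-baseline"` select the
#'   preset pairings; any other string declares a custom two-member spec
#'   whose members must be given explicitly.
#' @param transcription_member,translation_member lists with `kind` and
#'   `config` (defaults follow the label).
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(label = "BB",
                          transcription_member = NULL,
                          translation_member = NULL) {
  cnn_m <- list(kind = "cnn", config = list(epochs = 25))
  lstm_m <- list(kind = "lstm", config = list(epochs = 25))
  members <- switch(label,
    AB = list(transcription = lstm_m, translation = cnn_m),
    BB = list(transcription = lstm_m, translation = lstm_m),
    AA = list(transcription = cnn_m, translation = cnn_m),
    list())
  if (!is.null(transcription_member))
    members$transcription <- transcription_member
  if (!is.null(translation_member))
    members$translation <- translation_member
  structure(list(label = label, members = members),
            class = "ensemble_spec")
}

#' Build and fit a two-view ensemble
#'
#' Members are trained on the training split of each view; the combiner is
#' an intercept-plus-two-slopes least squares fitted only on out-of-fold
#' member predictions of the training arrays, so no member ever sees its
#' own training targets at combination time.  The `SVR-baseline` spec fits
#' one SVR on the concatenated feature views instead.
#'
#' @param spec an [ensemble_spec()].
#' @param transcription_ds,translation_ds [ml_dataset()]s sharing array ids
#'   and growth labels.
#' @param seed RNG seed (split, folds, member initialization).
#' @param train_frac training fraction (default 0.8).
#' @param folds out-of-fold prediction folds (default 5).
#' @return object of class `growth_ensemble` with members, combiner
#'   coefficients, and test-set `metrics`.
#' @export
build_ensemble <- function(spec, transcription_ds, translation_ds, seed = 0,
                           train_frac = 0.8, folds = 5) {
  at <- rownames(transcription_ds$X); ap <- rownames(translation_ds$X)
  if (!identical(at, ap))
    stopf("array ids differ between views: %s",
          paste(utils::head(c(setdiff(at, ap), setdiff(ap, at)), 5),
                collapse = ", "))
  if (max(abs(transcription_ds$y - translation_ds$y)) > 1e-12)
    stopf("growth labels differ between views")
  n <- nrow(transcription_ds$X)
  idx <- with_seed(seed, sample.int(n, round(train_frac * n)))
  tr_i <- sort(idx); te_i <- setdiff(seq_len(n), idx)
  y_tr <- transcription_ds$y[tr_i]; y_te <- transcription_ds$y[te_i]

  if (spec$label == "SVR-baseline") {
    Xall <- cbind(transcription_ds$X, translation_ds$X)
    fit <- ml_fit("svr", list(), Xall[tr_i, , drop = FALSE], y_tr,
                  seed = seed)
    pred_te <- ml_predict(fit, Xall[te_i, , drop = FALSE])
    return(structure(list(spec = spec, baseline = fit, seed = seed,
                          metrics = compute_metrics(y_te, pred_te),
                          test_predictions = pred_te),
                     class = "growth_ensemble"))
  }

  views <- list(transcription = transcription_ds$X,
                translation = translation_ds$X)
  fold_id <- with_seed(seed + 1L,
                       rep_len(seq_len(folds), length(tr_i))[
                         sample.int(length(tr_i))])
  oof <- matrix(NA_real_, length(tr_i), 2,
                dimnames = list(NULL, names(views)))
  members <- list()
  member_test <- matrix(NA_real_, length(te_i), 2,
                        dimnames = list(NULL, names(views)))
  for (v in names(views)) {
    mem <- spec$members[[v]]
    if (is.null(mem)) stopf("spec lacks a %s member", v)
    Xv <- views[[v]]
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      fit_f <- ml_fit(mem$kind, mem$config,
                      Xv[tr_i[!hold], , drop = FALSE], y_tr[!hold],
                      seed = seed + f)
      oof[hold, v] <- ml_predict(fit_f, Xv[tr_i[hold], , drop = FALSE])
    }
    members[[v]] <- ml_fit(mem$kind, mem$config, Xv[tr_i, , drop = FALSE],
                           y_tr, seed = seed)
    member_test[, v] <- ml_predict(members[[v]],
                                   Xv[te_i, , drop = FALSE])
  }
  comb_df <- data.frame(y = y_tr, pt = oof[, 1], pp = oof[, 2])
  comb <- stats::lm(y ~ pt + pp, data = comb_df)
  pred_te <- as.numeric(stats::predict(
    comb, data.frame(pt = member_test[, 1], pp = member_test[, 2])))
  structure(list(
    spec = spec, members = members, combiner = comb,
    combiner_coef = stats::coef(comb), oof = oof, seed = seed,
    member_metrics = lapply(seq_len(2), function(j)
      compute_metrics(y_te, member_test[, j])),
    metrics = compute_metrics(y_te, pred_te),
    test_predictions = pred_te),
    class = "growth_ensemble")
}

#' @export
print.growth_ensemble <- function(x, ...) {
  cat(sprintf("Growth ensemble (%s): test ", x$spec$label))
  print(x$metrics)
  invisible(x)
}

#' Predict growth rates for compendium expression profiles
#'
#' Maps compendium genes onto each member's training features (training
#' means fill unmappable features, with a warning count) and combines the
#' member predictions.
#'
#' @param ensemble a fitted [build_ensemble()] object.
#' @param comp an `expression_compendium` (genes x arrays).
#' @return named numeric growth predictions, one per array.
#' @export
predict_growth_profiles <- function(ensemble, comp) {
  stopifnot(inherits(comp, "expression_compendium"))
  Xc <- t(comp$values)
  map_view <- function(fit) {
    feats <- fit$features
    missing <- setdiff(feats, colnames(Xc))
    if (length(missing) > 0.5 * length(feats))
      stopf("%d of %d features unmappable to the compendium",
            length(missing), length(feats))
    if (length(missing) > 0)
      warnf("%d unmappable feature(s) imputed by training means",
            length(missing))
    X <- matrix(rep(fit$feature_means, each = nrow(Xc)), nrow(Xc),
                dimnames = list(rownames(Xc), feats))
    shared <- intersect(feats, colnames(Xc))
    X[, shared] <- Xc[, shared]
    X
  }
  if (ensemble$spec$label == "SVR-baseline") {
    X <- map_view(ensemble$baseline)
    return(stats::setNames(ml_predict(ensemble$baseline, X), rownames(Xc)))
  }
  pt <- ml_predict(ensemble$members$transcription,
                   map_view(ensemble$members$transcription))
  pp <- ml_predict(ensemble$members$translation,
                   map_view(ensemble$members$translation))
  pred <- as.numeric(stats::predict(ensemble$combiner,
                                    data.frame(pt = pt, pp = pp)))
  stats::setNames(pred, rownames(Xc))
}

#' Compare ensemble specifications by repeated evaluation
#'
#' Rebuilds each spec `n_repeats` times under fresh splits (seeds
#' `seed0 .. seed0 + n - 1`) and ranks by mean test R-squared.
#'
#' @param specs list of [ensemble_spec()]s (>= 2).
#' @param transcription_ds,translation_ds the two view datasets.
#' @param n_repeats repetitions per spec (default 10).
#' @param seed0 base seed.
#' @return data.frame ranked by `mean_r2` (descending).
#' @export
compare_ensembles <- function(specs, transcription_ds, translation_ds,
                              n_repeats = 10, seed0 = 0) {
  stopifnot(length(specs) >= 2)
  rows <- lapply(specs, function(sp) {
    r2 <- numeric(n_repeats); rmse <- numeric(n_repeats)
    for (i in seq_len(n_repeats)) {
      ens <- build_ensemble(sp, transcription_ds, translation_ds,
                            seed = seed0 + i - 1L)
      r2[i] <- ens$metrics$r2; rmse[i] <- ens$metrics$rmse
    }
    data.frame(label = sp$label, mean_r2 = mean(r2), sd_r2 = stats::sd(r2),
               mean_rmse = mean(rmse), n_repeats = n_repeats)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_r2), ]
  out$rank <- rank(-out$mean_r2, ties.method = "min")
  rownames(out) <- NULL
  out
}
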