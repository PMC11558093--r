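svr_member <- list(kind = "svr", config = list())
two_view_specs <- function() list(
  ensemble_spec("custom", transcription_member = svr_member,
                translation_member = svr_member),
  ensemble_spec("SVR-baseline"))

test_that("identical memorizable members give a perfect ensemble", {
  x <- rep(seq(0, 1, length.out = 25), each = 6)
  X <- matrix(x, ncol = 1, dimnames = list(sprintf("a%03d", seq_along(x)),
                                           "f1"))
  y <- 2 * x + 1
  knn1 <- list(kind = "knn", config = list(k = 1))
  ds <- ml_dataset(X, y)
  ens <- build_ensemble(
    ensemble_spec("custom", transcription_member = knn1,
                  translation_member = knn1), ds, ds, seed = 1)
  expect_gt(ens$metrics$r2, 0.999)
})

test_that("the combiner is fitted strictly out-of-fold", {
  bm <- make_two_view_benchmark(n_arrays = 120, p_per_view = 20,
                                n_informative = 4, seed = 2)
  knn1 <- list(kind = "knn", config = list(k = 1))
  ens <- build_ensemble(
    ensemble_spec("custom", transcription_member = knn1,
                  translation_member = knn1),
    bm$transcription, bm$translation, seed = 0)
  # a 1-NN member predicts its own training points exactly, so in-sample
  # member predictions would equal the targets; the stored combiner inputs
  # must differ from the targets, proving they are out-of-fold
  y_tr <- ens$combiner$model[["y"]]
  expect_gt(mean((ens$oof[, 1] - y_tr)^2), 1e-6)
  expect_gt(mean((ens$oof[, 2] - y_tr)^2), 1e-6)
})

test_that("complementary views: ensemble beats members and the baseline", {
  bm <- make_two_view_benchmark(seed = 0)
  ens <- build_ensemble(two_view_specs()[[1]], bm$transcription,
                        bm$translation, seed = 0)
  max_member <- max(vapply(ens$member_metrics, `[[`, numeric(1), "r2"))
  expect_gte(ens$metrics$r2, max_member - 0.02)

  cmp <- compare_ensembles(two_view_specs(), bm$transcription,
                           bm$translation, n_repeats = 3, seed0 = 0)
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$label[1], "custom")   # two-member ensemble ranks first
})

test_that("a zero-information member gets a small combiner weight", {
  set.seed(5)
  n <- 150
  Xt <- matrix(runif(n * 10), n,
               dimnames = list(sprintf("a%03d", 1:n), paste0("tx", 1:10)))
  Xp <- matrix(runif(n * 10), n,
               dimnames = list(sprintf("a%03d", 1:n), paste0("tl", 1:10)))
  y <- 2 * Xt[, 1] + rnorm(n, sd = 0.05)   # translation view pure noise
  ens <- build_ensemble(two_view_specs()[[1]],
                        ml_dataset(Xt, y),
                        ml_dataset(Xp, y, view = "translation"), seed = 1)
  cf <- ens$combiner_coef
  expect_gt(abs(cf[["pt"]]), 2 * abs(cf[["pp"]]))
})

test_that("profile prediction maps compendium genes onto the views", {
  bm <- make_two_view_benchmark(n_arrays = 150, p_per_view = 25,
                                n_informative = 6, seed = 3)
  ens <- build_ensemble(two_view_specs()[[1]], bm$transcription,
                        bm$translation, seed = 0)
  vals <- t(cbind(bm$transcription$X, bm$translation$X))
  meta <- data.frame(array_id = colnames(vals), strain = "168",
                     medium = "LB", row.names = colnames(vals))
  comp <- structure(list(values = vals, gene_ids = rownames(vals),
                         array_meta = meta,
                         missing_mask = is.na(vals),
                         outlier_mask = vals != vals, provenance = NULL),
                    class = "expression_compendium")
  pred <- predict_growth_profiles(ens, comp)
  expect_length(pred, ncol(vals))
  expect_gt(cor(pred, bm$transcription$y), 0.8)

  # >50% unmappable features error
  small <- comp
  small$values <- vals[1:10, , drop = FALSE]
  expect_error(predict_growth_profiles(ens, small), "unmappable")

  # duplicated specs tie in the comparison table
  cmp <- compare_ensembles(list(two_view_specs()[[1]],
                                two_view_specs()[[1]]),
                           bm$transcription, bm$translation,
                           n_repeats = 2, seed0 = 0)
  expect_equal(cmp$mean_r2[1], cmp$mean_r2[2])
  expect_true(all(cmp$rank == 1L))
})

test_that("mismatched array ids are rejected with the differences listed", {
  bm <- make_two_view_benchmark(n_arrays = 30, p_per_view = 5,
                                n_informative = 3, seed = 4)
  other <- bm$translation
  rownames(other$X)[1] <- "zzz"
  expect_error(build_ensemble(two_view_specs()[[1]], bm$transcription,
                              other, seed = 0), "zzz")
})
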