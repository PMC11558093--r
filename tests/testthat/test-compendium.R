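make_meta <- function(ids) {
  data.frame(array_id = ids, strain = "168", medium = "LB",
             temperature = 37, pH = 7, stress = "none",
             perturbation = "none", row.names = ids)
}

test_that("harmonize_gene_ids merges synonyms and drops unmapped rows", {
  # identity map on an already-canonical table
  v <- matrix(1:4, 2, dimnames = list(c("BSU001", "BSU002"), c("a1", "a2")))
  t1 <- raw_expression_table(v, rownames(v), make_meta(c("a1", "a2")), "s1")
  idm <- data.frame(source_id = rownames(v), canonical_id = rownames(v))
  m <- harmonize_gene_ids(list(t1), idm)
  expect_equal(m$values, v)

  # synonym map across two tables with disjoint arrays
  va <- matrix(c(1, 2), 1, dimnames = list("g1", c("a1", "a2")))
  vb <- matrix(c(3, 4), 1, dimnames = list("gA", c("b1", "b2")))
  ta <- raw_expression_table(va, "g1", make_meta(c("a1", "a2")), "sA")
  tb <- raw_expression_table(vb, "gA", make_meta(c("b1", "b2")), "sB")
  idm2 <- data.frame(source_id = c("g1", "gA"),
                     canonical_id = c("BSU001", "BSU001"))
  m2 <- harmonize_gene_ids(list(ta, tb), idm2)
  expect_equal(rownames(m2$values), "BSU001")
  expect_equal(as.numeric(m2$values["BSU001", c("a1", "a2", "b1", "b2")]),
               c(1, 2, 3, 4))

  # unmapped id dropped and logged
  idm3 <- data.frame(source_id = "g1", canonical_id = "BSU001")
  m3 <- harmonize_gene_ids(list(ta, tb), idm3)
  expect_equal(attr(m3, "harmonize_log")$n_dropped, 1L)
  expect_equal(nrow(m3$values), 1L)

  # duplicate array ids across tables error
  tdup <- raw_expression_table(va, "g2", make_meta(c("a1", "a2")), "sC")
  expect_error(harmonize_gene_ids(list(ta, tdup), idm2), "duplicate array")

  # two sources mapping to one canonical id in the same array -> missing
  v1 <- matrix(c(1, 2), 2, 1, dimnames = list(c("g1", "g1b"), "x1"))
  tc <- raw_expression_table(v1, rownames(v1), make_meta("x1"), "sD")
  idm4 <- data.frame(source_id = c("g1", "g1b"),
                     canonical_id = c("BSU009", "BSU009"))
  m4 <- harmonize_gene_ids(list(tc), idm4)
  expect_true(is.na(m4$values["BSU009", "x1"]))
  expect_equal(attr(m4, "harmonize_log")$n_conflicts, 1L)
})

test_that("minmax_rescale maps rows to [0,1] with stated conventions", {
  expect_equal(as.numeric(minmax_rescale(matrix(c(1, 2, 3), 1))),
               c(0, 0.5, 1))
  expect_equal(as.numeric(minmax_rescale(matrix(c(5, 5, 5), 1))),
               c(0, 0, 0))
  r <- matrix(c(0, 0.25, 1), 1)
  expect_equal(as.numeric(minmax_rescale(r)), c(0, 0.25, 1))
  m <- rbind(gA = c(NA_real_, NA_real_), gB = c(1, 2))
  expect_error(minmax_rescale(m), "gA")
  # missing cells stay missing
  m2 <- minmax_rescale(matrix(c(1, NA, 3), 1))
  expect_true(is.na(m2[1, 2]))
})

test_that("flag_magnitude_outliers follows the log10-median rule", {
  m <- matrix(c(1, 1, 1, 1000), 1)
  expect_equal(as.logical(flag_magnitude_outliers(m, 2)),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_magnitude_outliers(matrix(c(1, 2, 3), 1), 2)))
  expect_false(any(flag_magnitude_outliers(m, 1e6)))
  expect_error(flag_magnitude_outliers(matrix(c(1, -1), 1)), "non-positive")
})

test_that("outlier mask is monotone in the threshold", {
  set.seed(7)
  m <- matrix(10^rnorm(200, sd = 1.5), 20)
  for (k in list(c(0.5, 1), c(1, 2), c(1.5, 3))) {
    m1 <- flag_magnitude_outliers(m, k[1])
    m2 <- flag_magnitude_outliers(m, k[2])
    expect_true(all(m1 | !m2))   # mask(k2) subset of mask(k1)
  }
})

test_that("random-forest imputation recovers a planted linear relation", {
  set.seed(3)
  n <- 50
  g1 <- runif(n, 1, 10)
  mat <- rbind(g1, 2 * g1,
               matrix(runif(8 * n, 1, 10), 8))
  rownames(mat) <- paste0("g", 1:10)
  target_col <- which.min(abs(g1 - median(g1)))
  truthv <- mat[2, target_col]
  mat[2, target_col] <- NA
  for (s in c(1, 2)) {
    imp <- impute_missing(mat, n_trees = 100, seed = s)
    expect_lt(abs(imp[2, target_col] - truthv) / truthv, 0.10)
  }
  # identity on complete input
  full <- matrix(runif(20), 4)
  expect_equal(impute_missing(full), full, ignore_attr = TRUE)
  # min_obs guard
  sparse <- matrix(c(1, NA, NA, NA, 2, 2, 2, 2), 2, byrow = TRUE)
  rownames(sparse) <- c("gX", "gY")
  expect_error(impute_missing(sparse), "gX")
})

test_that("normalize_pipeline applies the five stages in order", {
  v <- matrix(runif(40, 1, 10), 4,
              dimnames = list(paste0("BSU", 1:4), paste0("a", 1:10)))
  t1 <- raw_expression_table(v, rownames(v), make_meta(colnames(v)), "s1")
  idm <- data.frame(source_id = rownames(v), canonical_id = rownames(v))
  res <- normalize_pipeline(list(t1), idm)
  expect_true(all(res$compendium$values >= 0 & res$compendium$values <= 1))
  expect_equal(res$report$n_outliers_removed, 0L)
  expect_equal(res$report$n_imputed, 0L)
  expect_equal(res$report$stage_order,
               c("harmonize_gene_ids", "minmax_rescale",
                 "flag_magnitude_outliers", "impute_missing",
                 "minmax_rescale"))
})

test_that("planted outliers are detected and counted by the pipeline", {
  syn <- make_synthetic_compendium(organism = 30, n_arrays = 40,
                                   missing_frac = 0, outlier_frac = 0.03,
                                   seed = 11)
  res <- normalize_pipeline(syn$tables, syn$id_map, seed = 1)
  expect_equal(res$report$n_outliers_removed,
               nrow(syn$truth$outlier_positions))
  expect_gt(res$report$n_imputed, 0)   # outlier cells get imputed
})

test_that("clean synthetic data leaves masks empty", {
  syn <- make_synthetic_compendium(organism = 20, n_arrays = 30,
                                   missing_frac = 0, outlier_frac = 0,
                                   seed = 2)
  res <- normalize_pipeline(syn$tables, syn$id_map, seed = 1)
  expect_equal(sum(res$compendium$outlier_mask), 0L)
  expect_equal(sum(res$compendium$missing_mask), 0L)
})

test_that("condition_correlation matches the correlation formula", {
  syn <- make_synthetic_compendium(organism = 30, n_arrays = 40,
                                   missing_frac = 0, outlier_frac = 0,
                                   seed = 5)
  comp <- normalize_pipeline(syn$tables, syn$id_map, seed = 1)$compendium
  cc <- condition_correlation(comp, "medium", "LB")
  expect_true(all(abs(cc$pcc) <= 1 + 1e-12))
  # brute-force formula check on one group
  grp <- comp$array_meta$medium
  p_ref <- rowMeans(comp$values[, grp == "LB", drop = FALSE])
  g1 <- cc$group[1]
  p_g <- rowMeans(comp$values[, grp == g1, drop = FALSE])
  expect_equal(cc$pcc[1], pcc_formula(p_g, p_ref), tolerance = 1e-12)

  # identical and anticorrelated constructed groups
  v <- matrix(runif(200, 1, 5), 20,
              dimnames = list(paste0("g", 1:20), paste0("a", 1:10)))
  v[, 6:10] <- v[, 1:5]               # duplicate of reference
  meta <- make_meta(colnames(v))
  meta$medium <- rep(c("REF", "SAME"), each = 5)
  comp2 <- structure(list(values = v, gene_ids = rownames(v),
                          array_meta = meta,
                          missing_mask = is.na(v),
                          outlier_mask = v != v, provenance = NULL),
                     class = "expression_compendium")
  cc2 <- condition_correlation(comp2, "medium", "REF")
  expect_equal(cc2$pcc[cc2$group == "SAME"], 1)
  expect_true(cc2$flag[cc2$group == "SAME"])
  # noisy copy retains PCC > 0.8
  set.seed(9)
  v3 <- cbind(v[, 1:5], v[, 1:5] + matrix(rnorm(100, sd = 0.05), 20))
  colnames(v3) <- paste0("b", 1:10)
  meta3 <- make_meta(colnames(v3)); meta3$medium <- rep(c("REF", "NOISY"), each = 5)
  comp3 <- comp2; comp3$values <- v3; comp3$array_meta <- meta3
  cc3 <- condition_correlation(comp3, "medium", "REF")
  expect_gt(cc3$pcc[cc3$group == "NOISY"], 0.8)
})

test_that("differential expression calls planted shifts and is symmetric", {
  set.seed(21)
  ng <- 300; n1 <- 6; n2 <- 6
  base <- runif(ng, 3, 8)
  la <- base + matrix(rnorm(ng * n1, sd = 0.2), ng)
  lb <- base + matrix(rnorm(ng * n2, sd = 0.2), ng)
  shifted <- 1:30
  la[shifted, ] <- la[shifted, ] + 2
  vals <- cbind(2^la, 2^lb)
  rownames(vals) <- paste0("g", seq_len(ng))
  colnames(vals) <- paste0("a", seq_len(n1 + n2))
  de <- differential_expression(vals, 1:n1, n1 + (1:n2))
  expect_gte(sum(de$class[shifted] == "up"), 25)
  expect_equal(sum(de$class[-shifted] == "down"), 0)
  expect_equal(sum(de$class[-shifted] == "up"), 0)

  # swapping groups exchanges up and down exactly
  de_sw <- differential_expression(vals, n1 + (1:n2), 1:n1)
  expect_equal(de$class == "up", de_sw$class == "down")
  expect_equal(de$class == "down", de_sw$class == "up")

  # identical groups -> all unchanged
  de_id <- differential_expression(cbind(2^la, 2^la), 1:n1, n1 + (1:n1))
  expect_true(all(de_id$class == "unchanged"))
  # degenerate contrast
  expect_error(differential_expression(vals, 1:6, 6:8), "overlap")
})

test_that("compendium PCA returns scores and variance fractions", {
  syn <- make_synthetic_compendium(organism = 25, n_arrays = 30,
                                   missing_frac = 0, outlier_frac = 0,
                                   seed = 3)
  comp <- normalize_pipeline(syn$tables, syn$id_map, seed = 1)$compendium
  pca <- compendium_pca(comp, 3)
  expect_equal(dim(pca$scores), c(30L, 3L))
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
})
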