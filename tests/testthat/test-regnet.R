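test_that("network loading validates, collapses duplicates and round-trips", {
  tmp <- tempfile(fileext = ".tsv")
  ed <- data.frame(tf_id = c("TF1", "TF1", "TF2"),
                   operon_id = c("op1", "op1", "op2"),
                   target_gene_id = c("BSU1", "BSU1", "BSU2"),
                   sign = c("+", "+", "-"))
  write.table(ed, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(net <- load_network(tmp), "duplicate")
  expect_equal(nrow(net$edges), 2L)

  # round-trip of a clean 3-edge network
  ed3 <- data.frame(tf_id = paste0("TF", 1:3), operon_id = paste0("op", 1:3),
                    target_gene_id = paste0("BSU", 1:3),
                    sign = c("+", "-", "unknown"))
  net3 <- regulatory_network(ed3)
  tmp2 <- tempfile(fileext = ".tsv")
  write_network(net3, tmp2)
  net3b <- load_network(tmp2)
  cols <- c("tf_id", "operon_id", "target_gene_id", "sign")
  expect_equal(net3$edges[cols], net3b$edges[cols])

  # empty table -> empty network
  tmp3 <- tempfile(fileext = ".tsv")
  writeLines("tf_id\toperon_id\ttarget_gene_id\tsign", tmp3)
  expect_equal(nrow(load_network(tmp3)$edges), 0L)

  # malformed row errors with its line number
  tmp4 <- tempfile(fileext = ".tsv")
  writeLines(c("tf_id\toperon_id\ttarget_gene_id\tsign",
               "TF1\top1\tBSU1\t+", "TF2\top2\t\t-"), tmp4)
  expect_error(load_network(tmp4), "line 3")
})

test_that("regression recovers exact and planted coefficients", {
  # exact linear case: target = 2 * tf
  set.seed(1)
  tf <- runif(20)
  vals <- rbind(TF1 = tf, BSU1 = 2 * tf)
  net <- regulatory_network(data.frame(tf_id = "TF1", operon_id = "op1",
                                       target_gene_id = "BSU1", sign = "+"))
  fit <- fit_tf_gene_regression(vals, net)
  expect_equal(fit$beta, 2, tolerance = 1e-9)
  expect_gt(fit$confidence, 0.999)
  expect_equal(fit$class, "activation")

  # independent noise: small beta, low confidence
  set.seed(2)
  vals2 <- rbind(TF1 = rnorm(100), BSU1 = rnorm(100))
  f2 <- fit_tf_gene_regression(vals2, net)
  expect_lt(abs(f2$beta), 0.3)
  expect_lt(f2$confidence, 0.95)

  # two planted regulators recovered within 5%
  set.seed(3)
  n <- 500
  t1 <- runif(n); t2 <- runif(n)
  y <- 1 + 1.5 * t1 - 0.8 * t2 + rnorm(n, sd = 0.1)
  vals3 <- rbind(TFa = t1, TFb = t2, BSUy = y)
  net3 <- regulatory_network(data.frame(
    tf_id = c("TFa", "TFb"), operon_id = "op1",
    target_gene_id = "BSUy", sign = c("+", "-")))
  f3 <- fit_tf_gene_regression(vals3, net3)
  expect_equal(f3$beta[f3$tf_id == "TFa"], 1.5, tolerance = 0.05)
  expect_equal(f3$beta[f3$tf_id == "TFb"], -0.8, tolerance = 0.05)
  expect_equal(f3$class, c("activation", "repression"))
})

test_that("OLS invariances hold: array permutation and regressor scaling", {
  r <- make_regulatory_truth(n_tfs = 3, n_targets = 6, n_arrays = 80,
                             sigma = 0.05, seed = 4)
  f1 <- fit_tf_gene_regression(r$expression, r$network)
  perm <- sample(ncol(r$expression))
  f2 <- fit_tf_gene_regression(r$expression[, perm], r$network)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)

  scaled <- r$expression
  tf1 <- r$network$edges$tf_id[1]
  scaled[tf1, ] <- scaled[tf1, ] * 4
  f3 <- fit_tf_gene_regression(scaled, r$network)
  sel <- f1$tf_id == tf1
  expect_equal(f3$beta[sel], f1$beta[sel] / 4, tolerance = 1e-9)
})

test_that("collinear regressors are flagged unclassified", {
  set.seed(5)
  tf <- runif(30)
  vals <- rbind(TF1 = tf, TF2 = tf, BSU1 = 3 * tf + rnorm(30, sd = 0.01))
  net <- regulatory_network(data.frame(
    tf_id = c("TF1", "TF2"), operon_id = "op",
    target_gene_id = "BSU1", sign = "unknown"))
  f <- fit_tf_gene_regression(vals, net)
  expect_true(any(f$class == "unclassified"))
})

test_that("confident-edge classification counts activation and repression", {
  fits <- data.frame(
    tf_id = paste0("TF", 1:7), target_gene_id = paste0("g", 1:7),
    beta = c(1, 2, 3, -1, -2, 0.5, -0.5),
    stderr = 0.1,
    p_value = c(0.01, 0.02, 0.001, 0.01, 0.04, 0.5, 0.5))
  fits$confidence <- 1 - fits$p_value
  fits$class <- ifelse(fits$beta > 0, "activation", "repression")
  cl <- classify_confident_edges(fits, 0.95)
  expect_equal(cl$n_activation, 3L)
  expect_equal(cl$n_repression, 2L)
  # threshold 0 keeps everything
  cl0 <- classify_confident_edges(fits, 0)
  expect_equal(nrow(cl0$edges), 7L)
  # all p = 0.5 -> empty
  fits$confidence <- 0.5
  cl5 <- classify_confident_edges(fits, 0.95)
  expect_equal(nrow(cl5$edges), 0L)
})

test_that("planted network edges are recovered end to end", {
  r <- make_regulatory_truth(n_tfs = 6, n_targets = 25, n_arrays = 500,
                             sigma = 0.1, seed = 7)
  fits <- fit_tf_gene_regression(r$expression, r$network)
  key <- paste(fits$tf_id, fits$target_gene_id)
  tkey <- paste(r$truth$tf_id, r$truth$target_gene_id)
  beta_true <- r$truth$beta_true[match(key, tkey)]
  conf <- classify_confident_edges(fits, 0.95)$edges
  bt <- beta_true[match(paste(conf$tf_id, conf$target_gene_id), key)]
  sign_acc <- mean(sign(conf$beta) == sign(bt))
  expect_gte(sign_acc, 0.95)
})
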