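# Sparse group lasso by proximal gradient descent: the penalty combines a
# lasso term with a group-l2 term, so selection acts at both the feature and
# the group (operon / pathway) level.

#' Sparse-group-lasso feature selection
#'
#' Minimizes `(1/2n) ||y - X b||^2 +
#' lambda * (alpha_mix * ||b||_1 + (1 - alpha_mix) * sum_g sqrt(p_g) ||b_g||_2)`
#' by proximal gradient descent (soft-threshold then groupwise shrinkage)
#' with a Lipschitz step size, on standardized features and centred targets.
#'
#' @param ds an [ml_dataset()] (or list with `X`, `y`).
#' @param groups group label per feature (length = ncol(X)).
#' @param lambda penalty strength (>= 0).
#' @param alpha_mix lasso/group mixing in [0, 1] (default 0.95).
#' @param max_iter,tol iteration controls.
#' @return list with `selected` (feature names with nonzero coefficients),
#'   `beta` (named coefficients on the standardized scale), `n_iter`.
#' @export
sgl_select <- function(ds, groups, lambda, alpha_mix = 0.95,
                       max_iter = 2000, tol = 1e-7) {
  if (lambda < 0) stopf("lambda must be >= 0")
  X <- as.matrix(ds$X); y <- ds$y
  p <- ncol(X)
  if (length(groups) != p) stopf("groups must label every feature")
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, sdv, "/")
  yc <- y - mean(y)
  n <- nrow(Xs)
  # Lipschitz constant of the gradient: max eigenvalue of X'X / n
  L <- power_iter_eig(crossprod(Xs) / n)
  step <- 1 / max(L, 1e-8)
  g_idx <- split(seq_len(p), groups)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    grad <- crossprod(Xs, Xs %*% beta - yc) / n
    b <- beta - step * as.numeric(grad)
    # lasso prox
    b <- sign(b) * pmax(abs(b) - step * lambda * alpha_mix, 0)
    # group prox
    for (g in g_idx) {
      nrm <- sqrt(sum(b[g]^2))
      thr <- step * lambda * (1 - alpha_mix) * sqrt(length(g))
      b[g] <- if (nrm <= thr) 0 else b[g] * (1 - thr / nrm)
    }
    if (max(abs(b - beta)) < tol) {
      beta <- b
      break
    }
    beta <- b
  }
  names(beta) <- colnames(X)
  list(selected = colnames(X)[abs(beta) > 1e-10], beta = beta, n_iter = it)
}

power_iter_eig <- function(M, iters = 100) {
  v <- rep(1 / sqrt(ncol(M)), ncol(M))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(M %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) return(0)
    v <- v2 / nv
  }
  as.numeric(t(v) %*% M %*% v)
}
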