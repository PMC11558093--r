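# Brute-force oracles used across test files.

# Vertex-enumeration LP oracle for small problems with finite bounds:
# every vertex of {Ax = b, lb <= x <= ub} has n - m variables at a bound.
enumerate_lp <- function(obj, A, rhs, lb, ub, maximize = FALSE) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  best <- NULL; bestv <- if (maximize) -Inf else Inf
  feasible <- FALSE
  for (bs in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, bs, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nbs <- setdiff(seq_len(n), bs)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nbs)))
    if (length(nbs) == 0) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(nbs) > 0) {
        at_ub <- as.logical(grid[g, ])
        x[nbs] <- ifelse(at_ub, ub[nbs], lb[nbs])
      }
      xb <- solve(B, rhs - A[, nbs, drop = FALSE] %*% x[nbs])
      x[bs] <- xb
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      feasible <- TRUE
      v <- sum(obj * x)
      if ((maximize && v > bestv) || (!maximize && v < bestv)) {
        bestv <- v; best <- x
      }
    }
  }
  if (!feasible) return(list(status = "infeasible"))
  list(status = "optimal", x = best, obj = bestv)
}

# Plain-formula Pearson correlation (independent of stats::cor)
pcc_formula <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
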