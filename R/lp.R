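# Dense two-phase primal simplex with variable bounds.
#
# All flux-balance, variability and bisection solves in the ME module run
# through this kernel.  Problems are desk-scale (tens of rows, low hundreds
# of columns), so a full-tableau method with Bland's anti-cycling rule is
# both fast enough and numerically transparent.  Upper bounds are handled by
# explicit slack rows after shifting variables to zero lower bounds; rows are
# max-abs equilibrated before solving and the final basic solution and duals
# are re-solved against the unpivoted matrix for accuracy.

#' Solve a bounded linear program
#'
#' Solves `min (or max) obj'x` subject to `A x = rhs` and `lb <= x <= ub`.
#'
#' @param obj numeric objective vector (length n).
#' @param A constraint matrix (m x n), dense.
#' @param rhs right-hand side (length m).
#' @param lb,ub variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param maximize logical; maximize instead of minimize.
#' @param tol feasibility tolerance on the phase-1 objective (default 1e-9).
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `x` (primal solution), `obj` (objective value), `duals` (row duals,
#'   sign convention of the stated minimization), `residual`
#'   (`max|Ax - rhs|`).
#' @examples
#' # max x1 + x2 s.t. x1 + 2 x2 = 4, 0 <= x <= 3
#' lp_solve(c(1, 1), matrix(c(1, 2), 1), 4, c(0, 0), c(3, 3), maximize = TRUE)
#' @export
lp_solve <- function(obj, A, rhs, lb, ub, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n,
            length(ub) == n)
  if (any(!is.finite(lb))) stopf("lp_solve: lower bounds must be finite")
  if (any(ub < lb - 1e-12)) stopf("lp_solve: ub < lb for variable %d",
                                  which(ub < lb - 1e-12)[1])
  c0 <- if (maximize) -obj else obj

  # shift to z = x - lb >= 0; finite ranges get slack rows z_j + s_j = r_j
  b1 <- as.numeric(rhs - A %*% lb)
  r <- ub - lb
  fin <- which(is.finite(r))
  nb <- length(fin)
  Ae <- matrix(0, m + nb, n + nb)
  Ae[seq_len(m), seq_len(n)] <- A
  if (nb > 0) {
    for (k in seq_len(nb)) {
      Ae[m + k, fin[k]] <- 1
      Ae[m + k, n + k] <- 1
    }
  }
  be <- c(b1, r[fin])
  ce <- c(c0, rep(0, nb))

  # row equilibration
  rs <- apply(abs(Ae), 1, max)
  rs[rs < 1e-300] <- 1
  Ae <- Ae / rs
  be <- be / rs

  res <- simplex_two_phase(Ae, be, ce, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, obj = NA_real_,
                duals = NULL, residual = NA_real_))
  }
  z <- res$x[seq_len(n)]
  x <- z + lb
  # snap only round-off-sized bound violations; larger ones would trade a
  # bound violation for a mass-balance residual, so they are kept visible
  snap <- 1e-9
  x <- ifelse(x < lb & x > lb - snap, lb, x)
  x <- ifelse(x > ub & x < ub + snap, ub, x)
  objv <- sum(obj * x)
  duals <- res$y[seq_len(m)] / rs[seq_len(m)]
  if (maximize) duals <- -duals
  resid <- max(abs(A %*% x - rhs))
  list(status = "optimal", x = x, obj = objv, duals = as.numeric(duals),
       residual = resid)
}

# two-phase simplex on min c'z, Az = b, z >= 0 (dense tableau, Bland's rule)
simplex_two_phase <- function(A, b, cvec, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # phase 1: artificials with identity basis
  A1 <- cbind(A, diag(m))
  Tab <- cbind(A1, b)
  basis <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- simplex_iterate(Tab, basis, c1, ncols = n + m, tol = tol,
                         A0 = A1, b0 = b)
  if (ph1$status != "optimal") return(list(status = "infeasible"))
  Tab <- ph1$Tab; basis <- ph1$basis
  p1obj <- sum(c1[basis] * Tab[, ncol(Tab)])
  if (p1obj > 1e-10) return(list(status = "infeasible"))

  # drive artificials out of the basis; a stuck artificial marks its own
  # original row (artificial j <-> row j) as redundant, and both the
  # tableau row and that original row are dropped together
  keep <- rep(TRUE, m)                 # original rows retained
  keep_tab <- rep(TRUE, length(basis))
  for (i in seq_along(basis)) {
    if (basis[i] > n) {
      # the artificial is basic at (numerical) zero: zero it exactly and
      # demand a well-scaled pivot, else treat the row as redundant
      Tab[i, ncol(Tab)] <- 0
      piv <- which(abs(Tab[i, seq_len(n)]) > 1e-6)
      piv <- setdiff(piv, basis)
      if (length(piv) > 0) {
        Tab <- pivot_tableau(Tab, i, piv[1])
        basis[i] <- piv[1]
      } else {
        keep[basis[i] - n] <- FALSE
        keep_tab[i] <- FALSE
      }
    }
  }
  if (!all(keep_tab)) {
    Tab <- Tab[keep_tab, , drop = FALSE]
    basis <- basis[keep_tab]
  }

  # phase 2 on structural columns only
  A2 <- A[keep, , drop = FALSE]
  b2 <- b[keep]
  Tab2 <- Tab[, c(seq_len(n), n + m + 1), drop = FALSE]
  ph2 <- simplex_iterate(Tab2, basis, cvec, ncols = n, tol = tol,
                         A0 = A2, b0 = b2)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  Tab2 <- ph2$Tab; basis <- ph2$basis

  x <- numeric(n)
  # refine basic values against the original matrix for accuracy
  # (two rounds of iterative refinement keep ||Bx - b|| near round-off)
  B <- A[keep, basis, drop = FALSE]
  xb <- tryCatch({
    z <- solve(B, b[keep])
    for (ref in 1:2) z <- z + solve(B, b[keep] - as.numeric(B %*% z))
    z
  }, error = function(e) Tab2[, ncol(Tab2)])
  xb[xb < 0 & xb > -1e-9] <- 0
  x[basis] <- xb
  y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) rep(NA_real_, nrow(B)))
  yfull <- numeric(m)
  yfull[which(keep)] <- y
  yfull[neg] <- -yfull[neg]
  list(status = "optimal", x = x, y = yfull, basis = basis)
}

# Bland's rule pivoting on tableau Tab = [B^{-1}A | B^{-1}b]; the tableau
# is refactorized from the original (A0, b0) every `refactor` pivots and at
# termination, so round-off cannot accumulate into an invalid basis.
simplex_iterate <- function(Tab, basis, cvec, ncols, tol = 1e-9,
                            max_iter = NULL, A0 = NULL, b0 = NULL,
                            refactor = 40L) {
  m <- nrow(Tab)
  if (is.null(max_iter)) max_iter <- 500L * (m + ncols)
  last <- ncol(Tab)
  refactorize <- function(Tab, basis) {
    if (is.null(A0)) return(Tab)
    B <- A0[, basis, drop = FALSE]
    out <- tryCatch(solve(B, cbind(A0, b0)), error = function(e) NULL)
    if (is.null(out)) return(Tab)
    out[, last][abs(out[, last]) < 1e-11] <- 0
    out
  }
  since_ref <- 0L
  for (it in seq_len(max_iter)) {
    if (since_ref >= refactor) {
      Tab <- refactorize(Tab, basis)
      since_ref <- 0L
    }
    cb <- cvec[basis]
    zrow <- cvec[seq_len(ncols)] - as.numeric(crossprod(cb, Tab[, seq_len(ncols), drop = FALSE]))
    cand <- which(zrow < -1e-9)
    cand <- cand[!(cand %in% basis)]
    if (length(cand) == 0)
      return(list(status = "optimal", Tab = refactorize(Tab, basis),
                  basis = basis))
    j <- min(cand)                       # Bland: smallest index enters
    col <- Tab[, j]
    pos <- which(col > 1e-7)
    if (length(pos) == 0) return(list(status = "unbounded"))
    ratio <- pmax(Tab[pos, last], 0) / col[pos]  # clamp round-off negatives
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + 1e-10]
    i <- ties[which.min(basis[ties])]    # Bland: smallest basis index leaves
    Tab <- pivot_tableau(Tab, i, j)
    basis[i] <- j
    since_ref <- since_ref + 1L
  }
  list(status = "iteration_limit")
}

pivot_tableau <- function(Tab, i, j) {
  piv <- Tab[i, j]
  Tab[i, ] <- Tab[i, ] / piv
  others <- setdiff(seq_len(nrow(Tab)), i)
  Tab[others, ] <- Tab[others, , drop = FALSE] -
    outer(Tab[others, j], Tab[i, ])
  Tab[others, j] <- 0
  Tab
}
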