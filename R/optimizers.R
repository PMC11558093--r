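# Five hyperparameter search strategies over a declared space: exhaustive
# grid, uniform random, ant-colony sampling over a discretized lattice,
# Harris-Hawks population search, and Gaussian-process Bayesian optimization
# with expected improvement.  All operate on unit-cube coordinates that are
# decoded into typed parameter values.

decode_config <- function(u, space) {
  cfg <- list()
  for (j in seq_along(space)) {
    p <- space[[j]]
    v <- switch(p$type,
      int = as.integer(round(p$lower + u[j] * (p$upper - p$lower))),
      real = if (isTRUE(p$log))
        p$lower * (p$upper / p$lower)^u[j] else
          p$lower + u[j] * (p$upper - p$lower),
      choice = p$choices[[min(length(p$choices),
                              1L + floor(u[j] * length(p$choices)))]])
    cfg[[p$name]] <- v
  }
  cfg
}

levy_flight <- function(d, beta = 1.5) {
  num <- gamma(1 + beta) * sin(pi * beta / 2)
  den <- gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)
  sigma <- (num / den)^(1 / beta)
  u <- stats::rnorm(d, sd = sigma)
  v <- stats::rnorm(d)
  u / abs(v)^(1 / beta)
}

#' Search a hyperparameter space
#'
#' @param kind model family (used for the default space and CV evaluation).
#' @param method one of `"grid"`, `"random"`, `"aco"`, `"hho"`, `"bayes"`.
#' @param space parameter space (default [hp_space()] for `kind`).
#' @param budget maximum number of configuration evaluations (>= 1).
#' @param train training [ml_dataset()] for the default 5-fold CV objective
#'   (validation R-squared); ignored when `eval_fn` is given.
#' @param seed RNG seed; the whole search is deterministic per seed.
#' @param eval_fn optional objective `function(config) -> score` (higher is
#'   better), overriding the CV objective — used e.g. for surrogate
#'   benchmarks.
#' @param folds CV folds for the default objective (default 5).
#' @return list with `best_config`, `best_score` and `trace` (a data.frame
#'   with one row per evaluated configuration).
#' @export
optimize_hyperparams <- function(kind, method = c("grid", "random", "aco",
                                                  "hho", "bayes"),
                                 space = NULL, budget = 50, train = NULL,
                                 seed = 0, eval_fn = NULL, folds = 5) {
  method <- match.arg(method)
  space <- space %||% hp_space(kind)
  if (length(space) == 0) stopf("empty hyperparameter space")
  if (!is_count(budget) || budget < 1) stopf("budget must be >= 1")
  d <- length(space)

  if (is.null(eval_fn)) {
    if (is.null(train)) stopf("either train data or eval_fn required")
    n <- nrow(train$X)
    fold_id <- with_seed(seed + 104729L,
                         rep_len(seq_len(folds), n)[sample.int(n)])
    eval_fn <- function(config) {
      pred <- numeric(n)
      for (f in seq_len(folds)) {
        te <- fold_id == f
        pred[te] <- train_predict(kind, config,
                                  subset_ds(train, which(!te)),
                                  subset_ds(train, which(te)), seed = seed)
      }
      1 - sum((train$y - pred)^2) / sum((train$y - mean(train$y))^2)
    }
  }

  trace_u <- list(); trace_s <- numeric(0)
  evaluate <- function(u) {
    s <- eval_fn(decode_config(u, space))
    trace_u[[length(trace_u) + 1L]] <<- u
    trace_s[length(trace_s) + 1L] <<- s
    s
  }
  left <- function() budget - length(trace_s)

  with_seed(seed, {
    switch(method,
      grid = {
        sizes <- vapply(space, function(p)
          if (p$type == "choice") length(p$choices) else NA_integer_,
          integer(1))
        n_cont <- sum(is.na(sizes))
        prod_choice <- prod(sizes[!is.na(sizes)], 1)
        lev <- if (n_cont > 0)
          max(1L, floor((budget / prod_choice)^(1 / n_cont))) else 1L
        axes <- lapply(space, function(p) {
          if (p$type == "choice")
            (seq_along(p$choices) - 0.5) / length(p$choices)
          else if (lev == 1L) 0.5 else seq(0, 1, length.out = lev)
        })
        gridu <- as.matrix(expand.grid(axes))
        gridu <- gridu[seq_len(min(nrow(gridu), budget)), , drop = FALSE]
        for (i in seq_len(nrow(gridu))) evaluate(gridu[i, ])
      },
      random = {
        for (i in seq_len(budget)) evaluate(stats::runif(d))
      },
      aco = {
        n_levels <- vapply(space, function(p)
          if (p$type == "choice") length(p$choices) else 16L, integer(1))
        tau <- lapply(n_levels, function(L) rep(1, L))
        rho <- 0.1
        n_ants <- min(10L, budget)
        while (left() > 0) {
          gen_u <- list(); gen_s <- numeric(0)
          for (a in seq_len(min(n_ants, left()))) {
            levs <- vapply(seq_len(d), function(j)
              sample.int(n_levels[j], 1, prob = tau[[j]]), integer(1))
            u <- (levs - stats::runif(d)) / n_levels
            s <- evaluate(u)
            gen_u[[length(gen_u) + 1L]] <- levs
            gen_s[length(gen_s) + 1L] <- s
          }
          tau <- lapply(tau, function(t) (1 - rho) * t)
          best <- which.max(gen_s)
          for (j in seq_len(d))
            tau[[j]][gen_u[[best]][j]] <- tau[[j]][gen_u[[best]][j]] + 1
        }
      },
      hho = {
        n_pop <- min(10L, budget)
        pop <- matrix(stats::runif(n_pop * d), n_pop)
        fit <- apply(pop, 1, evaluate)
        while (left() > 0) {
          tmax <- max(1, ceiling(budget / n_pop))
          tcur <- length(trace_s) / n_pop
          E1 <- 2 * (1 - tcur / tmax)
          rb <- pop[which.max(fit), ]
          xm <- colMeans(pop)
          for (i in seq_len(n_pop)) {
            if (left() <= 0) break
            E <- E1 * stats::runif(1, -1, 1)
            J <- 2 * (1 - stats::runif(1))
            x <- pop[i, ]
            if (abs(E) >= 1) {
              if (stats::runif(1) >= 0.5) {
                xr <- pop[sample.int(n_pop, 1), ]
                xn <- xr - stats::runif(1) * abs(xr - 2 * stats::runif(1) * x)
              } else {
                xn <- (rb - xm) - stats::runif(1) * stats::runif(d)
              }
            } else if (stats::runif(1) >= 0.5) {
              xn <- if (abs(E) >= 0.5)
                (rb - x) - E * abs(J * rb - x) else
                  rb - E * abs(rb - x)
            } else {
              Y <- rb - E * abs(J * rb - x)
              Z <- Y + stats::runif(d) * levy_flight(d) * 0.01
              Y <- pmin(pmax(Y, 0), 1); Z <- pmin(pmax(Z, 0), 1)
              fy <- evaluate(Y)
              if (fy > fit[i]) { pop[i, ] <- Y; fit[i] <- fy }
              if (left() <= 0) break
              xn <- Z
            }
            xn <- pmin(pmax(xn, 0), 1)
            fn <- evaluate(xn)
            if (fn > fit[i]) { pop[i, ] <- xn; fit[i] <- fn }
          }
        }
      },
      bayes = {
        n_init <- min(max(4L, 2L * d), budget)
        U <- matrix(stats::runif(n_init * d), n_init)
        for (i in seq_len(n_init)) evaluate(U[i, ])
        ell <- 0.2 * sqrt(d); sf2 <- 1; sn2 <- 1e-6
        while (left() > 0) {
          Uo <- do.call(rbind, trace_u)
          s <- trace_s
          mu_s <- mean(s); sd_s <- max(stats::sd(s), 1e-8)
          z <- (s - mu_s) / sd_s
          K <- sf2 * exp(-as.matrix(stats::dist(Uo))^2 / (2 * ell^2)) +
            diag(sn2, nrow(Uo))
          Ki <- tryCatch(solve(K), error = function(e)
            solve(K + diag(1e-4, nrow(K))))
          alpha <- Ki %*% z
          cand <- matrix(stats::runif(256 * d), 256)
          D2 <- outer(rowSums(cand^2), rowSums(Uo^2), "+") -
            2 * cand %*% t(Uo)
          Ks <- sf2 * exp(-pmax(D2, 0) / (2 * ell^2))
          mu <- as.numeric(Ks %*% alpha)
          v <- sf2 - rowSums((Ks %*% Ki) * Ks)
          sdv <- sqrt(pmax(v, 1e-12))
          zbest <- max(z)
          imp <- mu - zbest - 0.01
          zz <- imp / sdv
          ei <- imp * stats::pnorm(zz) + sdv * stats::dnorm(zz)
          evaluate(cand[which.max(ei), ])
        }
      })
  })

  best <- which.max(trace_s)
  tr <- as.data.frame(do.call(rbind, lapply(trace_u, function(u)
    unlist(decode_config(u, space)))))
  tr$score <- trace_s
  list(best_config = decode_config(trace_u[[best]], space),
       best_score = trace_s[best], trace = tr)
}
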