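# Minimal 1-D convolutional and LSTM regressors with hand-derived gradients
# and Adam updates.  Sized for desk-scale expression matrices: the per-array
# feature vector is treated as a 1-D sequence in column (genome-coordinate)
# order; the CNN convolves it directly, the LSTM consumes it in chunks.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

clip_grads <- function(grads, max_norm = 5) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm)
    grads <- lapply(grads, function(g) g * max_norm / nrm)
  grads
}

std_fit <- function(X, y) {
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(x_mu = mu, x_sd = sdv, y_mu = mean(y),
       y_sd = max(stats::sd(y), 1e-8))
}
std_x <- function(sc, X) sweep(sweep(X, 2, sc$x_mu), 2, sc$x_sd, "/")

#' Fit a small 1-D convolutional regression network
#'
#' One valid-mode convolution layer (`filters` filters of width `kernel`)
#' with ReLU, flattened into a dense output unit; trained full-batch with
#' Adam on standardized inputs and targets.
#'
#' @param X array x feature matrix. @param y numeric targets.
#' @param filters,kernel,lr,epochs hyperparameters.
#' @param seed RNG seed for initialization.
#' @return fit object (class `cnn_fit`) with a `loss` history per epoch.
#' @export
cnn_fit <- function(X, y, filters = 4, kernel = 7, lr = 0.01, epochs = 30,
                    seed = 0) {
  X <- as.matrix(X)
  p <- ncol(X)
  kernel <- min(kernel, p)
  Tlen <- p - kernel + 1
  sc <- std_fit(X, y)
  Xs <- std_x(sc, X)
  ys <- (y - sc$y_mu) / sc$y_sd
  n <- nrow(Xs)
  with_seed(seed, {
    params <- list(
      Wc = matrix(stats::rnorm(kernel * filters, sd = 0.3), kernel),
      bc = numeric(filters),
      Wo = matrix(stats::rnorm(Tlen * filters, sd = 0.05), Tlen * filters, 1),
      bo = 0)
    st <- adam_init(params)
    loss <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      fw <- cnn_forward(Xs, params, Tlen, kernel, filters)
      err <- fw$pred - ys
      loss[ep] <- mean(err^2)
      dpred <- matrix(2 * err / n, n, 1)
      grads <- list(
        Wc = matrix(0, kernel, filters), bc = numeric(filters),
        Wo = crossprod(fw$flat, dpred), bo = sum(dpred))
      dflat <- dpred %*% t(params$Wo)
      for (f in seq_len(filters)) {
        cols <- ((f - 1) * Tlen + 1):(f * Tlen)
        dC <- dflat[, cols, drop = FALSE] * fw$mask[[f]]
        grads$bc[f] <- sum(dC)
        for (k in seq_len(kernel))
          grads$Wc[k, f] <- sum(Xs[, k:(k + Tlen - 1), drop = FALSE] * dC)
      }
      grads <- clip_grads(grads)
      upd <- adam_step(params, grads, st, lr)
      params <- upd$params; st <- upd$state
    }
    structure(list(params = params, scaler = sc, kernel = kernel,
                   filters = filters, Tlen = Tlen, loss = loss),
              class = "cnn_fit")
  })
}

cnn_forward <- function(Xs, params, Tlen, kernel, filters) {
  n <- nrow(Xs)
  flat <- matrix(0, n, Tlen * filters)
  mask <- vector("list", filters)
  for (f in seq_len(filters)) {
    C <- matrix(params$bc[f], n, Tlen)
    for (k in seq_len(kernel))
      C <- C + Xs[, k:(k + Tlen - 1), drop = FALSE] * params$Wc[k, f]
    mask[[f]] <- C > 0
    flat[, ((f - 1) * Tlen + 1):(f * Tlen)] <- pmax(C, 0)
  }
  pred <- as.numeric(flat %*% params$Wo + params$bo)
  list(flat = flat, mask = mask, pred = pred)
}

#' Predict from a fitted CNN
#' @param fit a `cnn_fit`. @param X feature matrix.
#' @return numeric predictions on the original target scale.
#' @export
cnn_predict <- function(fit, X) {
  Xs <- std_x(fit$scaler, as.matrix(X))
  fw <- cnn_forward(Xs, fit$params, fit$Tlen, fit$kernel, fit$filters)
  fw$pred * fit$scaler$y_sd + fit$scaler$y_mu
}

#' Fit a small LSTM regression network
#'
#' The feature vector is split into `chunk`-sized steps (zero-padded) and
#' fed through a single LSTM layer; the last hidden state drives a linear
#' output unit.  Full-batch backpropagation through time with Adam.
#'
#' @param X array x feature matrix. @param y numeric targets.
#' @param hidden,chunk,lr,epochs hyperparameters.
#' @param seed RNG seed.
#' @return fit object (class `lstm_fit`) with a `loss` history.
#' @export
lstm_fit <- function(X, y, hidden = 8, chunk = 10, lr = 0.02, epochs = 40,
                     seed = 0) {
  X <- as.matrix(X)
  p <- ncol(X)
  d <- min(chunk, p)
  Tlen <- ceiling(p / d)
  sc <- std_fit(X, y)
  Xs <- std_x(sc, X)
  if (Tlen * d > p) Xs <- cbind(Xs, matrix(0, nrow(Xs), Tlen * d - p))
  ys <- (y - sc$y_mu) / sc$y_sd
  n <- nrow(Xs); H <- hidden
  with_seed(seed, {
    params <- list(
      W = matrix(stats::rnorm(d * 4 * H, sd = 0.2), d),
      U = matrix(stats::rnorm(H * 4 * H, sd = 0.2), H),
      b = c(rep(0, H), rep(1, H), rep(0, 2 * H)),  # forget bias 1
      Wo = matrix(stats::rnorm(H, sd = 0.1), H, 1),
      bo = 0)
    st <- adam_init(params)
    loss <- numeric(epochs)
    idx <- lapply(seq_len(Tlen), function(t) ((t - 1) * d + 1):(t * d))
    sig <- function(z) 1 / (1 + exp(-z))
    for (ep in seq_len(epochs)) {
      h <- matrix(0, n, H); cc <- matrix(0, n, H)
      cache <- vector("list", Tlen)
      for (t in seq_len(Tlen)) {
        xt <- Xs[, idx[[t]], drop = FALSE]
        z <- xt %*% params$W + h %*% params$U +
          matrix(params$b, n, 4 * H, byrow = TRUE)
        i_g <- sig(z[, 1:H, drop = FALSE])
        f_g <- sig(z[, (H + 1):(2 * H), drop = FALSE])
        o_g <- sig(z[, (2 * H + 1):(3 * H), drop = FALSE])
        g_g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
        c_new <- f_g * cc + i_g * g_g
        tc <- tanh(c_new)
        cache[[t]] <- list(xt = xt, i = i_g, f = f_g, o = o_g, g = g_g,
                           c_prev = cc, h_prev = h, c = c_new, tc = tc)
        cc <- c_new
        h <- o_g * tc
      }
      pred <- as.numeric(h %*% params$Wo + params$bo)
      err <- pred - ys
      loss[ep] <- mean(err^2)
      dpred <- matrix(2 * err / n, n, 1)
      grads <- list(W = params$W * 0, U = params$U * 0, b = params$b * 0,
                    Wo = crossprod(h, dpred), bo = sum(dpred))
      dh <- dpred %*% t(params$Wo)
      dc <- matrix(0, n, H)
      for (t in rev(seq_len(Tlen))) {
        ch <- cache[[t]]
        do_g <- dh * ch$tc
        dct <- dc + dh * ch$o * (1 - ch$tc^2)
        di <- dct * ch$g
        df <- dct * ch$c_prev
        dg <- dct * ch$i
        dz <- cbind(di * ch$i * (1 - ch$i),
                    df * ch$f * (1 - ch$f),
                    do_g * ch$o * (1 - ch$o),
                    dg * (1 - ch$g^2))
        grads$W <- grads$W + crossprod(ch$xt, dz)
        grads$U <- grads$U + crossprod(ch$h_prev, dz)
        grads$b <- grads$b + colSums(dz)
        dh <- dz %*% t(params$U)
        dc <- dct * ch$f
      }
      grads <- clip_grads(grads)
      upd <- adam_step(params, grads, st, lr)
      params <- upd$params; st <- upd$state
    }
    structure(list(params = params, scaler = sc, hidden = H, chunk = d,
                   Tlen = Tlen, p = p, loss = loss), class = "lstm_fit")
  })
}

#' Predict from a fitted LSTM
#' @param fit an `lstm_fit`. @param X feature matrix.
#' @return numeric predictions on the original target scale.
#' @export
lstm_predict <- function(fit, X) {
  Xs <- std_x(fit$scaler, as.matrix(X))
  d <- fit$chunk; Tlen <- fit$Tlen; H <- fit$hidden
  if (Tlen * d > ncol(Xs)) Xs <- cbind(Xs, matrix(0, nrow(Xs),
                                                  Tlen * d - ncol(Xs)))
  n <- nrow(Xs)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  for (t in seq_len(Tlen)) {
    xt <- Xs[, ((t - 1) * d + 1):(t * d), drop = FALSE]
    z <- xt %*% fit$params$W + h %*% fit$params$U +
      matrix(fit$params$b, n, 4 * H, byrow = TRUE)
    i_g <- sig(z[, 1:H, drop = FALSE])
    f_g <- sig(z[, (H + 1):(2 * H), drop = FALSE])
    o_g <- sig(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g_g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f_g * cc + i_g * g_g
    h <- o_g * tanh(cc)
  }
  as.numeric(h %*% fit$params$Wo + fit$params$bo) * fit$scaler$y_sd +
    fit$scaler$y_mu
}
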