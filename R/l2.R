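# Conditional RBMs: the sequential (L2) layer.
#
# A cRBM is an RBM whose visible and hidden biases are shifted by linear
# functions of the last `tau` visible frames (the history), capturing
# temporal dependencies over a context of tau frames. The model bank spans
# contexts from 30 to 600 ms on the 10 ms frame clock.

#' Initialize conditional-RBM parameters
#'
#' @param n_visible Visible dimension (the number of L1 units feeding in).
#' @param n_hidden Hidden units per cRBM (300 in the full-scale bank).
#' @param tau Context length in frames (>= 1).
#' @param init_sd Initial weight scale; autoregressive weights start at zero.
#' @param seed RNG seed.
#' @return List of class `crbm_params`: `W` (n_visible x n_hidden), static
#'   biases `A`, `B`, and autoregressive matrices `C` ((n_visible * tau) x
#'   n_visible, history to visible) and `D` ((n_visible * tau) x n_hidden,
#'   history to hidden). The history vector is the concatenation of frames
#'   t-1, t-2, ..., t-tau.
#' @export
crbm_params <- function(n_visible, n_hidden = 300L, tau, init_sd = 0.01, seed = 1) {
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1 frame")
  set.seed(seed)
  structure(list(
    W = matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd), n_visible, n_hidden),
    A = numeric(n_visible),
    B = numeric(n_hidden),
    C = matrix(0, n_visible * tau, n_visible),
    D = matrix(0, n_visible * tau, n_hidden),
    tau = tau),
    class = "crbm_params")
}

#' Dynamic biases from the context history
#'
#' `a_hat = A + t(history) %*% C` and `b_hat = B + t(history) %*% D`; the
#' linear contribution of the last `tau` frames to the visible and hidden
#' biases.
#'
#' @param history Either a numeric vector of length `n_visible * tau` or a
#'   `tau` x `n_visible` matrix (most recent frame first); zero-pad at a
#'   sequence start.
#' @param params A `crbm_params`.
#' @return List with `a_hat` (length n_visible) and `b_hat` (length
#'   n_hidden).
#' @export
dynamic_biases <- function(history, params) {
  if (is.matrix(history)) {
    if (nrow(history) != params$tau) stop("history must hold exactly tau frames")
    history <- as.numeric(t(history))
  }
  if (length(history) != nrow(params$C)) stop("history must hold exactly tau frames")
  list(a_hat = params$A + drop(crossprod(history, params$C)),
       b_hat = params$B + drop(crossprod(history, params$D)))
}

#' Conditional-RBM energy
#'
#' `1/2 sum (x - a_hat)^2 - sum h * b_hat - t(x) %*% W %*% h`, with the
#' dynamic biases computed from the history. With zero history (or zero
#' autoregressive weights) this reduces to [rbm_energy()] with `(W, A, B)`.
#'
#' @param x Visible vector at time t.
#' @param h Binary hidden vector.
#' @param history See [dynamic_biases()].
#' @param params A `crbm_params`.
#' @return Scalar energy.
#' @export
crbm_energy <- function(x, h, history, params) {
  if (length(x) != nrow(params$W) || length(h) != ncol(params$W))
    stop("dimension mismatch")
  if (!all(h %in% c(0, 1))) stop("h must be binary")
  db <- dynamic_biases(history, params)
  0.5 * sum((x - db$a_hat)^2) - sum(h * db$b_hat) -
    drop(crossprod(x, params$W %*% h))
}

# history rows for the given time indices; lags never cross segment
# boundaries (frames from another segment are zeroed)
gather_history <- function(X, idx, tau, seg = NULL) {
  n_v <- ncol(X)
  H <- matrix(0, length(idx), n_v * tau)
  for (l in seq_len(tau)) {
    src <- idx - l
    ok <- src >= 1L
    if (!is.null(seg)) ok <- ok & seg[pmax(src, 1L)] == seg[idx]
    if (any(ok))
      H[ok, ((l - 1) * n_v + 1):(l * n_v)] <- X[src[ok], , drop = FALSE]
  }
  H
}

#' Train one conditional RBM
#'
#' CD-1 training on a stream (or list of streams) of standardized L1
#' responses. Histories are zero-padded at each sequence start and never span
#' two sequences.
#'
#' @param responses frames x n_visible matrix, or list of such matrices (one
#'   per training segment). Should already be standardized.
#' @param tau Context length in frames.
#' @param n_hidden Hidden units.
#' @param epochs,batch_size,lr,momentum CD hyperparameters (same recipe as
#'   [train_l1()]).
#' @param seed RNG seed.
#' @return A `crbm_params` with a training `log`.
#' @export
train_l2 <- function(responses, tau, n_hidden = 300L, epochs = 50L,
                     batch_size = 128L, lr = 1e-3, momentum = 0.9, seed = 1) {
  if (is.list(responses) && !is.matrix(responses)) {
    seg <- rep(seq_along(responses), vapply(responses, nrow, 1L))
    X <- do.call(rbind, responses)
  } else {
    X <- as.matrix(responses)
    seg <- rep(1L, nrow(X))
  }
  tau <- as.integer(tau)
  if (nrow(X) < tau + 1L) stop("response stream shorter than tau + 1 frames")
  params <- crbm_params(ncol(X), n_hidden, tau, seed = seed)
  set.seed(seed + 1L)
  vel <- list(W = 0 * params$W, A = 0 * params$A, B = 0 * params$B,
              C = 0 * params$C, D = 0 * params$D)
  log <- data.frame(epoch = integer(0), recon_error = numeric(0))
  n <- nrow(X)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    errs <- numeric(0)
    for (b in seq(1, n, by = batch_size)) {
      idx <- ord[b:min(b + batch_size - 1, n)]
      xb <- X[idx, , drop = FALSE]
      Hh <- gather_history(X, idx, tau, seg)
      a_hat <- sweep(Hh %*% params$C, 2, params$A, "+")
      b_hat <- sweep(Hh %*% params$D, 2, params$B, "+")
      ph <- stats::plogis(xb %*% params$W + b_hat)
      hs <- matrix(stats::runif(length(ph)) < ph, nrow = nrow(ph)) * 1
      x_neg <- hs %*% t(params$W) + a_hat
      nh <- stats::plogis(x_neg %*% params$W + b_hat)
      m <- nrow(xb)
      dW <- (crossprod(xb, ph) - crossprod(x_neg, nh)) / m
      dvis <- xb - x_neg
      dhid <- ph - nh
      dA <- colMeans(dvis)
      dB <- colMeans(dhid)
      dC <- crossprod(Hh, dvis) / m
      dD <- crossprod(Hh, dhid) / m
      if (!all(is.finite(dW))) stop("non-finite CD gradient in cRBM training")
      vel$W <- momentum * vel$W + lr * dW
      vel$A <- momentum * vel$A + lr * dA
      vel$B <- momentum * vel$B + lr * dB
      vel$C <- momentum * vel$C + lr * dC
      vel$D <- momentum * vel$D + lr * dD
      params$W <- params$W + vel$W
      params$A <- params$A + vel$A
      params$B <- params$B + vel$B
      params$C <- params$C + vel$C
      params$D <- params$D + vel$D
      errs <- c(errs, mean(dvis^2))
    }
    log <- rbind(log, data.frame(epoch = e, recon_error = mean(errs)))
  }
  params$log <- log
  params
}

#' Apply a cRBM (or a bank) linearly to an L1 response stream
#'
#' The trained sequential layer is applied deterministically: per frame the
#' output is the pre-sigmoid hidden drive
#' `t(W) %*% x(t) + b_hat(t)` with the dynamic hidden bias from the last tau
#' frames (zero-padded at the start). No sampling, no squashing.
#'
#' @param responses frames x n_visible matrix of (standardized) L1 responses.
#' @param params A `crbm_params`, or a list of them (a context bank).
#' @return frames x n_hidden matrix, or a named list of such matrices (names
#'   `tau_<frames>`).
#' @export
apply_l2 <- function(responses, params) {
  X <- as.matrix(responses)
  if (!inherits(params, "crbm_params")) {
    out <- lapply(params, function(p) apply_l2(X, p))
    names(out) <- paste0("tau_", vapply(params, function(p) p$tau, 1L))
    return(out)
  }
  Hh <- gather_history(X, seq_len(nrow(X)), params$tau)
  sweep(X %*% params$W + Hh %*% params$D, 2, params$B, "+")
}
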