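# Sparse Gaussian-Bernoulli RBM: the simultaneous (L1) layer.
#
# Energy: E(x, h) = 1/2 sum_k (x_k - A_k)^2 - sum_l B_l h_l - sum_kl x_k h_l w_kl
# Visible units are real-valued (unit-variance Gaussian), hidden units are
# Bernoulli. Trained by contrastive divergence with a cross-entropy sparsity
# penalty on the mean hidden activation.

#' Initialize RBM parameters
#'
#' @param n_visible Visible dimension (384 = 3 frames x 128 channels).
#' @param n_hidden Number of hidden units K (400 in the full-scale layer).
#' @param p Sparsity target: desired mean hidden activation, in (0, 1).
#' @param sparsity_cost Weight of the sparsity penalty gradient.
#' @param init_sd Standard deviation of the random initial weights.
#' @param seed RNG seed for the weight init.
#' @return List of class `rbm_params` with `W` (n_visible x n_hidden), `A`
#'   (visible biases), `B` (hidden biases), `p`, `sparsity_cost`.
#' @export
rbm_params <- function(n_visible = 384L, n_hidden = 400L, p = 0.05,
                       sparsity_cost = 0.1, init_sd = 0.01, seed = 1) {
  if (n_hidden < 1L) stop("need at least one hidden unit")
  if (p <= 0 || p >= 1) stop("sparsity target p must lie in (0, 1)")
  set.seed(seed)
  structure(list(
    W = matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd), n_visible, n_hidden),
    A = numeric(n_visible),
    B = numeric(n_hidden),
    p = p, sparsity_cost = sparsity_cost),
    class = "rbm_params")
}

#' RBM energy
#'
#' @param x Visible vector (real-valued).
#' @param h Hidden vector with entries in \{0, 1\}.
#' @param params An `rbm_params`.
#' @return Scalar energy
#'   `1/2 * sum((x - A)^2) - sum(B * h) - t(x) %*% W %*% h`.
#' @export
rbm_energy <- function(x, h, params) {
  if (length(x) != nrow(params$W) || length(h) != ncol(params$W))
    stop("dimension mismatch between x, h and params")
  if (!all(h %in% c(0, 1))) stop("h must be binary")
  0.5 * sum((x - params$A)^2) - sum(params$B * h) -
    drop(crossprod(x, params$W %*% h))
}

#' Hidden activation probabilities
#'
#' Logistic of the hidden pre-activation `t(x) %*% W + B` (the hidden bias is
#' included, matching the energy function).
#'
#' @param x Visible vector, or a matrix with one sample per row.
#' @param params An `rbm_params`.
#' @return Vector (or matrix) of probabilities in (0, 1).
#' @export
hidden_prob <- function(x, params) {
  if (is.matrix(x)) {
    stats::plogis(sweep(x %*% params$W, 2, params$B, "+"))
  } else {
    stats::plogis(drop(crossprod(x, params$W)) + params$B)
  }
}

#' Sparsity penalty (cross entropy to the target activation)
#'
#' `p * log(q) + (1 - p) * log(1 - q)`, maximized at `q == p`. `q` at the
#' boundary is clamped to `[eps, 1 - eps]` with `eps = 1e-7`.
#'
#' @param q Observed mean hidden activation(s).
#' @param p Sparsity target in (0, 1).
#' @return Penalty value(s) (non-positive scale, -Inf-avoiding).
#' @export
sparsity_penalty <- function(q, p) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  eps <- 1e-7
  q <- pmin(pmax(q, eps), 1 - eps)
  p * log(q) + (1 - p) * log(1 - q)
}

#' One contrastive-divergence update
#'
#' CD-k on a minibatch: positive-phase statistics from the data, negative
#' phase from k steps of alternating Gibbs sampling with a mean-field visible
#' reconstruction `x_hat = h %*% t(W) + A`. The hidden-bias update carries the
#' sparsity-penalty gradient `sparsity_cost * (p - q)`.
#'
#' @param batch Matrix of visible samples (rows), already standardized.
#' @param params An `rbm_params`.
#' @param k_steps Number of Gibbs steps (CD-k), >= 1.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient on the parameter velocity.
#' @param velocity Optional velocity list from the previous call.
#' @return List: updated `params`, `recon_error` (mean squared reconstruction
#'   error), `mean_q` (mean hidden activation), `velocity`, and `delta` (the
#'   raw gradient estimate, before momentum/lr).
#' @export
cd_step <- function(batch, params, k_steps = 1L, lr = 1e-3,
                    momentum = 0, velocity = NULL) {
  if (k_steps < 1L) stop("k_steps must be >= 1")
  if (!is.matrix(batch)) batch <- matrix(batch, nrow = 1)
  n <- nrow(batch)
  ph <- hidden_prob(batch, params)             # positive phase
  h <- matrix(stats::runif(length(ph)) < ph, nrow = n) * 1
  x_neg <- sweep(h %*% t(params$W), 2, params$A, "+")
  for (k in seq_len(k_steps)) {
    nh <- hidden_prob(x_neg, params)
    if (k < k_steps) {
      hs <- matrix(stats::runif(length(nh)) < nh, nrow = n) * 1
      x_neg <- sweep(hs %*% t(params$W), 2, params$A, "+")
    }
  }
  q <- colMeans(ph)
  dW <- (crossprod(batch, ph) - crossprod(x_neg, nh)) / n
  dA <- colMeans(batch) - colMeans(x_neg)
  dB <- q - colMeans(nh) + params$sparsity_cost * (params$p - q)
  if (!all(is.finite(dW)) || !all(is.finite(dA)) || !all(is.finite(dB)))
    stop("non-finite CD gradient; check input scaling")
  if (is.null(velocity))
    velocity <- list(W = 0 * params$W, A = 0 * params$A, B = 0 * params$B)
  velocity$W <- momentum * velocity$W + lr * dW
  velocity$A <- momentum * velocity$A + lr * dA
  velocity$B <- momentum * velocity$B + lr * dB
  params$W <- params$W + velocity$W
  params$A <- params$A + velocity$A
  params$B <- params$B + velocity$B
  list(params = params,
       recon_error = mean((batch - x_neg)^2),
       mean_q = mean(q),
       velocity = velocity,
       delta = list(W = dW, A = dA, B = dB))
}

#' Train the simultaneous (L1) layer
#'
#' Minibatch CD training of the sparse Gaussian-Bernoulli RBM on spectrogram
#' patches. Patches are standardized per dimension (the standardization is
#' stored with the parameters and re-applied at inference). Fully
#' deterministic given `seed`.
#'
#' @param patches A `patch_set` (see [extract_patches()]) or a samples x 384
#'   matrix.
#' @param n_hidden Number of hidden units K.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param k_steps CD-k Gibbs steps.
#' @param p,sparsity_cost Sparsity target and penalty weight.
#' @param seed RNG seed (init, shuffling, sampling).
#' @return An `rbm_params` with extra fields `center`, `scale` (patch
#'   standardization) and `log` (per-epoch reconstruction error and mean
#'   hidden activation).
#' @export
train_l1 <- function(patches, n_hidden = 400L, epochs = 50L, batch_size = 128L,
                     lr = 1e-3, momentum = 0.9, k_steps = 1L,
                     p = 0.05, sparsity_cost = 0.1, seed = 1) {
  X <- if (inherits(patches, "patch_set")) patches$patches else as.matrix(patches)
  if (nrow(X) == 0L) stop("empty training set")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  X <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  params <- rbm_params(ncol(X), n_hidden, p, sparsity_cost, seed = seed)
  set.seed(seed + 1L)
  vel <- NULL
  log <- data.frame(epoch = integer(0), recon_error = numeric(0),
                    mean_q = numeric(0))
  n <- nrow(X)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    errs <- qs <- numeric(0)
    for (b in seq(1, n, by = batch_size)) {
      idx <- ord[b:min(b + batch_size - 1, n)]
      st <- cd_step(X[idx, , drop = FALSE], params, k_steps, lr, momentum, vel)
      params <- st$params; vel <- st$velocity
      errs <- c(errs, st$recon_error); qs <- c(qs, st$mean_q)
    }
    log <- rbind(log, data.frame(epoch = e, recon_error = mean(errs),
                                 mean_q = mean(qs)))
  }
  params$center <- center
  params$scale <- scale
  params$log <- log
  params
}

#' Reshape RBM weights into 2-D spectro-temporal filters
#'
#' Each hidden unit's weight column becomes a 3 (time) x 128 (frequency)
#' filter F(t, f), inverting the patch flattening of [extract_patches()].
#'
#' @param params An `rbm_params`.
#' @param n_channels Number of frequency channels per frame (128).
#' @return A 3-D array of class `l1_filterbank`, dim `c(3, n_channels, K)`.
#' @export
weights_to_filters <- function(params, n_channels = nrow(params$W) / 3L) {
  n_t <- nrow(params$W) / n_channels
  F <- array(0, c(n_t, n_channels, ncol(params$W)))
  for (k in seq_len(ncol(params$W)))
    F[, , k] <- matrix(params$W[, k], n_t, n_channels, byrow = TRUE)
  structure(F, class = c("l1_filterbank", "array"))
}

#' Apply L1 filters convolutionally to a spectrogram
#'
#' Computes the raw L1 responses
#' `r_k(t) = sum_f sum_tau S(tau, f) F_k(t - tau, f)`:
#' convolution along time, full summation over frequency, "same" output
#' length with zero-padded edges. Equivalent to projecting the (standardized)
#' 3-frame patch ending at `t` onto each weight column.
#'
#' @param spec An `auditory_spectrogram` (>= 3 frames) or plain matrix.
#' @param params An `rbm_params` (its `center`/`scale`, when present, are
#'   applied to each patch) or an `l1_filterbank` for raw, unstandardized
#'   filtering.
#' @return frames x K matrix of raw responses.
#' @export
apply_l1 <- function(spec, params) {
  S <- unclass(spec)
  if (inherits(params, "l1_filterbank")) {
    K <- dim(params)[3]
    W <- matrix(0, dim(params)[1] * dim(params)[2], K)
    for (k in seq_len(K)) W[, k] <- as.numeric(t(params[, , k]))
    center <- NULL; scale <- NULL
  } else {
    W <- params$W
    center <- params$center; scale <- params$scale
  }
  n <- nrow(S)
  Sp <- rbind(matrix(0, 2, ncol(S)), S)          # zero-padded leading edge
  P <- cbind(Sp[1:n, , drop = FALSE],
             Sp[2:(n + 1), , drop = FALSE],
             Sp[3:(n + 2), , drop = FALSE])
  if (!is.null(center))
    P <- sweep(sweep(P, 2, center, "-"), 2, scale, "/")
  P %*% W
}

#' Synaptic adaptation of L1 responses
#'
#' Closed-loop divisive adaptation: a per-unit gain `a(t)` obeying
#' `da/dt = (1 - a)/tau_a - alpha * a * r(t)`, integrated exactly over each
#' 10 ms frame (piecewise-constant input), with output `a(t) * r(t)`. The
#' gain starts at 1 and stays in (0, 1\] for non-negative inputs; for a
#' constant input `c` it converges to `a* = 1 / (1 + tau_a * alpha * c)`.
#'
#' @param raw frames x K matrix of non-negative (rectified) raw responses.
#' @param tau_a Recovery time constant in seconds (0.300).
#' @param alpha Synaptic utilization parameter (1e-5).
#' @param dt Frame step in seconds (0.010).
#' @return List: `values` (adapted responses `a * raw`) and `a` (the gain
#'   trajectory).
#' @export
adapt <- function(raw, tau_a = 0.300, alpha = 1e-5, dt = 0.010) {
  if (!is.matrix(raw)) raw <- matrix(raw, ncol = 1)
  n <- nrow(raw)
  a <- matrix(1, n, ncol(raw))
  cur <- rep(1, ncol(raw))
  for (t in seq_len(n)) {
    lam <- 1 / tau_a + alpha * raw[t, ]
    ainf <- (1 / tau_a) / lam
    cur <- ainf + (cur - ainf) * exp(-lam * dt)
    cur <- pmin(pmax(cur, .Machine$double.eps), 1)
    a[t, ] <- cur
  }
  list(values = a * raw, a = a)
}
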