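# Temporal-coherence (L3) layer: a Hebbian synaptic matrix V accumulated
# from co-activations of L2 channels and applied multiplicatively,
# R_hat_t = R_t V_t. Responses are centered by a causal moving average before
# the outer product so that anti-correlated channels weaken their
# connection; a multiplicative leak keeps V bounded.

#' Initialize a coherence matrix
#'
#' @param m Number of channels (L2 hidden units within one context).
#' @param leak Per-step multiplicative decay in (0, 1\].
#' @return An `m` x `m` identity matrix of class `coherence_matrix` with a
#'   `leak` attribute (identity start = no prior binding).
#' @export
coherence_matrix <- function(m, leak = 0.99) {
  if (leak <= 0 || leak > 1) stop("leak must lie in (0, 1]")
  structure(diag(m), leak = leak, class = c("coherence_matrix", "matrix", "array"))
}

#' One Hebbian coherence update
#'
#' `V <- leak * V + r %*% t(r)`: co-active (same-signed, centered) channels
#' strengthen their connection, anti-correlated channels weaken it. Symmetry
#' is preserved.
#'
#' @param V A `coherence_matrix` (or plain symmetric matrix).
#' @param r_t Centered response vector at time t.
#' @param leak Leak override (defaults to the matrix's attribute, else 1).
#' @return Updated matrix (attributes preserved).
#' @export
update_coherence <- function(V, r_t, leak = attr(V, "leak")) {
  if (!all(is.finite(r_t))) stop("non-finite response vector")
  if (length(r_t) != nrow(V)) stop("dimension mismatch")
  if (is.null(leak)) leak <- 1
  out <- leak * unclass(V) + tcrossprod(r_t)
  attributes(out) <- attributes(V)
  out
}

#' Apply coherence weights to a response stream
#'
#' Row t of the output is `R[t, ] %*% V_t`.
#'
#' @param R frames x m response matrix.
#' @param V A single matrix (applied to every frame) or a list of per-frame
#'   matrices.
#' @return frames x m weighted responses.
#' @export
apply_coherence <- function(R, V) {
  R <- as.matrix(R)
  if (is.list(V)) {
    if (length(V) != nrow(R)) stop("need one V per frame")
    out <- R
    for (t in seq_len(nrow(R))) out[t, ] <- R[t, , drop = FALSE] %*% V[[t]]
    out
  } else {
    if (ncol(R) != nrow(V)) stop("dimension mismatch")
    R %*% V
  }
}

#' Run the temporal-coherence layer over a response stream
#'
#' Causally accumulates the Hebbian matrix from responses centered by a
#' moving average over `window` frames (the channel's context length), and
#' applies it frame by frame: `R_hat[t, ] = R[t, ] %*% V_t`, with `V_t`
#' updated from the centered response at t.
#'
#' @param R frames x m response matrix (one L2 context block).
#' @param leak Per-step decay of V.
#' @param window Centering window in frames.
#' @param keep_v Return the per-frame V snapshots? (memory-heavy; default
#'   keeps only the final matrix).
#' @return List: `values` (the weighted responses), `V` (final coherence
#'   matrix), optionally `V_t` (list of snapshots).
#' @export
run_coherence <- function(R, leak = 0.99, window = 6L, keep_v = FALSE) {
  R <- as.matrix(R)
  n <- nrow(R); m <- ncol(R)
  V <- coherence_matrix(m, leak)
  out <- matrix(0, n, m)
  snaps <- if (keep_v) vector("list", n) else NULL
  csum <- matrix(0, n + 1, m)
  csum[-1, ] <- apply(R, 2, cumsum)
  for (t in seq_len(n)) {
    w0 <- max(0L, t - window)
    mu <- (csum[t + 1, ] - csum[w0 + 1, ]) / (t - w0)
    V <- update_coherence(V, R[t, ] - mu)
    out[t, ] <- R[t, , drop = FALSE] %*% unclass(V)
    if (keep_v) snaps[[t]] <- unclass(V)
  }
  res <- list(values = out, V = V)
  if (keep_v) res$V_t <- snaps
  res
}
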