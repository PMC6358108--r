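# Independent oracles used across the suite.

# Exact maximum-likelihood gradient of a tiny Gaussian-Bernoulli RBM by
# enumerating all hidden states: P(h) ~ exp(B.h + A'Wh + ||Wh||^2/2),
# E[x|h] = A + Wh.
exact_rbm_gradient <- function(X, par) {
  K <- ncol(par$W)
  hs <- as.matrix(expand.grid(rep(list(0:1), K)))
  lw <- apply(hs, 1, function(h)
    sum(par$B * h) + sum(par$A * (par$W %*% h)) + 0.5 * sum((par$W %*% h)^2))
  p <- exp(lw - max(lw))
  p <- p / sum(p)
  Exh <- matrix(0, nrow(par$W), K)
  Eh <- numeric(K)
  Ex <- numeric(nrow(par$W))
  for (i in seq_len(nrow(hs))) {
    h <- hs[i, ]
    mu <- par$A + drop(par$W %*% h)
    Exh <- Exh + p[i] * outer(mu, h)
    Eh <- Eh + p[i] * h
    Ex <- Ex + p[i] * mu
  }
  ph <- hidden_prob(X, par)
  list(W = crossprod(X, ph) / nrow(X) - Exh,
       A = colMeans(X) - Ex,
       B = colMeans(ph) - Eh)
}

# normal quantile by root finding on the distribution function, independent
# of qnorm()
probit_root <- function(p) {
  stats::uniroot(function(z) stats::pnorm(z) - p, c(-10, 10),
                 tol = 1e-10)$root
}

# tiny deterministic spectrogram-like matrix
toy_spec <- function(frames = 10, channels = 8, seed = 1) {
  set.seed(seed)
  matrix(abs(stats::rnorm(frames * channels)), frames, channels)
}

# cosine similarity between two arrays
cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
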