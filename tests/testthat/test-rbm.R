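test_that("RBM energy matches its closed form", {
  par <- rbm_params(4, 3, seed = 1)
  par$A <- c(0.5, -1, 0, 2)
  par$B <- c(0.3, -0.2, 0.1)

  expect_equal(rbm_energy(par$A, rep(0, 3), par), 0)

  par1 <- rbm_params(1, 2, seed = 1)
  expect_equal(rbm_energy(1, c(0, 0), par1), 0.5)

  # toggling hidden unit l changes E by -B_l - sum_k x_k w_kl
  x <- c(1, -2, 0.5, 1.5)
  h0 <- c(0, 1, 0)
  h1 <- c(0, 1, 1)
  expect_equal(rbm_energy(x, h1, par) - rbm_energy(x, h0, par),
               -par$B[3] - sum(x * par$W[, 3]))

  # per-unit additivity: E(x, h) - E(x, 0) is linear in h
  dE <- vapply(1:3, function(l) {
    e <- rep(0, 3); e[l] <- 1
    rbm_energy(x, e, par) - rbm_energy(x, rep(0, 3), par)
  }, 1)
  expect_equal(rbm_energy(x, c(1, 1, 1), par) - rbm_energy(x, rep(0, 3), par),
               sum(dE))

  expect_error(rbm_energy(c(1, 2), c(0, 1, 0), par), "mismatch")
  expect_error(rbm_energy(x, c(0.5, 0, 1), par), "binary")
})

test_that("hidden activation is the logistic of the biased pre-activation", {
  par <- rbm_params(3, 2, seed = 2)
  par$B <- c(0, 0)
  # x orthogonal to both weight columns, zero bias -> 0.5
  W <- cbind(c(1, 0, 0), c(0, 1, 0))
  par$W <- W
  expect_equal(hidden_prob(c(0, 0, 5), par), c(0.5, 0.5))
  # logistic(ln 3) = 0.75
  par$B <- c(log(3), 0)
  expect_equal(hidden_prob(c(0, 0, 1), par)[1], 0.75)
  # monotone in x . w
  par$B <- c(0, 0)
  probs <- vapply(seq(-2, 2, by = 0.5),
                  function(a) hidden_prob(c(a, 0, 0), par)[1], 1)
  expect_true(all(diff(probs) > 0))
})

test_that("sparsity penalty is the cross entropy, maximized at q = p", {
  expect_equal(sparsity_penalty(0.5, 0.5), log(0.5), tolerance = 1e-12)
  qs <- seq(0.01, 0.99, by = 0.01)
  pen <- sparsity_penalty(qs, 0.2)
  expect_equal(qs[which.max(pen)], 0.2)
  # boundary clamp keeps the penalty finite
  expect_true(is.finite(sparsity_penalty(0, 0.3)))
  expect_lt(sparsity_penalty(1e-9, 0.3), -4)
})

test_that("CD update vanishes for a zero model on zero data", {
  par <- rbm_params(4, 3, init_sd = 0, sparsity_cost = 0, seed = 1)
  batch <- matrix(0, 8, 4)
  st <- cd_step(batch, par, lr = 0.1)
  expect_equal(st$params$W, par$W)
  expect_equal(st$params$A, par$A)
  expect_equal(st$params$B, par$B)
  expect_equal(st$recon_error, 0)
})

test_that("expected CD direction matches the enumerated exact gradient", {
  set.seed(42)
  par <- rbm_params(3, 2, p = 0.5, sparsity_cost = 0, init_sd = 0.3, seed = 7)
  par$A <- c(0.2, -0.1, 0.3)
  par$B <- c(0.1, -0.2)
  X <- rbind(matrix(stats::rnorm(150, 1, 0.5), ncol = 3),
             matrix(stats::rnorm(150, -1, 0.5), ncol = 3))
  eg <- exact_rbm_gradient(X, par)
  avg_delta <- function(k) {
    acc <- matrix(0, 3, 2)
    set.seed(99)
    for (r in 1:300) acc <- acc + cd_step(X, par, k_steps = k, lr = 1)$delta$W
    acc / 300
  }
  c1 <- cosine(avg_delta(1), eg$W)
  c10 <- cosine(avg_delta(10), eg$W)
  expect_gt(c1, 0.9)
  expect_gte(c10, c1 - 0.02)   # longer chains do not drift away
})

test_that("L1 training is seeded-deterministic and reduces reconstruction error", {
  X <- toy_spec(80, 12, seed = 3)
  X <- cbind(X, X, X)[, 1:36]
  m1 <- train_l1(X, n_hidden = 8, epochs = 20, batch_size = 16, seed = 5)
  m2 <- train_l1(X, n_hidden = 8, epochs = 20, batch_size = 16, seed = 5)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$log, m2$log)
  expect_lt(m1$log$recon_error[20], m1$log$recon_error[1])
})

test_that("the sparsity penalty drives mean hidden activation toward its target", {
  set.seed(11)
  X <- matrix(stats::rnorm(200 * 20), 200, 20)
  m <- train_l1(X, n_hidden = 10, epochs = 60, batch_size = 32,
                p = 0.1, sparsity_cost = 5, lr = 5e-3, seed = 4)
  q <- utils::tail(m$log$mean_q, 1)
  expect_gt(q, 0.05)
  expect_lt(q, 0.15)
})

test_that("default simultaneous-layer width matches the architecture", {
  expect_equal(eval(formals(train_l1)$n_hidden), 400L)
  expect_equal(eval(formals(stream_config)$n_hidden_l1), 400L)
})

test_that("weight columns reshape to 3 x 128 filters and back", {
  par <- rbm_params(384, 5, seed = 9)
  F <- weights_to_filters(par)
  expect_equal(dim(F), c(3L, 128L, 5L))
  for (k in 1:5)
    expect_identical(as.numeric(t(F[, , k])), par$W[, k])
  # a single nonzero at (frame 2, channel 60)
  par$W[, 2] <- 0
  par$W[128 + 60, 2] <- 7
  F <- weights_to_filters(par)
  expect_equal(F[2, 60, 2], 7)
  expect_equal(sum(F[, , 2] != 0), 1L)
})

test_that("convolutional application obeys sifting and linearity", {
  S <- toy_spec(20, 128, seed = 4)
  # impulse filter at the current frame, channel 10 -> r(t) = S(t, 10)
  par <- rbm_params(384, 2, init_sd = 0, seed = 1)
  par$W[2 * 128 + 10, 1] <- 1          # (dt = 0) block
  par$W[10, 2] <- 1                    # (dt = -2) block
  r <- apply_l1(S, par)
  expect_equal(r[, 1], S[, 10])
  expect_equal(r[3:20, 2], S[1:18, 10])
  expect_equal(r[1:2, 2], c(0, 0))     # zero-padded edge

  # zero input -> zero response; linearity
  expect_true(all(apply_l1(matrix(0, 10, 128), par) == 0))
  S2 <- toy_spec(20, 128, seed = 8)
  expect_equal(apply_l1(2 * S + 3 * S2, par),
               2 * apply_l1(S, par) + 3 * apply_l1(S2, par))
})

test_that("a matched filter responds maximally at the aligned lag", {
  set.seed(21)
  S <- matrix(0, 30, 128)
  patch <- matrix(abs(stats::rnorm(3 * 128)), 3, 128)
  S[14:16, ] <- patch
  par <- rbm_params(384, 1, init_sd = 0, seed = 1)
  par$W[, 1] <- c(t(patch))
  r <- apply_l1(S, par)
  expect_equal(which.max(r), 16L)
})

test_that("adaptation relaxes, saturates at the closed-form gain, and never amplifies", {
  # zero input: gain recovers to 1, output stays 0
  out <- adapt(matrix(0, 50, 2))
  expect_true(all(out$values == 0))
  expect_equal(out$a[50, ], c(1, 1))

  # constant input: simulated gain converges to a* = 1/(1 + tau_a alpha c)
  c0 <- 60
  out <- adapt(matrix(c0, 3000, 1), tau_a = 0.3, alpha = 0.01)
  expect_equal(out$a[3000, 1], 1 / (1 + 0.3 * 0.01 * c0), tolerance = 1e-6)

  # steady-state gain strictly decreasing in the input level
  ss <- vapply(c(10, 50, 100, 500), function(cc)
    adapt(matrix(cc, 2000, 1), alpha = 0.01)$a[2000, 1], 1)
  expect_true(all(diff(ss) < 0))

  # |r| <= |r_hat|
  set.seed(3)
  raw <- matrix(abs(stats::rnorm(200)), 100, 2)
  out <- adapt(raw, alpha = 0.05)
  expect_true(all(out$values <= raw + 1e-12))
  expect_true(all(out$a > 0 & out$a <= 1))
})
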