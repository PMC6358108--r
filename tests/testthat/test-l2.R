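test_that("dynamic biases are linear in the history and reduce statically", {
  par <- crbm_params(4, 3, tau = 2, seed = 1)
  par$A <- c(1, 2, 3, 4); par$B <- c(-1, 0, 1)
  h0 <- rep(0, 8)

  db <- dynamic_biases(h0, par)            # zero history
  expect_equal(db$a_hat, par$A)
  expect_equal(db$b_hat, par$B)

  set.seed(2)
  par$C <- matrix(stats::rnorm(8 * 4), 8, 4)
  par$D <- matrix(stats::rnorm(8 * 3), 8, 3)
  h <- stats::rnorm(8)
  d1 <- dynamic_biases(h, par)
  d2 <- dynamic_biases(2 * h, par)
  expect_equal(d2$a_hat - par$A, 2 * (d1$a_hat - par$A))
  expect_equal(d2$b_hat - par$B, 2 * (d1$b_hat - par$B))

  parz <- par; parz$C[] <- 0; parz$D[] <- 0   # C = D = 0 -> static
  dz <- dynamic_biases(h, parz)
  expect_equal(dz$a_hat, par$A)
  expect_equal(dz$b_hat, par$B)

  expect_error(dynamic_biases(stats::rnorm(7), par), "tau")
})

test_that("conditional energy matches its closed form and the static RBM", {
  par <- crbm_params(4, 3, tau = 2, seed = 3)
  par$A <- c(0.5, -1, 0, 1); par$B <- c(0.2, 0, -0.2)
  h0 <- rep(0, 8)

  expect_equal(crbm_energy(par$A, rep(0, 3), h0, par), 0)

  rpar <- rbm_params(4, 3, seed = 1)
  rpar$W <- par$W; rpar$A <- par$A; rpar$B <- par$B
  x <- c(1, 0.5, -0.3, 2); h <- c(1, 0, 1)
  expect_equal(crbm_energy(x, h, h0, par), rbm_energy(x, h, rpar))

  # toggling one hidden unit changes E by -b_hat_l - sum_k W_kl x_k
  set.seed(4)
  par$C <- matrix(stats::rnorm(32), 8, 4); par$D <- matrix(stats::rnorm(24), 8, 3)
  hist <- stats::rnorm(8)
  bh <- dynamic_biases(hist, par)$b_hat
  e0 <- crbm_energy(x, c(1, 0, 0), hist, par)
  e1 <- crbm_energy(x, c(1, 0, 1), hist, par)
  expect_equal(e1 - e0, -bh[3] - sum(x * par$W[, 3]))
})

test_that("cRBM training is deterministic and has the documented width", {
  expect_equal(eval(formals(train_l2)$n_hidden), 300L)
  set.seed(6)
  X <- matrix(stats::rnorm(300 * 6), 300, 6)
  m1 <- train_l2(X, tau = 3, n_hidden = 4, epochs = 3, batch_size = 64, seed = 2)
  m2 <- train_l2(X, tau = 3, n_hidden = 4, epochs = 3, batch_size = 64, seed = 2)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$C, m2$C)
  expect_error(train_l2(X[1:3, ], tau = 3, n_hidden = 4), "tau")
})

test_that("autoregressive weights grow on temporally structured input", {
  # strongly autocorrelated vs white input of matched scale
  norms <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 400
    ar <- apply(matrix(stats::rnorm(n * 5), n, 5), 2,
                function(e) as.numeric(stats::filter(e, 0.95, "recursive")))
    ar <- scale(ar)
    wh <- matrix(stats::rnorm(n * 5), n, 5)
    ma <- train_l2(ar, tau = 2, n_hidden = 4, epochs = 5, lr = 5e-3, seed = s)
    mw <- train_l2(wh, tau = 2, n_hidden = 4, epochs = 5, lr = 5e-3, seed = s)
    c(sqrt(sum(ma$C^2) + sum(ma$D^2)), sqrt(sum(mw$C^2) + sum(mw$D^2)))
  }, c(1, 1))
  expect_gt(mean(norms[1, ] > norms[2, ]), 0.8)
})

test_that("linear application reduces correctly and is history-pure", {
  set.seed(8)
  X <- matrix(stats::rnorm(20 * 4), 20, 4)
  par <- crbm_params(4, 3, tau = 2, seed = 5)

  # zero input, zero biases -> zero output
  par0 <- par; par0$B[] <- 0
  expect_true(all(apply_l2(matrix(0, 10, 4), par0) == 0))

  # C = D = 0 -> W'x + B per frame
  out <- apply_l2(X, par)
  expect_equal(out, sweep(X %*% par$W, 2, par$B, "+"))

  # with autoregressive weights, changing frame t changes output at t by W'dx
  set.seed(9)
  par$D <- matrix(stats::rnorm(8 * 3), 8, 3)
  X2 <- X; X2[10, ] <- X2[10, ] + c(1, -1, 0, 2)
  o1 <- apply_l2(X, par); o2 <- apply_l2(X2, par)
  expect_equal(o2[10, ] - o1[10, ], drop(c(1, -1, 0, 2) %*% par$W))

  # swapped models give swapped outputs (functional purity)
  parB <- crbm_params(4, 3, tau = 2, seed = 99)
  expect_equal(apply_l2(X, list(parB, par)),
               rev(apply_l2(X, list(par, parB))), ignore_attr = TRUE)
})

test_that("a context bank stays time-aligned across tau", {
  set.seed(10)
  X <- matrix(stats::rnorm(30 * 4), 30, 4)
  bank <- list(crbm_params(4, 3, tau = 2, seed = 1),
               crbm_params(4, 3, tau = 6, seed = 2))
  out <- apply_l2(X, bank)
  expect_named(out, c("tau_2", "tau_6"))
  expect_true(all(vapply(out, nrow, 1L) == 30L))
})
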