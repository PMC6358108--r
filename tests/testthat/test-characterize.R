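test_that("a stimulus-independent stage measures as 0 dB everywhere", {
  fixed <- matrix(abs(stats::rnorm(128 * 4, 1, 0.1)), 128, 4)
  stage <- function(sig) fixed
  m <- measure_mtf(stage, rates = c(4, 16), scales = c(0.5, 2),
                   n_rep = 1, seed = 1)
  expect_true(all(abs(m$gain_db) < 1e-9))
  expect_equal(dim(m$gain_db), c(2L, 2L))
})

test_that("a known temporal modulation filter is recovered within 1 dB", {
  # stage: FIR g along time on the cochleagram plus post-detector noise;
  # the same measurement with a unit-gain stage is the reference, so the
  # difference of the two measured surfaces is the filter's 20 log10 |G|
  g <- c(0.8, 0.25)
  Gmag <- function(f) abs(sum(g * exp(-2i * pi * f * 0.01 * (0:1))))
  post_noise <- function(R, sig, sd) {
    set.seed(sum(as.integer(as.numeric(sig[1:50]) * 1e6)) %% 100000L)
    R + matrix(stats::rnorm(length(R), 0, sd), nrow(R))
  }
  stage_g <- function(sig) {
    R <- unclass(cochleagram(sig)) * 20
    Rf <- apply(R, 2, function(u) as.numeric(stats::filter(u, g, sides = 1)))
    Rf[is.na(Rf)] <- 0
    post_noise(Rf, sig, 1.5)
  }
  stage_id <- function(sig) post_noise(unclass(cochleagram(sig)) * 20, sig, 1.5)
  rates <- c(4, 8, 16, 24)
  m_g <- measure_mtf(stage_g, rates, scales = 0.5, n_rep = 6, seed = 1)
  m_i <- measure_mtf(stage_id, rates, scales = 0.5, n_rep = 6, seed = 1)
  measured <- drop(m_g$gain_db - m_i$gain_db)
  expected <- 20 * log10(vapply(rates, Gmag, 1))
  expect_lt(max(abs(measured - expected)), 1)
})

test_that("the grid covers the printed rate and scale ranges", {
  expect_equal(range(default_rates()), c(-50, 50))
  expect_equal(range(default_scales()), c(0.25, 16))
})

test_that("agglomerative clustering recovers well-separated tuning blobs", {
  set.seed(3)
  blob <- function(mu, n) t(replicate(n, mu + stats::rnorm(8, sd = 0.02)))
  A <- blob(c(1, 1, 1, 1, 0, 0, 0, 0), 6)
  B <- blob(c(0, 0, 0, 0, 1, 1, 1, 1), 5)
  cl <- cluster_units(rbind(A, B), k = 2)
  expect_length(unique(cl$labels[1:6]), 1L)
  expect_length(unique(cl$labels[7:11]), 1L)
  expect_false(cl$labels[1] == cl$labels[7])
  expect_gt(cl$silhouette, 0.8)
  # identical profiles collapse into one cluster; repeated runs identical
  one <- cluster_units(blob(rep(1, 8), 5), k = 1)
  expect_equal(unique(one$labels), 1L)
  expect_identical(cl$labels, cluster_units(rbind(A, B), k = 2)$labels)
  expect_error(cluster_units(rbind(A, B), k = 20), "k must")
})

test_that("cluster tags follow the harmonicity / onset / rate heuristics", {
  rates <- c(-40, -4, 4, 40)
  scales <- c(0.25, 0.5, 1.5, 4)
  mk <- function(ri, si) {
    g <- matrix(0.01, 4, 4)
    g[ri, si] <- 1
    g
  }
  # 3 units peaked at (4 Hz, 1.5 cyc/oct); 3 at (40 Hz, 0.25 cyc/oct)
  pu <- array(0, c(6, 4, 4))
  for (u in 1:3) pu[u, , ] <- mk(3, 3) + 0.005 * u
  for (u in 4:6) pu[u, , ] <- mk(4, 1) + 0.005 * u
  cl <- cluster_units(pu, k = 2, rates = rates, scales = scales)
  # onset-polarity filters for the fast units (weight in the latest frame)
  F <- array(0, c(3, 128, 6))
  F[3, , ] <- 1
  F[1, , ] <- -0.5
  cl <- tag_clusters(cl, structure(F, class = c("l1_filterbank", "array")))
  slow_cluster <- cl$labels[1]
  fast_cluster <- cl$labels[4]
  expect_true("H" %in% cl$tags[[slow_cluster]])
  expect_true("S" %in% cl$tags[[slow_cluster]])
  expect_true(all(c("F", "O") %in% cl$tags[[fast_cluster]]))
  expect_false("H" %in% cl$tags[[fast_cluster]])
  expect_setequal(units_with_tag(cl, "H"), 1:3)
  expect_setequal(units_with_tag(cl, "O"), 4:6)
})

test_that("slow-fraction summarizes where MTF mass sits", {
  m <- list(rates = c(-40, -10, 10, 40), scales = c(1, 2),
            gain_db = matrix(c(0, 10, 10, 0, 0, 10, 10, 0), 4, 2))
  class(m) <- "mtf_grid"
  expect_gt(slow_fraction(m), 0.8)
  m$gain_db <- matrix(c(10, 0, 0, 10, 10, 0, 0, 10), 4, 2)
  expect_lt(slow_fraction(m), 0.2)
})

test_that("MTF measurement is stable across ripple seeds", {
  stage <- function(sig) unclass(cochleagram(sig))
  g1 <- measure_mtf(stage, rates = 8, scales = 0.5, n_rep = 2, seed = 1)$gain_db
  g2 <- measure_mtf(stage, rates = 8, scales = 0.5, n_rep = 2, seed = 500)$gain_db
  expect_lt(abs(g1 - g2), 3)
})
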