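# Model characterization: modulation transfer functions from ripple pairs,
# per-unit rate-scale tuning, agglomerative clustering, semantic tags.

#' Stage function for a model layer
#'
#' Wraps a trained model layer as a `function(audio_signal) -> frames x units`
#' matrix, the interface [measure_mtf()] probes.
#'
#' @param model A `stream_model`.
#' @param layer `"l1"` or `"l2"` (L2 blocks are concatenated; L3 is untrained
#'   and not characterized).
#' @return A closure.
#' @export
layer_stage <- function(model, layer = c("l1", "l2")) {
  layer <- match.arg(layer)
  if (layer == "l1") {
    function(sig) predict(model, sig, layer = "l1")
  } else {
    function(sig) do.call(cbind, predict(model, sig, layer = "l2"))
  }
}

#' Measure a modulation transfer function with ripple pairs
#'
#' For every rate-density combination `(omega0, Omega0)` a fully modulated
#' ripple (`dA` = 100%) and its unmodulated twin (`dA` = 0%, same component
#' phases) are synthesized and passed through `stage`. `M` is the magnitude
#' of each unit's response component synchronized at exactly `omega0` (the
#' Fourier coefficient over the steady-state window), pooled across units by
#' root mean square, and the tuning gain is
#' `10 * log10(||M_100||^2 / ||M_0||^2)`.
#'
#' Rates are rounded to the 1 Hz bins of the 1 s steady-state window; a zero
#' denominator yields `+Inf` with a warning.
#'
#' @param stage `function(audio_signal) -> frames x units matrix` (see
#'   [layer_stage()]).
#' @param rates Ripple velocities in Hz, signed, within \[-50, 50\].
#' @param scales Ripple densities in cyc/oct, within \[0.25, 16\].
#' @param duration Ripple duration in seconds (the last 1 s is analyzed; the
#'   first `duration - 1` s settle transients).
#' @param n_rep Ripple phase draws averaged per grid point.
#' @param seed Base seed for the phase draws.
#' @param per_unit Also return the per-unit |M_100| grids (needed for
#'   clustering)?
#' @param f0,level Ripple spectrum edge and level.
#' @return List of class `mtf_grid`: `rates`, `scales`, `gain_db`
#'   (rates x scales), and optionally `per_unit` (units x rates x scales).
#' @export
measure_mtf <- function(stage, rates = default_rates(), scales = default_scales(),
                        duration = 1.28, n_rep = 2L, seed = 1,
                        per_unit = FALSE, f0 = 120, level = 0.4) {
  rates <- round(rates)
  frame_rate <- 100
  n_steady <- 100L
  gain <- matrix(NA_real_, length(rates), length(scales))
  pu <- NULL
  for (si in seq_along(scales)) {
    for (ri in seq_along(rates)) {
      c1 <- c0 <- NULL
      for (rep in seq_len(n_rep)) {
        sd_i <- seed + 1000L * rep
        sp1 <- ripple_spec(rates[ri], scales[si], dA = 1, f0 = f0, level = level)
        sp0 <- ripple_spec(rates[ri], scales[si], dA = 0, f0 = f0, level = level)
        R1 <- stage(ripple(sp1, duration, seed = sd_i))
        R0 <- stage(ripple(sp0, duration, seed = sd_i))
        nfr <- nrow(R1)
        w <- (nfr - n_steady + 1):nfr
        bin <- abs(rates[ri]) * n_steady / frame_rate + 1L
        # complex coefficients: the ripple-synchronized component has a
        # deterministic phase, so averaging over realizations keeps it while
        # the incoherent floor averages down
        a1 <- apply(R1[w, , drop = FALSE], 2, function(u) stats::fft(u)[bin])
        a0 <- apply(R0[w, , drop = FALSE], 2, function(u) stats::fft(u)[bin])
        c1 <- if (is.null(c1)) a1 else c1 + a1
        c0 <- if (is.null(c0)) a0 else c0 + a0
      }
      m1 <- Mod(c1) / n_rep
      m0 <- Mod(c0) / n_rep
      num2 <- mean(m1^2)
      den2 <- mean(m0^2)
      pu_acc <- m1
      if (den2 == 0) {
        warning("zero noise floor at (", rates[ri], " Hz, ", scales[si],
                " cyc/oct); gain reported as +Inf")
        gain[ri, si] <- Inf
      } else {
        gain[ri, si] <- 10 * log10(num2 / den2)
      }
      if (per_unit) {
        if (is.null(pu))
          pu <- array(0, c(length(pu_acc), length(rates), length(scales)))
        pu[, ri, si] <- pu_acc
      }
    }
  }
  structure(list(rates = rates, scales = scales, gain_db = gain,
                 per_unit = pu),
            class = "mtf_grid")
}

#' @export
print.mtf_grid <- function(x, ...) {
  cat(sprintf("<mtf_grid> %d rates x %d scales; gain %.1f..%.1f dB\n",
              length(x$rates), length(x$scales),
              min(x$gain_db[is.finite(x$gain_db)]),
              max(x$gain_db[is.finite(x$gain_db)])))
  invisible(x)
}

#' @export
plot.mtf_grid <- function(x, ...) {
  graphics::filled.contour(x$rates[order(x$rates)], log2(x$scales),
                           x$gain_db[order(x$rates), ],
                           xlab = "rate (Hz)", ylab = "scale (log2 cyc/oct)", ...)
  invisible(x)
}

#' Default characterization grid
#'
#' Rates span -50..50 Hz, scales 0.25..16 cyc/oct (log-spaced).
#' @param n Number of points.
#' @return Numeric vector.
#' @export
default_rates <- function(n = 21L) round(seq(-50, 50, length.out = n))

#' @rdname default_rates
#' @export
default_scales <- function(n = 13L) 2^seq(log2(0.25), log2(16), length.out = n)

#' Fraction of MTF energy at slow rates
#'
#' Linear-power fraction of a transfer function's mass at temporal rates
#' below a cutoff; the quantity that distinguishes the slow sequential layer
#' from the faster simultaneous layer.
#'
#' @param mtf An `mtf_grid`.
#' @param cutoff_hz Rate cutoff (30 Hz).
#' @return Fraction in \[0, 1\].
#' @export
slow_fraction <- function(mtf, cutoff_hz = 30) {
  g <- 10^(mtf$gain_db / 10)
  g[!is.finite(g)] <- 0
  slow <- abs(mtf$rates) < cutoff_hz
  sum(g[slow, ]) / sum(g)
}

#' Agglomerative clustering of unit tuning profiles
#'
#' Units are described by their flattened rate-scale tuning surfaces
#' (per-unit grids from [measure_mtf()], each normalized to unit peak), and
#' merged by average-linkage agglomerative clustering on Euclidean distance.
#' Deterministic given its inputs.
#'
#' @param per_unit units x rates x scales array (or units x features matrix).
#' @param k Number of clusters (1..units).
#' @param rates,scales Axis values carried through for tagging.
#' @return List of class `cluster_assignment`: `labels` (unit -> cluster),
#'   `centroids` (k x features, mean normalized profiles), `silhouette`
#'   (mean silhouette width, NA for k = 1), `rates`, `scales`.
#' @export
cluster_units <- function(per_unit, k, rates = NULL, scales = NULL) {
  X <- if (length(dim(per_unit)) == 3L) {
    if (is.null(rates)) rates <- seq_len(dim(per_unit)[2])
    if (is.null(scales)) scales <- seq_len(dim(per_unit)[3])
    matrix(per_unit, nrow = dim(per_unit)[1])
  } else as.matrix(per_unit)
  if (k < 1 || k > nrow(X)) stop("k must lie in 1..units")
  pk <- apply(X, 1, max)
  pk[pk == 0] <- 1
  Xn <- X / pk
  d <- stats::dist(Xn)
  labels <- if (k == 1L) rep(1L, nrow(X)) else
    stats::cutree(stats::hclust(d, method = "average"), k = k)
  centroids <- t(vapply(seq_len(k), function(c)
    colMeans(Xn[labels == c, , drop = FALSE]), numeric(ncol(Xn))))
  structure(list(labels = labels, centroids = centroids,
                 silhouette = mean_silhouette(as.matrix(d), labels),
                 rates = rates, scales = scales,
                 dims = if (length(dim(per_unit)) == 3L) dim(per_unit)[2:3] else NULL),
            class = "cluster_assignment")
}

# mean silhouette width from a distance matrix and integer labels
mean_silhouette <- function(D, labels) {
  k <- length(unique(labels))
  if (k < 2L) return(NA_real_)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(c) mean(D[i, labels == c]), 1))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Tag tuning clusters with semantic labels
#'
#' Heuristic labels on cluster centroids: `H` (harmonicity) when the
#' centroid's spectral-modulation peak falls in 1-2 cyc/oct; `S` / `F`
#' (slow / fast) split at 25 Hz of rate-energy mass; `O` (onset) for fast
#' clusters whose member filters have a transient onset-polarity time
#' profile (more weight in the most recent frame than the oldest).
#'
#' @param assignment A `cluster_assignment` from [cluster_units()].
#' @param filters Optional `l1_filterbank` (enables the onset-polarity check;
#'   without it `O` follows the rate criterion alone).
#' @return The assignment with a `tags` element: per-cluster character
#'   vectors.
#' @export
tag_clusters <- function(assignment, filters = NULL) {
  k <- nrow(assignment$centroids)
  nr <- length(assignment$rates); ns <- length(assignment$scales)
  tags <- vector("list", k)
  for (c in seq_len(k)) {
    g <- matrix(assignment$centroids[c, ], nr, ns)
    e <- g^2
    if (sum(e) == 0) {              # silent cluster: no tuning, no tags
      tags[[c]] <- character(0)
      next
    }
    scale_prof <- colSums(e)
    rate_prof <- rowSums(e)
    peak_scale <- assignment$scales[which.max(scale_prof)]
    fast_frac <- sum(rate_prof[abs(assignment$rates) > 25]) / sum(rate_prof)
    t_c <- character(0)
    if (peak_scale >= 1 && peak_scale <= 2) t_c <- c(t_c, "H")
    t_c <- c(t_c, if (fast_frac > 0.5) "F" else "S")
    if (fast_frac > 0.5) {
      onset_ok <- TRUE
      if (!is.null(filters)) {
        members <- which(assignment$labels == c)
        sc <- vapply(members, function(u) {
          f <- filters[, , u]
          (sum(f[nrow(f), ]) - sum(f[1, ])) / (sum(abs(f)) + 1e-12)
        }, 1)
        onset_ok <- mean(sc) > 0
      }
      if (onset_ok) t_c <- c(t_c, "O")
    }
    tags[[c]] <- t_c
  }
  assignment$tags <- tags
  assignment
}

#' Units belonging to clusters carrying a tag
#'
#' @param assignment A tagged `cluster_assignment`.
#' @param tag Tag letter (`"H"`, `"O"`, `"S"`, `"F"`).
#' @param fallback_nearest For `"H"` only: if no cluster carries the tag,
#'   fall back to the cluster whose spectral peak is closest to 1.5 cyc/oct.
#' @return Integer unit ids (possibly empty).
#' @export
units_with_tag <- function(assignment, tag, fallback_nearest = FALSE) {
  hit <- which(vapply(assignment$tags, function(t) tag %in% t, TRUE))
  if (!length(hit) && fallback_nearest && tag == "H") {
    nr <- length(assignment$rates)
    peaks <- vapply(seq_len(nrow(assignment$centroids)), function(c) {
      g <- matrix(assignment$centroids[c, ], nr)
      assignment$scales[which.max(colSums(g^2))]
    }, 1)
    hit <- which.min(abs(log2(peaks / 1.5)))
  }
  which(assignment$labels %in% hit)
}
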