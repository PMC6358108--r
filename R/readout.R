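# Signal-detection readout: distances between final responses, noisy
# threshold decisions, d-prime, percent correct.

#' Euclidean distance between two response windows
#'
#' Distance between model responses restricted to a window of frames
#' (typically the final burst +/- 50 ms). With `relative = TRUE` the distance
#' is normalized by the summed window norms, giving the scale-free response
#' difference used by the streaming experiments.
#'
#' @param R1,R2 frames x units response matrices of equal shape.
#' @param window Integer frame indices to restrict to (default: all frames).
#' @param relative Normalize by `(||R1|| + ||R2||)` over the window?
#' @return Non-negative scalar.
#' @export
response_distance <- function(R1, R2, window = NULL, relative = FALSE) {
  R1 <- as.matrix(R1); R2 <- as.matrix(R2)
  if (!all(dim(R1) == dim(R2))) stop("response shapes differ")
  if (!is.null(window)) {
    window <- window[window >= 1 & window <= nrow(R1)]
    R1 <- R1[window, , drop = FALSE]
    R2 <- R2[window, , drop = FALSE]
  }
  d <- sqrt(sum((R1 - R2)^2))
  if (relative) {
    denom <- sqrt(sum(R1^2)) + sqrt(sum(R2^2))
    d <- if (denom > 0) d / denom else 0
  }
  d
}

#' Noisy threshold decision
#'
#' Reports "change" when `distance + eps > threshold` with
#' `eps ~ N(0, noise_sd^2)`; the standard signal-detection link between a
#' deterministic model response and trial-to-trial variability.
#'
#' @param distance Observed response distance (scalar).
#' @param threshold Decision criterion.
#' @param noise_sd Standard deviation of the internal noise.
#' @param n Number of trials to simulate.
#' @return Logical vector of length `n`: `TRUE` = "change".
#' @export
trial_decision <- function(distance, threshold, noise_sd, n = 1L) {
  if (threshold < 0 || noise_sd < 0) stop("threshold and noise_sd must be >= 0")
  eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  distance + eps > threshold
}

#' Sensitivity index d-prime
#'
#' `d' = z(H) - z(F)` with hit and false-alarm rates clipped to
#' `[1/(2n), 1 - 1/(2n)]` before the probit transform.
#'
#' @param hits Hit rate (or count when > 1 given `n_trials`).
#' @param false_alarms False-alarm rate (or count).
#' @param n_trials Number of trials per response class (>= 1).
#' @return List of class `dprime_score`: `hits`, `false_alarms`, `dprime`.
#' @export
dprime <- function(hits, false_alarms, n_trials = 1000L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (hits > 1) hits <- hits / n_trials
  if (false_alarms > 1) false_alarms <- false_alarms / n_trials
  lo <- 1 / (2 * n_trials)
  H <- min(max(hits, lo), 1 - lo)
  F <- min(max(false_alarms, lo), 1 - lo)
  structure(list(hits = H, false_alarms = F,
                 dprime = stats::qnorm(H) - stats::qnorm(F)),
            class = "dprime_score")
}

#' @export
print.dprime_score <- function(x, ...) {
  cat(sprintf("d' = %.3f  (H = %.3f, F = %.3f)\n",
              x$dprime, x$hits, x$false_alarms))
  invisible(x)
}

#' Calibrate the decision criterion and noise for one paradigm
#'
#' Threshold = midpoint of the distances produced by the paradigm's
#' "clearly one stream" and "clearly two streams" anchor conditions; the
#' internal noise is set so that a mid-difficulty distance yields about
#' `target` proportion "change" responses, then frozen for the whole
#' experiment.
#'
#' @param d_one Distance in the one-stream anchor condition.
#' @param d_two Distance in the two-stream anchor condition.
#' @param d_mid Distance at the paradigm's mid-difficulty condition (defaults
#'   to the anchor mean).
#' @param target Desired P("change") at `d_mid` (0.7).
#' @return List with `threshold` and `noise_sd`.
#' @export
calibrate_readout <- function(d_one, d_two, d_mid = NULL, target = 0.7) {
  threshold <- (d_one + d_two) / 2
  if (is.null(d_mid)) d_mid <- threshold + 0.1 * (d_two - d_one)
  noise_sd <- (d_mid - threshold) / stats::qnorm(target)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    noise_sd <- max(abs(d_two - d_one) / 4, 1e-6)
  list(threshold = threshold, noise_sd = noise_sd)
}

# frame window of the final target burst (+/- pad seconds) from a stimulus
# annotation; labels "A'" fall back to "A"
final_burst_window <- function(signal, pad = 0.050, frame_step = 0.010,
                               n_frames = NULL) {
  ann <- annotation(signal)
  rows <- ann[ann$label %in% c("A", "A'"), ]
  last <- rows[which.max(rows$onset), ]
  f0 <- floor((last$onset - pad) / frame_step) + 1L
  f1 <- ceiling((last$offset + pad) / frame_step)
  w <- max(1L, f0):f1
  if (!is.null(n_frames)) w <- w[w <= n_frames]
  w
}

# hit/false-alarm simulation for one condition: 'changed' trials carry the
# measured distance, 'unchanged' trials distance 0 (same stimulus twice)
simulate_condition <- function(distance, threshold, noise_sd, trials, seed) {
  set.seed(seed)
  hits <- mean(trial_decision(distance, threshold, noise_sd, trials))
  fas <- mean(trial_decision(0, threshold, noise_sd, trials))
  list(hit_rate = hits, fa_rate = fas,
       dprime = dprime(hits, fas, trials)$dprime,
       pc = 0.5 * hits + 0.5 * (1 - fas))
}

#' Gaussian-mixture token identification readout
#'
#' Fits one Gaussian mixture density per target class on per-utterance mean
#' responses and classifies test utterances by maximum log-likelihood,
#' subject to an acceptance threshold.
#'
#' @param train Named list (one entry per class) of utterances x features
#'   matrices of training mean responses.
#' @param test Matrix of test mean responses (one row per utterance).
#' @param truth Character vector of true class names for `test` rows.
#' @param n_components Mixture components per class (reduced with a warning
#'   for classes with too few examples).
#' @param threshold Log-likelihood acceptance threshold (`-Inf` = always
#'   answer).
#' @return List: `accuracy` (overall percent correct), `per_class`,
#'   `predicted`, `loglik` (test x class matrix).
#' @export
gmm_token_readout <- function(train, test, truth, n_components = 2L,
                              threshold = -Inf) {
  if (length(train) < 2L) stop("need at least two target classes")
  classes <- names(train)
  models <- lapply(classes, function(cl) {
    X <- train[[cl]]
    g <- min(n_components, nrow(X) - 1L)
    if (g < n_components)
      warning("class ", cl, ": reducing mixture components to ", g)
    mclust::densityMclust(X, G = max(1L, g),
                          modelNames = c("EII", "VII"),
                          verbose = FALSE, plot = FALSE)
  })
  ll <- vapply(models, function(m)
    mclust::dens(modelName = m$modelName, data = test,
                 parameters = m$parameters, logarithm = TRUE),
    numeric(nrow(test)))
  if (nrow(test) == 1L) ll <- matrix(ll, nrow = 1)
  colnames(ll) <- classes
  best <- max.col(ll, ties.method = "first")
  pred <- classes[best]
  pred[ll[cbind(seq_len(nrow(ll)), best)] < threshold] <- NA_character_
  correct <- !is.na(pred) & pred == truth
  per_class <- tapply(correct, truth, mean) * 100
  list(accuracy = mean(correct) * 100, per_class = per_class,
       predicted = pred, loglik = ll)
}
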