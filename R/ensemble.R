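# Synthetic training ensemble: a statistical stand-in for a natural-sound
# corpus (speech plus environmental effects). Segments are 3 s at 8 kHz,
# raised-cosine windowed, standardized to zero mean / unit variance.

synth_voiced <- function(n, sr) {
  # harmonic stack with drifting f0 (80-300 Hz) and a random formant envelope
  t <- (seq_len(n) - 1) / sr
  f0a <- stats::runif(1, 80, 260)
  f0b <- f0a * 2^stats::runif(1, -0.5, 0.5)
  f0 <- f0a + (f0b - f0a) * t / max(t)
  phase <- cumsum(2 * pi * f0 / sr)
  formants <- sort(stats::runif(3, 300, 3200))
  bw <- stats::runif(3, 0.25, 0.5)
  buf <- numeric(n)
  for (k in 1:floor(3600 / max(f0))) {
    fk <- k * mean(f0)
    g <- sum(exp(-0.5 * ((log2(fk) - log2(formants)) / bw)^2)) / k^0.4
    buf <- buf + g * sin(k * phase)
  }
  env <- 1 + 0.4 * sin(2 * pi * stats::runif(1, 2, 8) * t + stats::runif(1, 0, 2 * pi))
  buf * env
}

synth_am_noise <- function(n, sr) {
  rate <- 2^stats::runif(1, 1, 8)                 # 2-256 Hz AM
  depth <- stats::runif(1, 0.5, 1)
  lo <- stats::runif(1, 180, 800)
  hi <- stats::runif(1, 1500, 3999)
  t <- (seq_len(n) - 1) / sr
  band_noise(n, lo, hi, sr) * (1 + depth * sin(2 * pi * rate * t))
}

synth_fm <- function(n, sr) {
  # log-frequency chirps (frequency-modulated sweeps), a few per segment
  t <- (seq_len(n) - 1) / sr
  buf <- numeric(n)
  for (j in seq_len(sample(2:4, 1))) {
    fa <- stats::runif(1, 200, 2000)
    fb <- fa * 2^stats::runif(1, -2, 2)
    f <- fa * (fb / fa)^(t / max(t))
    buf <- buf + sin(cumsum(2 * pi * f / sr) + stats::runif(1, 0, 2 * pi))
  }
  buf
}

synth_transients <- function(n, sr) {
  # sparse clicks and short noise bursts
  buf <- 0.02 * stats::rnorm(n)
  n_ev <- sample(8:25, 1)
  for (j in seq_len(n_ev)) {
    at <- sample.int(n - 400L, 1)
    dur <- sample(40:400, 1)
    ev <- stats::rnorm(dur) * exp(-(seq_len(dur)) / (dur / 4))
    buf[at:(at + dur - 1L)] <- buf[at:(at + dur - 1L)] + 3 * ev
  }
  buf
}

tukey_window <- function(n, a = 0.1) {
  w <- rep(1, n)
  edge <- floor(a * (n - 1) / 2)
  i <- seq_len(edge + 1) - 1
  w[i + 1] <- 0.5 * (1 + cos(pi * (2 * i / (a * (n - 1)) - 1)))
  w[n - i] <- w[i + 1]
  w
}

#' Synthetic natural-sound training ensemble
#'
#' Generates the model's training material: 3-second, 8 kHz segments,
#' raised-cosine windowed and standardized to zero mean and unit variance.
#' The mixture emulates a speech + sound-effects corpus: harmonic/voiced
#' sounds with moving fundamentals, amplitude-modulated noises,
#' frequency-modulated sweeps, transients/clicks, and two-source mixtures.
#' Pure function of `(total_seconds, seed)`.
#'
#' @param total_seconds Total ensemble duration in seconds (default 600, the
#'   desk-scale study condition).
#' @param seed RNG seed.
#' @param segment_s Segment length in seconds (3).
#' @return List of `audio_signal` segments, each exactly
#'   `segment_s * 8000` samples, mean ~0 and variance ~1.
#' @export
training_ensemble <- function(total_seconds = 600, seed = 1, segment_s = 3) {
  if (total_seconds <= 0) stop("total_seconds must be > 0")
  sr <- 8000
  n <- round(segment_s * sr)
  n_seg <- max(1L, ceiling(total_seconds / segment_s))
  set.seed(seed)
  types <- sample(c("voiced", "am", "fm", "click", "mix"), n_seg, replace = TRUE,
                  prob = c(0.35, 0.25, 0.15, 0.10, 0.15))
  w <- tukey_window(n, 0.1)
  out <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    x <- switch(types[i],
                voiced = synth_voiced(n, sr),
                am = synth_am_noise(n, sr),
                fm = synth_fm(n, sr),
                click = synth_transients(n, sr),
                mix = synth_voiced(n, sr) +
                      0.8 * synth_am_noise(n, sr))
    x <- x * w
    x <- (x - mean(x)) / stats::sd(x)
    out[[i]] <- audio_signal(x, sr,
                             annotation = new_annotation(0, segment_s, NA_real_,
                                                         types[i]))
  }
  out
}
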