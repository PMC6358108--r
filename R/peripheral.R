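#' Peripheral (cochlear) analysis configuration
#'
#' Parameters of the auditory front end: a bank of 128 constant-Q bandpass
#' filters spaced at 24 per octave from 180 Hz upward, followed by spectral
#' sharpening (first difference across adjacent channels), half-wave
#' rectification and leaky integration with a 10 ms time constant, sampled on
#' a 10 ms frame grid. Channels whose center frequency exceeds the 4 kHz
#' Nyquist limit of the 8 kHz pipeline are retained but carry near-zero
#' energy.
#'
#' The filters are gammatone-like fourth-order magnitude responses applied
#' zero-phase in the frequency domain. They are asymmetric: the skirt above
#' the center frequency is steeper than below (`skirt_hi < skirt_lo`, in
#' units of cf/Q), mirroring cochlear tuning; with the spectral first
#' difference this places the energy peak for a pure tone at the channel whose
#' center frequency is nearest the tone.
#'
#' @param n_channels Number of frequency channels (128).
#' @param f_base Center frequency of the first channel in Hz (180).
#' @param steps_per_octave Channel density on the log-frequency axis (24).
#' @param q Filter quality factor (~4).
#' @param skirt_lo,skirt_hi Relative width of the low/high-frequency filter
#'   skirts.
#' @param tau Integration time constant in seconds (0.010); also the frame
#'   step.
#' @param sample_rate Canonical audio rate, Hz.
#' @return A list of class `peripheral_config` (includes
#'   `center_freqs`).
#' @export
peripheral_config <- function(n_channels = 128L, f_base = 180, steps_per_octave = 24,
                              q = 4, skirt_lo = 1.0, skirt_hi = 0.25,
                              tau = 0.010, sample_rate = 8000) {
  cfg <- list(n_channels = as.integer(n_channels), f_base = f_base,
              steps_per_octave = steps_per_octave, q = q,
              skirt_lo = skirt_lo, skirt_hi = skirt_hi,
              tau = tau, sample_rate = sample_rate)
  cfg$center_freqs <- f_base * 2^((seq_len(cfg$n_channels) - 1) / steps_per_octave)
  class(cfg) <- "peripheral_config"
  cfg
}

# Frequency-domain magnitude responses of the filterbank for an N-point FFT.
# Cached per (N, config) since stimuli of equal length recur constantly.
.fb_cache <- new.env(parent = emptyenv())

filterbank_response <- function(n, cfg) {
  key <- paste0(n, "|", cfg$n_channels, "|", cfg$f_base, "|", cfg$steps_per_octave,
                "|", cfg$q, "|", cfg$skirt_lo, "|", cfg$skirt_hi, "|", cfg$sample_rate)
  got <- .fb_cache[[key]]
  if (!is.null(got)) return(got)
  f <- (seq_len(n) - 1) * cfg$sample_rate / n
  f[f > cfg$sample_rate / 2] <- f[f > cfg$sample_rate / 2] - cfg$sample_rate
  fa <- abs(f)
  H <- matrix(0, n, cfg$n_channels)
  for (i in seq_len(cfg$n_channels)) {
    cf <- cfg$center_freqs[i]
    d <- cfg$q * (fa / cf - 1)
    s <- ifelse(fa > cf, cfg$skirt_hi, cfg$skirt_lo)
    H[, i] <- (1 + (d / s)^2)^(-2)
  }
  if (length(ls(.fb_cache)) > 8L) rm(list = ls(.fb_cache), envir = .fb_cache)
  .fb_cache[[key]] <- H
  H
}

#' Auditory spectrogram of an audio signal
#'
#' Transforms audio into a frames x 128 non-negative time-frequency energy
#' matrix S(t, f): constant-Q cochlear filtering, first-order difference along
#' frequency (spectral sharpening), half-wave rectification, then leaky
#' integration exp(-t/tau) with tau = 10 ms, sampled every 10 ms. The frame
#' count is `floor(duration / 0.010)`.
#'
#' @param signal An `audio_signal` at 8 kHz (see [resample_audio()]).
#' @param config A [peripheral_config()].
#' @return A matrix of class `auditory_spectrogram` with attributes
#'   `frame_step` (s) and `center_freqs` (Hz).
#' @export
cochleagram <- function(signal, config = peripheral_config()) {
  if (!inherits(signal, "audio_signal")) signal <- audio_signal(signal)
  sr <- attr(signal, "sample_rate")
  if (sr != config$sample_rate)
    stop("signal must be at ", config$sample_rate, " Hz; use resample_audio()")
  x <- as.numeric(signal)
  if (length(x) == 0L) stop("empty signal")
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  hop <- as.integer(round(config$tau * sr))          # 80 samples per frame
  n_frames <- length(x) %/% hop
  if (n_frames < 1L) stop("signal shorter than one 10 ms frame")
  n <- n_frames * hop
  x <- x[seq_len(n)]

  H <- filterbank_response(n, config)
  X <- stats::fft(x)
  Y <- Re(stats::mvfft(H * X, inverse = TRUE)) / n   # zero-phase filtering

  # spectral sharpening: first difference along ascending frequency,
  # then half-wave rectification
  D <- cbind(Y[, 1L], Y[, -1L, drop = FALSE] - Y[, -ncol(Y), drop = FALSE])
  D[D < 0] <- 0

  # leaky integration exp(-t/tau), evaluated at frame boundaries:
  # within-frame weighted sums, then a per-frame recursion with decay^hop
  dec <- exp(-1 / (sr * config$tau))
  w <- dec^((hop - 1):0)
  B <- crossprod(matrix(D, nrow = hop), w)           # (frames*channels) x 1
  B <- matrix(B, nrow = n_frames)
  S <- stats::filter(B, dec^hop, method = "recursive")
  S <- matrix(as.numeric(S), nrow = n_frames)

  structure(S,
            frame_step = config$tau,
            center_freqs = config$center_freqs,
            class = c("auditory_spectrogram", "matrix", "array"))
}

#' @export
print.auditory_spectrogram <- function(x, ...) {
  cat(sprintf("<auditory_spectrogram> %d frames x %d channels, frame step %g ms\n",
              nrow(x), ncol(x), 1000 * attr(x, "frame_step")))
  invisible(x)
}

#' @export
plot.auditory_spectrogram <- function(x, ...) {
  graphics::image(x = seq_len(nrow(x)) * attr(x, "frame_step"),
                  y = seq_len(ncol(x)),
                  z = unclass(x), xlab = "time (s)", ylab = "channel",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Cut a spectrogram into 3-frame patches
#'
#' Groups three consecutive spectrogram frames into one 384-dimensional
#' vector (the concatenation of frames t-2, t-1, t across all 128 channels);
#' these patches are the visible layer of the simultaneous (L1) network.
#'
#' @param spec An `auditory_spectrogram` (or frames x channels matrix) with at
#'   least 3 frames.
#' @return A list of class `patch_set`: `patches` is a (frames - 2) x
#'   (3 * channels) matrix, `frame_index` gives the time index of each patch's
#'   last frame.
#' @export
extract_patches <- function(spec) {
  S <- unclass(spec)
  n <- nrow(S)
  if (is.null(n) || n < 3L) stop("need at least 3 frames to form patches")
  P <- cbind(S[1:(n - 2L), , drop = FALSE],
             S[2:(n - 1L), , drop = FALSE],
             S[3:n, , drop = FALSE])
  structure(list(patches = P, frame_index = 3:n, n_channels = ncol(S)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of dimension %d\n",
              nrow(x$patches), ncol(x$patches)))
  invisible(x)
}

#' Export a spectrogram to a plain-text container
#'
#' Writes the energy matrix, channel center frequencies and frame step as a
#' small directory of CSV/JSON files so spectrograms can be inspected outside
#' R.
#'
#' @param spec An `auditory_spectrogram`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_spectrogram <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(unclass(spec), file.path(dir, "spectrogram.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(frame_step = attr(spec, "frame_step"),
         center_freqs = attr(spec, "center_freqs")),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
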