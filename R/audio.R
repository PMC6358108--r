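#' Construct an audio signal
#'
#' Light container for mono audio. The whole pipeline operates at a canonical
#' sampling rate of 8 kHz; [read_wav()] resamples on ingestion, and the
#' stimulus generators emit 8 kHz directly.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param annotation Optional `data.frame` with columns `onset`, `offset`
#'   (seconds), `freq` (Hz, `NA` for noise) and `label`, describing the events
#'   that make up the signal.
#' @return An object of class `audio_signal`: the sample vector with
#'   attributes `sample_rate` and (optionally) `annotation`.
#' @export
audio_signal <- function(samples, sample_rate = 8000, annotation = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty audio signal")
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  structure(samples,
            sample_rate = sample_rate,
            annotation = annotation,
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  sr <- attr(x, "sample_rate")
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x), sr, length(x) / sr))
  ann <- attr(x, "annotation")
  if (!is.null(ann)) cat(sprintf("  %d annotated events\n", nrow(ann)))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(x) length(x) / attr(x, "sample_rate")

#' Annotation table of a generated stimulus
#' @param x An `audio_signal`.
#' @return The annotation `data.frame`, or `NULL`.
#' @export
annotation <- function(x) attr(x, "annotation")

#' Resample an audio signal to a target rate
#'
#' Rational-ratio polyphase resampling (via the signal package). Used to bring
#' arbitrary WAV input down to the model's canonical 8 kHz.
#'
#' @param x An `audio_signal`.
#' @param rate Target sampling rate in Hz.
#' @return An `audio_signal` at `rate` Hz.
#' @export
resample_audio <- function(x, rate = 8000) {
  sr <- attr(x, "sample_rate")
  if (sr == rate) return(x)
  fr <- as.integer(c(rate, sr) / gcd_int(as.integer(rate), as.integer(sr)))
  y <- signal::resample(as.numeric(x), fr[1L], fr[2L])
  audio_signal(y, rate, annotation = attr(x, "annotation"))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for PCM 16-bit and IEEE float 32-bit mono/stereo
#' files (stereo is averaged to mono). The result is resampled to 8 kHz unless
#' `resample = FALSE`.
#'
#' @param path Path to a `.wav` file.
#' @param resample Resample to the canonical 8 kHz? Default `TRUE`.
#' @return An `audio_signal`.
#' @export
read_wav <- function(path, resample = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV file: ", path)
  x <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(dat, "integer", length(dat) / 2L, 2L, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(dat, "double", length(dat) / 4L, 4L, endian = "little")
  } else stop("unsupported WAV encoding (need PCM16 or float32)")
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  sig <- audio_signal(x, fmt$sample_rate)
  if (resample) resample_audio(sig, 8000) else sig
}

#' Write a WAV file (PCM 16-bit mono)
#'
#' @param x An `audio_signal`; samples are clipped to \[-1, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  sr <- as.integer(attr(x, "sample_rate"))
  s <- pmax(pmin(as.numeric(x), 1), -1)
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + nbytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")          # PCM, mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
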