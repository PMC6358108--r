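#' Convert a semitone offset to Hz
#'
#' @param base Reference frequency in Hz (> 0).
#' @param semitones Signed offset in semitones (frequency ratio `2^(st/12)`).
#' @return Frequency in Hz.
#' @export
#' @examples
#' semitone_to_hz(1000, -3)   # 840.9 Hz
semitone_to_hz <- function(base, semitones) {
  if (any(base <= 0)) stop("base frequency must be > 0")
  base * 2^(semitones / 12)
}

# raised-cosine on/off ramps (default 10 ms) to avoid spectral splatter
apply_ramp <- function(x, ramp = 0.010, sr = 8000) {
  nr <- min(round(ramp * sr), floor(length(x) / 2))
  if (nr < 1) return(x)
  r <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * r
  x[(length(x) - nr + 1):length(x)] <- x[(length(x) - nr + 1):length(x)] * rev(r)
  x
}

pure_tone <- function(freq, duration, level = 0.5, ramp = 0.010, sr = 8000, phase = 0) {
  n <- round(duration * sr)
  apply_ramp(level * sin(2 * pi * freq * (seq_len(n) - 1) / sr + phase), ramp, sr)
}

# add `wave` into `buf` starting at `onset` seconds
mix_at <- function(buf, wave, onset, sr = 8000) {
  i0 <- round(onset * sr) + 1L
  idx <- i0:(i0 + length(wave) - 1L)
  keep <- idx <= length(buf)
  buf[idx[keep]] <- buf[idx[keep]] + wave[keep]
  buf
}

# white noise band-limited by brick-wall FFT mask
band_noise <- function(n, lo = 180, hi = 3999, sr = 8000) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sr / n
  f[f > sr / 2] <- sr - f[f > sr / 2]
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

new_annotation <- function(onset, offset, freq, label) {
  data.frame(onset = onset, offset = offset, freq = freq, label = label,
             stringsAsFactors = FALSE)
}

#' Two-tone streaming sequence
#'
#' Classic A/B streaming stimulus: 100 ms tones, A fixed at 1000 Hz, B a given
#' number of semitones below A. Twenty-four tones in all (twelve A, twelve B).
#' In the `alternating` mode tones follow each other contiguously (ABAB...),
#' so consecutive same-frequency tones are separated by 100 ms and the
#' sequence lasts 2.4 s. In the `synchronous` mode A and B are presented
#' together as 12 simultaneous bursts separated by 100 ms of silence (2.3 s
#' total).
#'
#' @param dF_semitones Frequency separation of B below A, in semitones. The
#'   canonical set is `c(1, 3, 6, 9, 15)`; other values are accepted.
#' @param mode `"alternating"` or `"synchronous"`.
#' @param final_a_shift Fractional frequency change applied to the final A
#'   tone (e.g. `0.04` for the +4% change probe); 0 for the reference
#'   sequence.
#' @param level Per-tone amplitude.
#' @return An `audio_signal` at 8 kHz with an annotation of every tone
#'   (labels `"A"`, `"B"`, and `"A'"` for a shifted final tone).
#' @export
two_tone_sequence <- function(dF_semitones,
                              mode = c("alternating", "synchronous"),
                              final_a_shift = 0, level = 0.45) {
  mode <- match.arg(mode)
  sr <- 8000
  fA <- 1000
  fB <- semitone_to_hz(1000, -dF_semitones)
  tone_d <- 0.100
  if (mode == "alternating") {
    onsets <- (0:23) * tone_d                     # contiguous ABAB...
    freqs <- rep(c(fA, fB), 12)
    labels <- rep(c("A", "B"), 12)
    total <- 2.4
  } else {
    onsets <- rep((0:11) * 2 * tone_d, each = 2)  # bursts every 200 ms
    freqs <- rep(c(fA, fB), 12)
    labels <- rep(c("A", "B"), 12)
    total <- 2.3
  }
  lastA <- max(which(labels == "A"))
  if (final_a_shift != 0) {
    freqs[lastA] <- fA * (1 + final_a_shift)
    labels[lastA] <- "A'"
  }
  buf <- numeric(round(total * sr))
  for (i in seq_along(onsets))
    buf <- mix_at(buf, pure_tone(freqs[i], tone_d, level), onsets[i], sr)
  audio_signal(buf, sr,
               annotation = new_annotation(onsets, onsets + tone_d, freqs, labels))
}

#' ABA triplet sequence for streaming buildup
#'
#' Repeating ABA_ triplets: three contiguous 125 ms tones (A, B, A) followed
#' by a 125 ms silent gap, giving a 0.5 s triplet period. B sits a given
#' number of semitones above A. The sequence is truncated at `total_s`
#' (only complete triplets are produced; `floor(total_s / 0.5)` of them).
#'
#' @param fA A-tone frequency in Hz (canonically 500, 1000 or 2000).
#' @param d_semitones B above A, in semitones (canonically 1, 3, 6 or 9).
#' @param total_s Total sequence duration in seconds (1-10 in the buildup
#'   paradigm).
#' @param final_a_shift Fractional frequency change of the final A tone.
#' @param level Per-tone amplitude.
#' @return An annotated `audio_signal`.
#' @export
aba_triplet_sequence <- function(fA, d_semitones, total_s,
                                 final_a_shift = 0, level = 0.5) {
  sr <- 8000
  period <- 0.5
  tone_d <- 0.125
  if (total_s < period) stop("total_s must cover at least one triplet")
  n_trip <- floor(total_s / period)
  fB <- semitone_to_hz(fA, d_semitones)
  onsets <- freqs <- numeric(0); labels <- character(0)
  for (k in seq_len(n_trip)) {
    t0 <- (k - 1) * period
    onsets <- c(onsets, t0, t0 + tone_d, t0 + 2 * tone_d)
    freqs <- c(freqs, fA, fB, fA)
    labels <- c(labels, "A", "B", "A")
  }
  lastA <- max(which(labels == "A"))
  if (final_a_shift != 0) {
    freqs[lastA] <- fA * (1 + final_a_shift)
    labels[lastA] <- "A'"
  }
  buf <- numeric(round(total_s * sr))
  for (i in seq_along(onsets))
    buf <- mix_at(buf, pure_tone(freqs[i], tone_d, level), onsets[i], sr)
  audio_signal(buf, sr,
               annotation = new_annotation(onsets, onsets + tone_d, freqs, labels))
}

#' Amplitude-modulated noise triplet sequence
#'
#' ABA triplets of sinusoidally amplitude-modulated broadband noise bursts
#' (100% modulation depth). Bursts are 100 ms, contiguous within a triplet,
#' with a 20 ms silent gap after each triplet (0.32 s period, 20 triplets,
#' 6.4 s total). The A-burst modulation rate is fixed at 100 Hz; the B rate
#' sits `d_octaves` above it (100 * 2^d Hz). Each burst carries a fresh
#' noise carrier, band-limited so the modulation sidebands stay below the
#' 4 kHz Nyquist frequency.
#'
#' @param d_octaves AM-rate separation in octaves, in \[0, 3\].
#' @param final_rate_shift Fractional change of the final A burst's modulation
#'   rate (the 10% probe of the readout), 0 for the reference.
#' @param seed RNG seed for the noise carriers.
#' @param level Per-burst amplitude scale.
#' @return An annotated `audio_signal`; `freq` in the annotation holds the
#'   modulation rate in Hz.
#' @export
am_noise_sequence <- function(d_octaves, final_rate_shift = 0, seed = 1,
                              level = 0.6) {
  if (d_octaves < 0 || d_octaves > 3) stop("d_octaves must lie in [0, 3]")
  sr <- 8000
  burst_d <- 0.100; gap <- 0.020
  n_trip <- 20
  total <- n_trip * (3 * burst_d + gap)            # 6.4 s
  rateA <- 100
  rateB <- 100 * 2^d_octaves
  set.seed(seed)
  buf <- numeric(round(total * sr))
  onsets <- rates <- numeric(0); labels <- character(0)
  nb <- round(burst_d * sr)
  tt <- (seq_len(nb) - 1) / sr
  for (k in seq_len(n_trip)) {
    t0 <- (k - 1) * (3 * burst_d + gap)
    for (j in 1:3) {
      rate <- if (j == 2) rateB else rateA
      lab <- if (j == 2) "B" else "A"
      if (k == n_trip && j == 3 && final_rate_shift != 0) {
        rate <- rateA * (1 + final_rate_shift); lab <- "A'"
      }
      env <- 0.5 * (1 - cos(2 * pi * rate * tt))   # 100% depth, zero at onset
      # carrier band keeps modulation sidebands below the 4 kHz Nyquist
      w <- band_noise(nb, 180, 3999 - rate) * env
      w <- apply_ramp(level * w / max(abs(w)), 0.005, sr)
      buf <- mix_at(buf, w, t0 + (j - 1) * burst_d, sr)
      onsets <- c(onsets, t0 + (j - 1) * burst_d); rates <- c(rates, rate)
      labels <- c(labels, lab)
    }
  }
  audio_signal(buf, sr,
               annotation = new_annotation(onsets, onsets + burst_d, rates, labels))
}

#' One harmonic tone-complex burst
#'
#' A single burst of the harmonicity/onset paradigm. The target tone sits at
#' 1000 Hz, the N-th harmonic of f0 = 1000/N; background tones occupy every
#' other harmonic of f0 below 2000 Hz. Conditions: `harmonic` leaves all
#' components in place; `shifted` moves every background component by 25% of
#' f0 (direction `shift_dir`); `mistuned` moves only the target by 4%
#' (direction `mistune_dir`). Timing: in `sync` all tones span 100 ms
#' together; in `async` backgrounds are 100 ms and the target is 60 ms
#' starting 40 ms later, so all offsets coincide.
#'
#' @param N Harmonic index of the target (3, 4, 5 or 6).
#' @param condition `"harmonic"`, `"shifted"` or `"mistuned"`.
#' @param sync `"sync"` or `"async"`.
#' @param shift_dir,mistune_dir +1 or -1; direction of the shifted/mistuned
#'   manipulation.
#' @param target_shift Extra fractional frequency change of the target (the
#'   4% final-burst probe of the readout).
#' @param level Total burst amplitude budget (split across components).
#' @return List with `wave` (0.1 s at 8 kHz), `components` (Hz),
#'   `target_freq`, and an `annotation` data frame (onsets relative to burst
#'   start).
#' @export
complex_burst <- function(N, condition = c("harmonic", "shifted", "mistuned"),
                          sync = c("sync", "async"),
                          shift_dir = 1, mistune_dir = 1,
                          target_shift = 0, level = 0.7) {
  condition <- match.arg(condition)
  sync <- match.arg(sync)
  if (!N %in% 3:6) stop("N must be one of 3, 4, 5, 6")
  sr <- 8000
  f0 <- 1000 / N
  k <- seq_len(floor(1999.999 / f0))
  comps <- k * f0
  target_i <- which(k == N)
  if (condition == "shifted")
    comps[-target_i] <- comps[-target_i] + shift_dir * 0.25 * f0
  if (condition == "mistuned")
    comps[target_i] <- comps[target_i] * (1 + mistune_dir * 0.04)
  comps[target_i] <- comps[target_i] * (1 + target_shift)
  amp <- level / length(comps)
  burst_d <- 0.100
  buf <- numeric(round(burst_d * sr))
  t_on <- if (sync == "sync") 0 else 0.040
  t_dur <- if (sync == "sync") burst_d else 0.060
  ons <- offs <- numeric(length(comps)); lab <- character(length(comps))
  for (i in seq_along(comps)) {
    if (i == target_i) {
      buf <- mix_at(buf, pure_tone(comps[i], t_dur, amp), t_on, sr)
      ons[i] <- t_on; offs[i] <- t_on + t_dur; lab[i] <- "A"
    } else {
      buf <- mix_at(buf, pure_tone(comps[i], burst_d, amp), 0, sr)
      ons[i] <- 0; offs[i] <- burst_d; lab[i] <- "bg"
    }
  }
  list(wave = buf, components = comps, target_freq = comps[target_i],
       annotation = new_annotation(ons, offs, comps, lab))
}

#' Multiple-burst tone-complex sequence (MBS / MBD)
#'
#' Eight tone-complex bursts with the 1000 Hz target embedded in harmonically
#' related backgrounds. `MBS` ("multiple bursts same") draws one harmonic
#' index N for the whole sequence; `MBD` ("multiple bursts different")
#' redraws N for every burst under the constraint that consecutive bursts
#' never share N. Bursts are 100 ms long with onsets 200 ms apart (100 ms
#' burst followed by 100 ms of silence).
#'
#' @param mode `"MBS"` or `"MBD"`.
#' @param condition Burst condition, see [complex_burst()].
#' @param sync `"sync"` or `"async"`.
#' @param seed RNG seed for the N draws and manipulation directions.
#' @param final_target_shift Fractional frequency change of the target in the
#'   final burst (readout probe).
#' @return An annotated `audio_signal` (1.5 s); target rows are labeled
#'   `"A"` (`"A'"` in a shifted final burst), backgrounds `"bg"`.
#' @export
mbx_sequence <- function(mode = c("MBS", "MBD"),
                         condition = "harmonic", sync = "sync",
                         seed = 1, final_target_shift = 0) {
  mode <- match.arg(mode)
  sr <- 8000
  n_bursts <- 8L
  set.seed(seed)
  if (mode == "MBS") {
    Ns <- rep(sample(3:6, 1), n_bursts)
  } else {
    Ns <- integer(n_bursts)
    Ns[1] <- sample(3:6, 1)
    for (i in 2:n_bursts) Ns[i] <- sample(setdiff(3:6, Ns[i - 1]), 1)
  }
  dirs <- sample(c(-1, 1), n_bursts, replace = TRUE)
  period <- 0.2
  total <- (n_bursts - 1) * period + 0.1
  buf <- numeric(round(total * sr))
  ann <- NULL
  for (i in seq_len(n_bursts)) {
    b <- complex_burst(Ns[i], condition, sync,
                       shift_dir = dirs[i], mistune_dir = dirs[i],
                       target_shift = if (i == n_bursts) final_target_shift else 0)
    t0 <- (i - 1) * period
    buf <- mix_at(buf, b$wave, t0, sr)
    a <- b$annotation
    a$onset <- a$onset + t0; a$offset <- a$offset + t0
    if (i == n_bursts && final_target_shift != 0)
      a$label[a$label == "A"] <- "A'"
    a$burst <- i; a$N <- Ns[i]
    ann <- rbind(ann, a)
  }
  audio_signal(buf, sr, annotation = ann)
}

#' Ripple stimulus specification
#'
#' A moving ripple is broadband noise built from `n_tones` tones equally
#' spaced on the log-frequency axis over `span_oct` octaves, with a
#' spectro-temporal sinusoidal envelope
#' `L * (1 + dA * sin(2*pi*(omega*t + Omega*x) + phi))`,
#' where `x = log2(f/f0)`. Negative `omega` gives an upward-moving ripple.
#'
#' @param omega Ripple velocity in Hz (signed).
#' @param Omega Ripple density in cycles/octave.
#' @param dA Modulation depth in \[0, 1\].
#' @param phi Ripple phase in radians.
#' @param level Overall level L.
#' @param n_tones Number of tone components (280).
#' @param span_oct Log-frequency span in octaves (5).
#' @param f0 Lower edge of the spectrum in Hz. The default 120 Hz keeps the
#'   whole 5-octave span (top 3840 Hz) inside the 4 kHz band.
#' @return A list of class `ripple_spec`.
#' @export
ripple_spec <- function(omega, Omega, dA = 1, phi = 0, level = 0.4,
                        n_tones = 280L, span_oct = 5, f0 = 120) {
  if (dA < 0 || dA > 1) stop("dA must lie in [0, 1]")
  structure(list(omega = omega, Omega = Omega, dA = dA, phi = phi,
                 level = level, n_tones = as.integer(n_tones),
                 span_oct = span_oct, f0 = f0),
            class = "ripple_spec")
}

#' Ripple envelope value
#'
#' Evaluates the spectro-temporal envelope of a ripple at time `t` (s) and
#' log-frequency position `x` (octaves above the lower edge).
#'
#' @param spec A [ripple_spec()].
#' @param t Time(s), seconds.
#' @param x Position(s) on the tonotopic axis, octaves.
#' @return Envelope value(s).
#' @export
ripple_envelope <- function(spec, t, x) {
  spec$level * (1 + spec$dA * sin(2 * pi * (spec$omega * t + spec$Omega * x) + spec$phi))
}

#' Synthesize a ripple stimulus
#'
#' @param spec A [ripple_spec()].
#' @param duration Duration in seconds.
#' @param seed Seed for the random component phases.
#' @return An `audio_signal`. Component amplitudes are scaled by
#'   `1/n_tones`, which bounds the waveform by `2 * level`.
#' @export
ripple <- function(spec, duration = 1.28, seed = 1) {
  sr <- 8000
  n <- round(duration * sr)
  t <- (seq_len(n) - 1) / sr
  x <- spec$span_oct * (seq_len(spec$n_tones) - 1) / (spec$n_tones - 1)
  freqs <- spec$f0 * 2^x
  set.seed(seed)
  th <- stats::runif(spec$n_tones, 0, 2 * pi)
  buf <- numeric(n)
  for (i in seq_len(spec$n_tones)) {
    env <- ripple_envelope(spec, t, x[i])
    buf <- buf + env * sin(2 * pi * freqs[i] * t + th[i])
  }
  buf <- buf / spec$n_tones
  audio_signal(apply_ramp(buf, 0.010, sr), sr,
               annotation = new_annotation(0, duration, NA_real_, "ripple"))
}

#' Spectrally matched noise
#'
#' White noise shaped by a 512-tap linear-phase FIR filter fitted to the
#' average magnitude spectrum of a reference ensemble; the standard masker
#' for speech-in-noise experiments.
#'
#' @param reference An `audio_signal` or list of them (8 kHz).
#' @param duration Output duration in seconds.
#' @param seed RNG seed for the noise.
#' @param taps FIR length (512).
#' @return An `audio_signal` whose long-term spectrum matches the reference
#'   average; RMS matched to the reference ensemble mean RMS.
#' @export
matched_noise <- function(reference, duration = 3, seed = 1, taps = 512L) {
  if (inherits(reference, "audio_signal")) reference <- list(reference)
  if (length(reference) == 0L) stop("reference set is empty")
  sr <- 8000
  nseg <- 512L
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1)))
  acc <- numeric(nseg / 2 + 1); cnt <- 0
  rms <- 0
  for (r in reference) {
    x <- as.numeric(r)
    rms <- rms + sqrt(mean(x^2))
    starts <- seq(1, length(x) - nseg + 1, by = nseg %/% 2)
    for (s in starts) {
      X <- stats::fft(x[s:(s + nseg - 1)] * win)
      acc <- acc + Mod(X[seq_len(nseg / 2 + 1)])
      cnt <- cnt + 1
    }
  }
  rms <- rms / length(reference)
  mag <- acc / cnt
  mag <- mag / max(mag)
  fgrid <- seq(0, 1, length.out = length(mag))
  h <- as.numeric(signal::fir2(taps - 1L, fgrid, mag))  # 512 taps, linear phase
  set.seed(seed)
  n_out <- round(duration * sr)
  y <- stats::filter(stats::rnorm(n_out + taps), h, sides = 1)
  y <- as.numeric(y)[(taps + 1):(taps + n_out)]
  y <- y / sqrt(mean(y^2)) * rms
  audio_signal(y, sr, annotation = new_annotation(0, duration, NA_real_, "noise"))
}

#' Synthetic vowel-like token
#'
#' A short voiced token: a harmonic stack on a slowly drifting fundamental,
#' shaped by a class-specific two-formant spectral envelope. Four classes with
#' well-separated formant pairs are provided; used as a small synthetic
#' stand-in corpus for token-identification readouts.
#'
#' @param class Integer 1-4 selecting the formant pair.
#' @param seed RNG seed (fundamental jitter and drift).
#' @param duration Token duration in seconds.
#' @param level Peak amplitude.
#' @return An annotated `audio_signal`.
#' @export
vowel_token <- function(class, seed = 1, duration = 0.5, level = 0.7) {
  if (!class %in% 1:4) stop("class must be 1..4")
  formants <- list(c(300, 2300), c(750, 1200), c(400, 800), c(500, 1750))[[class]]
  sr <- 8000
  set.seed(seed)
  n <- round(duration * sr)
  t <- (seq_len(n) - 1) / sr
  f0 <- stats::runif(1, 105, 145)
  drift <- stats::runif(1, -15, 15)
  phase0 <- cumsum(2 * pi * (f0 + drift * t) / sr)
  buf <- numeric(n)
  kmax <- floor(3800 / (f0 + abs(drift) * duration))
  for (k in seq_len(kmax)) {
    fk <- k * f0
    g <- sum(exp(-0.5 * ((log2(fk) - log2(formants)) / 0.35)^2)) / k^0.3
    buf <- buf + g * sin(k * phase0)
  }
  buf <- level * buf / max(abs(buf))
  audio_signal(apply_ramp(buf, 0.02, sr), sr,
               annotation = new_annotation(0, duration, f0,
                                           paste0("vowel", class)))
}
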