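test_that("semitone conversion reproduces the canonical B-tone frequencies", {
  expect_equal(semitone_to_hz(1000, 0), 1000)
  expect_equal(semitone_to_hz(1000, -12), 500)
  expect_equal(round(semitone_to_hz(1000, -1), 1), 943.9)
  expect_equal(round(semitone_to_hz(1000, -3), 1), 840.9)
  expect_equal(round(semitone_to_hz(1000, -6), 1), 707.1)
  expect_equal(round(semitone_to_hz(1000, -9), 1), 594.6)
  expect_equal(round(semitone_to_hz(1000, -15), 1), 420.4)
})

test_that("two-tone sequences have the printed timing and tone count", {
  alt <- two_tone_sequence(6, "alternating")
  syn <- two_tone_sequence(6, "synchronous")
  expect_equal(audio_duration(alt), 2.4)
  expect_equal(audio_duration(syn), 2.3)
  expect_equal(nrow(annotation(alt)), 24L)
  expect_equal(nrow(annotation(syn)), 24L)
  expect_equal(sum(annotation(alt)$label == "A"), 12L)
  # alternating: consecutive same-frequency tones 100 ms apart (offset to onset)
  aon <- annotation(alt)$onset[annotation(alt)$label == "A"]
  expect_equal(unique(round(diff(aon), 10)), 0.2)
  # synchronous: A and B share onsets
  ann <- annotation(syn)
  expect_equal(ann$onset[ann$label == "A"], ann$onset[ann$label == "B"])
  # final-change probe moves only the last A tone by the requested fraction
  chg <- annotation(two_tone_sequence(6, "alternating", final_a_shift = 0.04))
  expect_equal(sum(chg$label == "A'"), 1L)
  expect_equal(chg$freq[chg$label == "A'"], 1040)
})

test_that("ABA triplets have a 0.5 s period and truncate to whole triplets", {
  x <- aba_triplet_sequence(1000, 6, 1)
  ann <- annotation(x)
  expect_equal(nrow(ann), 6L)               # 2 complete triplets
  expect_equal(audio_duration(x), 1)
  expect_equal(ann$onset[4] - ann$onset[1], 0.5)
  expect_equal(unique(round(ann$offset - ann$onset, 10)), 0.125)
  expect_equal(annotation(aba_triplet_sequence(1000, 12, 1))$freq[2], 2000)
})

test_that("AM-noise sequences follow the printed rates and 6.4 s duration", {
  x <- am_noise_sequence(3, seed = 1)
  expect_equal(audio_duration(x), 6.4)
  ann <- annotation(x)
  expect_equal(nrow(ann), 60L)              # 20 triplets x 3 bursts
  expect_equal(unique(ann$freq[ann$label == "A"]), 100)
  expect_equal(unique(ann$freq[ann$label == "B"]), 800)
  chg <- annotation(am_noise_sequence(1, final_rate_shift = 0.1, seed = 1))
  expect_equal(chg$freq[chg$label == "A'"], 110)
})

test_that("harmonic complexes place components at harmonics of 1000/N", {
  b <- complex_burst(3, "harmonic", "sync")
  expect_equal(b$components, c(1, 2, 3, 4, 5) * 1000 / 3, tolerance = 1e-9)
  expect_equal(b$target_freq, 1000)
  expect_equal(complex_burst(4, "mistuned", "sync", mistune_dir = 1)$target_freq,
               1040)
  expect_equal(complex_burst(4, "mistuned", "sync", mistune_dir = -1)$target_freq,
               960)
  sh <- complex_burst(5, "shifted", "sync", shift_dir = 1)
  expect_equal(sh$components[-5], (c(1:4, 6:9) + 0.25) * 200, tolerance = 1e-9)
  expect_equal(sh$target_freq, 1000)        # target spared by the shift
  # async: background leads the 60 ms target by 40 ms, offsets equal
  a <- complex_burst(4, "harmonic", "async")$annotation
  expect_equal(unique(a$onset[a$label == "A"] - a$onset[a$label == "bg"]), 0.040)
  expect_equal(unique(a$offset[a$label == "A"]), unique(a$offset[a$label == "bg"]))
})

test_that("MBS holds N fixed and MBD never repeats N across bursts", {
  for (s in 1:100) {
    ann <- annotation(mbx_sequence("MBD", seed = s))
    Ns <- unique(ann[, c("burst", "N")])$N
    expect_length(Ns, 8L)
    expect_true(all(diff(Ns) != 0))
  }
  ann <- annotation(mbx_sequence("MBS", seed = 7))
  expect_length(unique(ann$N), 1L)
  expect_equal(length(unique(ann$burst)), 8L)
})

test_that("ripples have 280 log-spaced components and the printed envelope", {
  sp <- ripple_spec(8, 1, dA = 0.5, phi = 0, level = 0.4)
  expect_equal(sp$n_tones, 280L)
  expect_equal(ripple_envelope(sp, 0, 0), 0.4)          # sin(0) = 0 -> L
  expect_equal(ripple_envelope(sp, 1 / 32, 0), 0.4 * 1.5)
  flat <- ripple_spec(8, 1, dA = 0)
  expect_equal(ripple_envelope(flat, seq(0, 1, 0.1), 0.3), rep(flat$level, 11))
  expect_error(ripple_spec(8, 1, dA = 1.2), "dA")
  expect_lte(max(abs(ripple(sp, 0.5, seed = 1))), 2 * sp$level)
})

test_that("matched noise reproduces the reference spectrum", {
  set.seed(1)
  ref <- audio_signal(stats::rnorm(24000))
  out <- matched_noise(ref, duration = 3, seed = 2)
  # white reference -> flat output spectrum within tolerance
  pw <- function(x) {
    n <- 2048
    seg <- matrix(as.numeric(x)[1:(n * floor(length(x) / n))], n)
    rowMeans(abs(apply(seg, 2, stats::fft))^2)[2:(n / 2)]
  }
  p <- pw(out)
  f <- (2:(2048 / 2)) * 8000 / 2048
  bands <- split(10 * log10(p), cut(log2(f), 8))
  bmeans <- vapply(bands, mean, 1)
  expect_lt(max(bmeans) - min(bmeans), 6)
  # harmonic reference -> energy concentrated near its partials
  tone <- audio_signal(sin(2 * pi * 500 * (0:23999) / 8000))
  shaped <- matched_noise(tone, duration = 2, seed = 3)
  p2 <- pw(shaped)
  near <- abs(f - 500) < 100
  expect_gt(mean(p2[near]), 20 * mean(p2[!near]))
})

test_that("generators are pure functions of their arguments and seed", {
  expect_identical(as.numeric(am_noise_sequence(1.5, seed = 4)),
                   as.numeric(am_noise_sequence(1.5, seed = 4)))
  expect_identical(as.numeric(mbx_sequence("MBD", seed = 11)),
                   as.numeric(mbx_sequence("MBD", seed = 11)))
  expect_identical(as.numeric(ripple(ripple_spec(4, 2), 0.5, seed = 3)),
                   as.numeric(ripple(ripple_spec(4, 2), 0.5, seed = 3)))
})

test_that("stimulus waveforms stay in [-1, 1] and match their annotations", {
  stims <- list(two_tone_sequence(15, "synchronous"),
                aba_triplet_sequence(500, 9, 2),
                am_noise_sequence(2, seed = 5),
                mbx_sequence("MBS", "mistuned", "async", seed = 2),
                ripple(ripple_spec(-16, 4), 1, seed = 1))
  for (x in stims) {
    expect_lte(max(abs(x)), 1)
    ann <- annotation(x)
    sr <- attr(x, "sample_rate")
    # annotated event onsets/offsets land inside the waveform (one-sample slack)
    expect_true(all(round(ann$offset * sr) <= length(x) + 1))
    # energy present within each annotated event
    for (i in seq_len(min(nrow(ann), 5))) {
      seg <- as.numeric(x)[max(1, round(ann$onset[i] * sr) + 40):
                             round(ann$offset[i] * sr - 40)]
      expect_gt(sqrt(mean(seg^2)), 0)
    }
  }
})

test_that("the synthetic ensemble meets the segment contract", {
  ens <- training_ensemble(12, seed = 3)
  expect_length(ens, 4L)
  for (seg in ens) {
    expect_length(as.numeric(seg), 24000L)
    expect_lt(abs(mean(as.numeric(seg))), 1e-10)
    expect_lt(abs(stats::var(as.numeric(seg)) - 1), 1e-6)
  }
  ens2 <- training_ensemble(12, seed = 3)
  expect_identical(lapply(ens, as.numeric), lapply(ens2, as.numeric))
  expect_error(training_ensemble(0), "total_seconds")
})

test_that("vowel tokens are class-consistent and seeded", {
  v1 <- vowel_token(1, seed = 5)
  expect_identical(as.numeric(v1), as.numeric(vowel_token(1, seed = 5)))
  expect_false(identical(as.numeric(v1), as.numeric(vowel_token(2, seed = 5))))
  expect_lte(max(abs(v1)), 1)
})
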