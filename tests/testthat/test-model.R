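test_that("the trained hierarchy exposes coherent shapes at every layer", {
  m <- tiny_model()
  sig <- two_tone_sequence(6, "alternating")
  S <- predict(m, sig, layer = "spectrogram")
  expect_equal(dim(S), c(240L, 128L))
  r1 <- predict(m, sig, layer = "l1")
  expect_equal(dim(r1), c(240L, 16L))
  expect_true(all(r1 >= 0))                  # rectified + adapted
  l2 <- predict(m, sig, layer = "l2")
  expect_named(l2, c("tau_6", "tau_12"))
  expect_true(all(vapply(l2, dim, c(1L, 1L)) == c(240L, 8L)))
  fin <- predict(m, sig)
  expect_equal(dim(fin), c(240L, 16L))       # concatenated context blocks
  expect_true(all(is.finite(fin)))
})

test_that("model printing and coefficients reflect the architecture", {
  m <- tiny_model()
  expect_output(print(m), "cRBM contexts")
  co <- coef(m)
  expect_equal(dim(co$l1$W), c(384L, 16L))
  expect_equal(length(co$l2), 2L)
  expect_equal(co$l2$tau_12$tau, 12L)
})

test_that("an empty lesion is the identity and lesions compose by union", {
  m <- tiny_model()
  sig <- aba_triplet_sequence(1000, 6, 1)
  expect_identical(predict(lesion(m), sig), predict(m, sig))

  ab <- lesion(lesion(m, units = c(1, 4), layer = "l1"),
               units = c(4, 9), layer = "l1")
  un <- lesion(m, units = c(1, 4, 9), layer = "l1")
  expect_identical(ab$l1_keep, un$l1_keep)
  expect_identical(predict(ab, sig), predict(un, sig))

  # lesioned channels drop out of the response dimensions
  expect_equal(ncol(predict(un, sig, layer = "l1")), 13L)
  l2les <- lesion(m, units = 1:3, layer = "l2")
  expect_equal(ncol(predict(l2les, sig)), 10L)

  expect_error(lesion(m, units = 1:16, layer = "l1"), "every unit")
  expect_error(lesion(m, units = 99, layer = "l1"), "invalid")
})

test_that("component lesions switch adaptation and coherence off", {
  m <- tiny_model()
  sig <- two_tone_sequence(15, "alternating")
  nocoh <- lesion(m, component = "coherence")
  expect_false(nocoh$coherence)
  l2 <- do.call(cbind, predict(nocoh, sig, layer = "l2"))
  expect_equal(predict(nocoh, sig), l2, ignore_attr = TRUE)
  noad <- lesion(m, component = "adaptation")
  expect_false(noad$adaptation)
  expect_false(identical(predict(noad, sig, layer = "l1"),
                         predict(m, sig, layer = "l1")))
})

test_that("models round-trip through serialization", {
  m <- tiny_model()
  f <- tempfile(fileext = ".rds")
  save_stream_model(m, f)
  m2 <- load_stream_model(f)
  expect_identical(coef(m2), coef(m))
  sig <- vowel_token(2, seed = 1)
  expect_identical(predict(m2, sig), predict(m, sig))
  unlink(f)
})

test_that("run_paradigm dispatches, writes summaries, and rejects unknowns", {
  m <- tiny_model()
  out <- tempfile()
  res <- run_paradigm(m, "two_tone", out_dir = out, dF_set = c(1, 15),
                      trials = 50, seed = 2)
  expect_true(file.exists(file.path(out, "two_tone_summary.csv")))
  expect_equal(nrow(res$summary), 4L)
  expect_error(run_paradigm(m, "nope"), "valid")
  unlink(out, recursive = TRUE)
})

test_that("WAV files round-trip and feed the pipeline after resampling", {
  sig <- two_tone_sequence(6, "alternating")
  f <- tempfile(fileext = ".wav")
  write_wav(sig, f)
  back <- read_wav(f)
  expect_equal(attr(back, "sample_rate"), 8000)
  expect_equal(as.numeric(back), as.numeric(sig), tolerance = 1e-3)
  # a 16 kHz tone file resamples to the canonical rate
  f2 <- tempfile(fileext = ".wav")
  write_wav(audio_signal(0.5 * sin(2 * pi * 440 * (0:15999) / 16000), 16000), f2)
  r <- read_wav(f2)
  expect_equal(attr(r, "sample_rate"), 8000)
  expect_equal(length(r), 8000L, tolerance = 0.01)
  unlink(c(f, f2))
})

test_that("token identification in noise degrades from high to low SNR", {
  m <- tiny_model()
  sp <- run_speech_synthetic(m, snrs_db = c(-18, 18), n_train = 8L,
                             n_test = 13L, seed = 1)
  acc <- sp$summary
  expect_gt(acc$accuracy[acc$snr_db == 18], acc$accuracy[acc$snr_db == -18])
  expect_gt(acc$accuracy[acc$snr_db == 18], sp$chance)
})
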