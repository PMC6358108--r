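# End-to-end streaming experiments: stimulus battery -> model -> readout.
#
# The per-condition decision variable is the coherence-weighted relative
# distance: the Euclidean distance between final responses (coherence
# output, final-burst window +/- 50 ms) normalized by the same distance
# measured before the coherence layer. The normalization removes
# stimulus-energy differences between conditions, so what remains is how
# strongly the temporal-coherence layer amplifies (segregated streams) or
# suppresses (fused streams) the probe-induced response difference. For
# stochastic stimuli the ratio is RMS-pooled over independent draws. Each
# experiment calibrates one decision criterion from its anchor conditions,
# freezes it, and reports hit/false-alarm rates, d-prime and percent
# correct.

# L2 and final (coherence-weighted) responses in one pass
model_responses <- function(model, signal) {
  l2 <- predict(model, signal, layer = "l2")
  l3 <- vector("list", length(l2))
  for (i in seq_along(l2)) {
    l3[[i]] <- if (model$coherence)
      run_coherence(l2[[i]], leak = model$config$leak,
                    window = model$taus_frames[i])$values
    else l2[[i]]
  }
  list(l2 = do.call(cbind, l2), final = do.call(cbind, l3))
}

# numerator (final response) and denominator (pre-coherence response)
# distances for one reference/changed stimulus pair
run_pair <- function(model, ref, chg, pad = 0.050) {
  Rr <- model_responses(model, ref)
  Rc <- model_responses(model, chg)
  w <- final_burst_window(chg, pad, n_frames = nrow(Rr$final))
  c(d3 = response_distance(Rc$final, Rr$final, window = w),
    d2 = response_distance(Rc$l2, Rr$l2, window = w))
}

pooled_gain <- function(pairs) {
  m <- matrix(unlist(pairs), nrow = 2)
  sqrt(sum(m[1, ]^2) / sum(m[2, ]^2))
}

#' Two-tone streaming experiment
#'
#' Alternating and synchronous A/B sequences across the frequency-separation
#' grid; the readout detects a 4% change of the final A tone. The decision
#' criterion is the midpoint between the alternating 1-semitone (one-stream
#' anchor) and the alternating widest-separation (two-stream anchor)
#' distances; the internal noise is calibrated at the mid separation and
#' frozen.
#'
#' @param model A `stream_model`.
#' @param dF_set Frequency separations in semitones.
#' @param trials Trials per condition and response class.
#' @param seed Decision-noise seed.
#' @param change Fractional final-tone change (0.04).
#' @return List: `summary` (one row per mode x dF), `calibration`,
#'   `trials_per_condition`.
#' @export
run_two_tone <- function(model, dF_set = c(1, 3, 6, 9, 15), trials = 200L,
                         seed = 1, change = 0.04, calibration = NULL) {
  grid <- expand.grid(mode = c("alternating", "synchronous"), dF = dF_set,
                      stringsAsFactors = FALSE)
  grid$distance <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ref <- two_tone_sequence(grid$dF[i], grid$mode[i])
    chg <- two_tone_sequence(grid$dF[i], grid$mode[i], final_a_shift = change)
    grid$distance[i] <- pooled_gain(list(run_pair(model, ref, chg)))
  }
  alt <- grid$mode == "alternating"
  cal <- if (is.null(calibration)) calibrate_readout(
    d_one = grid$distance[alt & grid$dF == min(dF_set)],
    d_two = grid$distance[alt & grid$dF == max(dF_set)],
    d_mid = grid$distance[alt][which.min(abs(dF_set - stats::median(dF_set)))])
  else calibration
  res <- lapply(seq_len(nrow(grid)), function(i)
    simulate_condition(grid$distance[i], cal$threshold, cal$noise_sd,
                       trials, seed + i))
  grid$hit_rate <- vapply(res, `[[`, 1, "hit_rate")
  grid$fa_rate <- vapply(res, `[[`, 1, "fa_rate")
  grid$dprime <- vapply(res, `[[`, 1, "dprime")
  grid$pc <- vapply(res, `[[`, 1, "pc")
  list(summary = grid, calibration = cal, trials_per_condition = trials)
}

#' Streaming buildup experiment
#'
#' ABA-triplet sequences of increasing total duration; percent correct
#' detection of a 4% change in the final A tone, averaged across the A
#' frequencies, traces the buildup of segregation over seconds.
#'
#' @param model A `stream_model`.
#' @param durations Sequence durations in seconds (1-10).
#' @param dF_set B-above-A separations in semitones.
#' @param fA_set A-tone frequencies (averaged over, as in the standard
#'   paradigm).
#' @param trials,seed,change As in [run_two_tone()].
#' @return List with `summary` (duration x dF percent correct, averaged over
#'   fA), `by_fA`, `calibration`.
#' @export
run_buildup <- function(model, durations = c(1, 2, 4, 6, 8, 10),
                        dF_set = c(1, 3, 6, 9), fA_set = c(500, 1000, 2000),
                        trials = 200L, seed = 1, change = 0.04) {
  grid <- expand.grid(duration = durations, dF = dF_set, fA = fA_set)
  grid$distance <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ref <- aba_triplet_sequence(grid$fA[i], grid$dF[i], grid$duration[i])
    chg <- aba_triplet_sequence(grid$fA[i], grid$dF[i], grid$duration[i],
                                final_a_shift = change)
    grid$distance[i] <- pooled_gain(list(run_pair(model, ref, chg)))
  }
  cal <- calibrate_readout(
    d_one = mean(grid$distance[grid$dF == min(dF_set) &
                                 grid$duration == min(durations)]),
    d_two = mean(grid$distance[grid$dF == max(dF_set) &
                                 grid$duration == max(durations)]),
    d_mid = mean(grid$distance[grid$dF == stats::median(dF_set) &
                                 grid$duration == stats::median(durations)]))
  res <- lapply(seq_len(nrow(grid)), function(i)
    simulate_condition(grid$distance[i], cal$threshold, cal$noise_sd,
                       trials, seed + i))
  grid$pc <- vapply(res, `[[`, 1, "pc")
  agg <- stats::aggregate(pc ~ duration + dF, grid, mean)
  list(summary = agg[order(agg$dF, agg$duration), ], by_fA = grid,
       calibration = cal)
}

#' Amplitude-modulated noise streaming experiment
#'
#' ABA noise-burst triplets with the B modulation rate 0-3 octaves above the
#' fixed 100 Hz A rate; the readout detects a 10% change of the final A
#' burst's modulation rate. Percent correct is the model's probability of
#' hearing two streams.
#'
#' @param model A `stream_model`.
#' @param d_set AM-rate separations in octaves.
#' @param trials,seed Decision simulation settings.
#' @param change Fractional modulation-rate change (0.10).
#' @return List with `summary`, `calibration`.
#' @export
run_am_noise <- function(model,
                         d_set = c(0, 0.3, 0.5, 0.7, 0.8, 1, 1.2, 1.4, 1.6,
                                   1.8, 2, 2.5, 3),
                         draws = 4L, trials = 200L, seed = 1, change = 0.10,
                         calibration = NULL) {
  grid <- data.frame(dAM = d_set, distance = NA_real_)
  for (i in seq_len(nrow(grid))) {
    grid$distance[i] <- pooled_gain(lapply(seq_len(draws), function(j) {
      s <- seed + 131L * j
      run_pair(model, am_noise_sequence(grid$dAM[i], seed = s),
               am_noise_sequence(grid$dAM[i], final_rate_shift = change,
                                 seed = s))
    }))
  }
  cal <- if (is.null(calibration)) calibrate_readout(
    d_one = grid$distance[which.min(d_set)],
    d_two = grid$distance[which.max(d_set)],
    d_mid = grid$distance[which.min(abs(d_set - 1))])
  else calibration
  res <- lapply(seq_len(nrow(grid)), function(i)
    simulate_condition(grid$distance[i], cal$threshold, cal$noise_sd,
                       trials, seed + i))
  grid$pc <- vapply(res, `[[`, 1, "pc")
  grid$dprime <- vapply(res, `[[`, 1, "dprime")
  list(summary = grid, calibration = cal)
}

#' Harmonicity / onset tone-complex experiment (MBS and MBD)
#'
#' Eight-burst complexes pitting harmonicity against onset synchrony:
#' conditions harmonic-sync, mistuned-sync, shifted-sync and harmonic-async,
#' for both same-N (MBS) and different-N (MBD) sequences. d-prime for
#' detecting a 4% change of the final target tone, averaged over N draws.
#'
#' @param model A `stream_model`.
#' @param draws Independent N/direction draws averaged per condition.
#' @param trials,seed,change As in [run_two_tone()].
#' @return List with `summary` (mode x condition), `calibration`.
#' @export
run_mbx <- function(model, draws = 3L, trials = 200L, seed = 1, change = 0.04,
                    calibration = NULL) {
  conds <- data.frame(
    condition = c("harmonic", "mistuned", "shifted", "harmonic"),
    sync = c("sync", "sync", "sync", "async"),
    stringsAsFactors = FALSE)
  grid <- merge(data.frame(mode = c("MBS", "MBD")), conds)
  grid$distance <- NA_real_
  for (i in seq_len(nrow(grid))) {
    grid$distance[i] <- pooled_gain(lapply(seq_len(draws), function(j) {
      s <- seed + 97L * j
      ref <- mbx_sequence(grid$mode[i], grid$condition[i], grid$sync[i], seed = s)
      chg <- mbx_sequence(grid$mode[i], grid$condition[i], grid$sync[i], seed = s,
                          final_target_shift = change)
      run_pair(model, ref, chg)
    }))
  }
  # MBS and MBD are calibrated separately: same-N and redrawn-N sequences
  # live on different distance scales
  cal <- if (is.null(calibration)) {
    lapply(stats::setNames(nm = c("MBS", "MBD")), function(md) {
      g <- grid[grid$mode == md, ]
      calibrate_readout(
        d_one = g$distance[g$condition == "harmonic" & g$sync == "sync"],
        d_two = g$distance[g$condition == "mistuned"],
        d_mid = mean(g$distance))
    })
  } else calibration
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cc <- cal[[grid$mode[i]]]
    simulate_condition(grid$distance[i], cc$threshold, cc$noise_sd,
                       trials, seed + i)
  })
  grid$dprime <- vapply(res, `[[`, 1, "dprime")
  grid$pc <- vapply(res, `[[`, 1, "pc")
  list(summary = grid, calibration = cal)
}

#' Characterize a trained model
#'
#' Measures L1 and L2 modulation transfer functions on the ripple grid,
#' clusters the L1 units by their rate-scale tuning (average-linkage
#' agglomerative clustering, default k = 8 with a silhouette report) and
#' tags the clusters (H/O/S/F).
#'
#' @param model A `stream_model`.
#' @param rates,scales Characterization grid.
#' @param k Cluster count.
#' @param n_rep,seed Ripple repetitions and seed.
#' @return List: `mtf_l1`, `mtf_l2` (with per-unit grids), `clusters`
#'   (tagged), `slow_fraction_l1`, `slow_fraction_l2`.
#' @export
characterize_model <- function(model, rates = default_rates(11L),
                               scales = default_scales(7L), k = 8L,
                               n_rep = 2L, seed = 1) {
  mtf1 <- measure_mtf(layer_stage(model, "l1"), rates, scales,
                      n_rep = n_rep, seed = seed, per_unit = TRUE)
  mtf2 <- measure_mtf(layer_stage(model, "l2"), rates, scales,
                      n_rep = n_rep, seed = seed, per_unit = TRUE)
  cl <- cluster_units(mtf1$per_unit, k = min(k, dim(mtf1$per_unit)[1]),
                      rates = rates, scales = scales)
  filters <- weights_to_filters(model$l1)
  cl <- tag_clusters(cl, filters)
  list(mtf_l1 = mtf1, mtf_l2 = mtf2, clusters = cl,
       slow_fraction_l1 = slow_fraction(mtf1),
       slow_fraction_l2 = slow_fraction(mtf2))
}

#' Lesion control suite
#'
#' Re-runs the key paradigms on targeted lesions of the trained model:
#' removing the harmonicity-tagged (H) L1 cluster (with L2 retrained on the
#' reduced input) and switching off the temporal-coherence layer. Reports the
#' paired comparisons against the intact model: two-tone separation effect
#' (spared by the H lesion), mistuned-harmonic segregation (harmed by the H
#' lesion), and the alternating-vs-synchronous distinction (abolished by the
#' coherence lesion).
#'
#' @param model A trained `stream_model`.
#' @param characterization Output of [characterize_model()] (computed here
#'   when `NULL`).
#' @param trials,seed Readout settings.
#' @return List with `full`, `h_lesion`, `coherence_lesion` experiment
#'   results and a `comparison` summary data frame.
#' @export
run_lesion_suite <- function(model, characterization = NULL, trials = 200L,
                             seed = 1) {
  if (is.null(characterization))
    characterization <- characterize_model(model, seed = seed)
  h_units <- units_with_tag(characterization$clusters, "H",
                            fallback_nearest = TRUE)
  m_h <- lesion(model, units = h_units, layer = "l1", retrain_l2 = TRUE)
  m_nocoh <- lesion(model, component = "coherence")

  dfs <- c(1, 15)
  full_tt <- run_two_tone(model, dF_set = dfs, trials = trials, seed = seed)
  h_tt <- run_two_tone(m_h, dF_set = dfs, trials = trials, seed = seed,
                       calibration = full_tt$calibration)
  nocoh_tt <- run_two_tone(m_nocoh, dF_set = dfs, trials = trials, seed = seed,
                           calibration = full_tt$calibration)
  full_mbx <- run_mbx(model, trials = trials, seed = seed)
  h_mbx <- run_mbx(m_h, trials = trials, seed = seed,
                   calibration = full_mbx$calibration)

  sep_effect <- function(tt) {
    s <- tt$summary
    s$dprime[s$mode == "alternating" & s$dF == 15] -
      s$dprime[s$mode == "alternating" & s$dF == 1]
  }
  sync_gap <- function(tt) {
    s <- tt$summary
    s$dprime[s$mode == "alternating" & s$dF == 15] -
      s$dprime[s$mode == "synchronous" & s$dF == 15]
  }
  mistuned_d <- function(mb) {
    s <- mb$summary
    mean(s$dprime[s$condition == "mistuned"])
  }
  comparison <- data.frame(
    measure = c("two_tone_separation_effect", "sync_alt_gap_15st",
                "mistuned_dprime"),
    full = c(sep_effect(full_tt), sync_gap(full_tt), mistuned_d(full_mbx)),
    h_lesion = c(sep_effect(h_tt), sync_gap(h_tt), mistuned_d(h_mbx)),
    coherence_lesion = c(sep_effect(nocoh_tt), sync_gap(nocoh_tt), NA))
  list(full = list(two_tone = full_tt, mbx = full_mbx),
       h_lesion = list(two_tone = h_tt, mbx = h_mbx, units = h_units),
       coherence_lesion = list(two_tone = nocoh_tt),
       comparison = comparison)
}

#' Synthetic speech-token identification in noise
#'
#' A scaled-down token-identification paradigm on the synthetic vowel corpus:
#' for each SNR, per-class Gaussian-mixture models are fit on mean model
#' responses to training tokens mixed with spectrally matched noise at that
#' SNR (multi-condition training), and held-out test tokens at the same SNR
#' are classified by maximum likelihood. The noise masker is fitted to the
#' average spectrum of the training corpus.
#'
#' @param model A `stream_model`.
#' @param snrs_db Signal-to-noise ratios in dB.
#' @param n_train,n_test Tokens per class.
#' @param n_components GMM components per class.
#' @param seed Corpus seed.
#' @return List with `summary` (accuracy per SNR) and `chance` (100/classes).
#' @export
run_speech_synthetic <- function(model, snrs_db = c(-18, -6, 6, 18),
                                 n_train = 10L, n_test = 8L,
                                 n_components = 2L, seed = 1) {
  classes <- 1:4
  mean_resp <- function(sig) colMeans(predict(model, sig))
  mix_at_snr <- function(tok, noise, snr) {
    g <- sqrt(mean(as.numeric(tok)^2)) /
      (sqrt(mean(as.numeric(noise)^2)) * 10^(snr / 20))
    audio_signal(as.numeric(tok) + g * as.numeric(noise)[seq_along(tok)],
                 8000, annotation = annotation(tok))
  }
  clean <- list()
  for (cl in classes)
    clean[[cl]] <- lapply(seq_len(n_train), function(j)
      vowel_token(cl, seed = seed + 1000L * cl + j))
  masker_ref <- unlist(clean, recursive = FALSE)
  acc <- data.frame(snr_db = snrs_db, accuracy = NA_real_)
  for (si in seq_along(snrs_db)) {
    snr <- snrs_db[si]
    train <- list()
    feats <- NULL; truth <- character(0)
    for (cl in classes) {
      train[[as.character(cl)]] <- do.call(rbind, lapply(
        seq_len(n_train), function(j) {
          tok <- clean[[cl]][[j]]
          noise <- matched_noise(masker_ref, duration = audio_duration(tok),
                                 seed = seed + 3000L + 100L * si + 10L * cl + j)
          mean_resp(mix_at_snr(tok, noise, snr))
        }))
      for (j in seq_len(n_test)) {
        tok <- vowel_token(cl, seed = seed + 5000L + 1000L * cl + j)
        noise <- matched_noise(masker_ref, duration = audio_duration(tok),
                               seed = seed + 7000L + 100L * si + 10L * cl + j)
        feats <- rbind(feats, mean_resp(mix_at_snr(tok, noise, snr)))
        truth <- c(truth, as.character(cl))
      }
    }
    acc$accuracy[si] <- gmm_token_readout(train, feats, truth,
                                          n_components = n_components)$accuracy
  }
  list(summary = acc, chance = 100 / length(classes))
}

#' Train a model from a config and write a run manifest
#'
#' The reproducibility entry point: trains the full hierarchy from a config
#' (synthetic ensemble or a directory of WAV files), and writes the model
#' plus a manifest (config echo, seed, package/R versions, model hash) when
#' an output directory is given. Identical config + seed give identical
#' manifest hashes.
#'
#' @param config A [stream_config()].
#' @param wav_dir Optional directory of WAV training material (otherwise the
#'   synthetic ensemble is used).
#' @param out_dir Optional output directory.
#' @return List: `model`, `manifest`.
#' @export
run_pipeline <- function(config = stream_config(), wav_dir = NULL,
                         out_dir = NULL) {
  if (!inherits(config, "stream_config"))
    stop("config must be a stream_config(); got ", class(config)[1])
  if (is.null(config$seed) || !is.finite(config$seed))
    stop("config error in field 'seed': an explicit finite seed is required")
  ensemble <- NULL
  if (!is.null(wav_dir)) {
    files <- list.files(wav_dir, "\\.wav$", full.names = TRUE,
                        ignore.case = TRUE)
    if (!length(files)) stop("no WAV files in ", wav_dir)
    ensemble <- lapply(files, read_wav)
  }
  model <- train_stream_model(config, ensemble)
  manifest <- list(
    package = "gstreams",
    version = as.character(utils::packageVersion("gstreams")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[setdiff(names(config), "peripheral")],
    model_hash = object_md5(model))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_stream_model(model, file.path(out_dir, "model.rds"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(model$l1$log, file.path(out_dir, "l1_training_log.csv"),
                     row.names = FALSE)
    for (nm in names(model$l2))
      utils::write.csv(model$l2[[nm]]$log,
                       file.path(out_dir, paste0("l2_", nm, "_training_log.csv")),
                       row.names = FALSE)
  }
  list(model = model, manifest = manifest)
}

object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run one named paradigm end to end
#'
#' Dispatcher over the experiment battery; writes summary (and calibration)
#' CSV/JSON when `out_dir` is given.
#'
#' @param model A trained `stream_model`.
#' @param paradigm One of `"two_tone"`, `"buildup"`, `"am_noise"`, `"mbx"`,
#'   `"speech_synthetic"`, `"mtf"`, `"lesion_suite"`.
#' @param out_dir Optional output directory.
#' @param ... Passed to the paradigm function.
#' @return The paradigm result.
#' @export
run_paradigm <- function(model, paradigm, out_dir = NULL, ...) {
  fns <- list(two_tone = run_two_tone, buildup = run_buildup,
              am_noise = run_am_noise, mbx = run_mbx,
              speech_synthetic = run_speech_synthetic,
              mtf = function(model, ...) characterize_model(model, ...),
              lesion_suite = run_lesion_suite)
  if (!paradigm %in% names(fns))
    stop("unknown paradigm '", paradigm, "'; valid: ",
         paste(names(fns), collapse = ", "))
  res <- fns[[paradigm]](model, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$summary))
      utils::write.csv(res$summary,
                       file.path(out_dir, paste0(paradigm, "_summary.csv")),
                       row.names = FALSE)
    if (!is.null(res$calibration))
      jsonlite::write_json(res$calibration,
                           file.path(out_dir, paste0(paradigm, "_calibration.json")),
                           auto_unbox = TRUE, digits = NA)
  }
  res
}
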