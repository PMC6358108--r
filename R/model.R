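#' Model configuration
#'
#' Collects every tunable of the pipeline: peripheral front end, L1 RBM and
#' its CD recipe, the L2 context bank, the L3 coherence layer, and the
#' training-ensemble specification. A trained model is a pure function of a
#' config (all randomness flows from `seed`).
#'
#' @param seed Root seed; training, stimulus synthesis and decision noise use
#'   fixed offsets from it.
#' @param n_hidden_l1 L1 hidden units K (400 at full scale).
#' @param n_hidden_l2 Hidden units per cRBM (300 at full scale).
#' @param taus_ms Context lengths of the L2 bank in milliseconds (within
#'   30-600 ms).
#' @param epochs_l1,epochs_l2 CD training epochs per layer.
#' @param batch_size,lr,momentum,k_steps CD recipe.
#' @param p,sparsity_cost L1 sparsity target and penalty weight.
#' @param tau_a,alpha Adaptation constants (seconds, utilization).
#' @param leak Coherence leak per 10 ms step.
#' @param ensemble_seconds Synthetic training-ensemble duration.
#' @param peripheral A [peripheral_config()].
#' @return List of class `stream_config`.
#' @export
stream_config <- function(seed = 1,
                          n_hidden_l1 = 400L, n_hidden_l2 = 300L,
                          taus_ms = c(30, 60, 120, 240, 480, 600),
                          epochs_l1 = 50L, epochs_l2 = 50L,
                          batch_size = 128L, lr = 1e-3, momentum = 0.9,
                          k_steps = 1L, p = 0.05, sparsity_cost = 0.1,
                          tau_a = 0.300, alpha = 1e-5, leak = 0.99,
                          ensemble_seconds = 600,
                          peripheral = peripheral_config()) {
  if (any(taus_ms < 30 | taus_ms > 600)) stop("taus_ms must lie within 30-600 ms")
  if (is.unsorted(taus_ms, strictly = TRUE)) stop("taus_ms must be strictly increasing")
  structure(as.list(environment()), class = "stream_config")
}

#' Desk-scale configuration
#'
#' The scaled-down study condition used throughout the test battery: 64 L1
#' units, 48 hidden units in each of two cRBM contexts (60 and 240 ms), a
#' 10-minute synthetic ensemble, and a shortened CD schedule. Small enough to
#' train end-to-end on one CPU in minutes while preserving the qualitative
#' behavior of the full-scale layout.
#'
#' @param seed Root seed.
#' @param ... Overrides passed on to [stream_config()].
#' @return A `stream_config`.
#' @export
scaled_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_hidden_l1 = 64L, n_hidden_l2 = 48L,
               taus_ms = c(60, 240), epochs_l1 = 12L, epochs_l2 = 8L,
               ensemble_seconds = 600)
  over <- list(...)
  args[names(over)] <- over
  do.call(stream_config, args)
}

#' Train the full hierarchical stream-segregation model
#'
#' End-to-end unsupervised training: the ensemble is mapped to auditory
#' spectrograms, 3-frame patches train the sparse RBM (L1), L1 responses
#' (filtered, rectified, adapted, standardized) train one conditional RBM per
#' temporal context (L2). The coherence layer L3 has no trained parameters.
#'
#' @param config A [stream_config()].
#' @param ensemble Optional list of `audio_signal` segments (e.g. 3-s WAV
#'   excerpts read with [read_wav()]). By default a synthetic ensemble is
#'   generated from the config (`ensemble_seconds`, `seed`).
#' @return An object of class `stream_model`.
#' @export
train_stream_model <- function(config = stream_config(), ensemble = NULL) {
  if (is.null(ensemble))
    ensemble <- training_ensemble(config$ensemble_seconds, seed = config$seed)
  specs <- lapply(ensemble, cochleagram, config = config$peripheral)
  patches <- do.call(rbind, lapply(specs, function(s) extract_patches(s)$patches))
  l1 <- train_l1(patches, n_hidden = config$n_hidden_l1,
                 epochs = config$epochs_l1, batch_size = config$batch_size,
                 lr = config$lr, momentum = config$momentum,
                 k_steps = config$k_steps, p = config$p,
                 sparsity_cost = config$sparsity_cost, seed = config$seed)

  resp <- lapply(specs, function(s) {
    r <- apply_l1(s, l1)
    r[r < 0] <- 0
    adapt(r, config$tau_a, config$alpha)$values
  })
  allr <- do.call(rbind, resp)
  r_center <- colMeans(allr)
  r_scale <- apply(allr, 2, stats::sd)
  r_scale[r_scale < 1e-8] <- 1
  respz <- lapply(resp, function(r)
    sweep(sweep(r, 2, r_center, "-"), 2, r_scale, "/"))

  taus_frames <- as.integer(round(config$taus_ms / 1000 / config$peripheral$tau))
  l2 <- lapply(seq_along(taus_frames), function(i)
    train_l2(respz, tau = taus_frames[i], n_hidden = config$n_hidden_l2,
             epochs = config$epochs_l2, batch_size = config$batch_size,
             lr = config$lr, momentum = config$momentum,
             seed = config$seed + i))
  names(l2) <- paste0("tau_", taus_frames)

  structure(list(
    config = config,
    l1 = l1,
    l1_keep = rep(TRUE, config$n_hidden_l1),
    l2_input_keep = rep(TRUE, config$n_hidden_l1),
    r_center = r_center, r_scale = r_scale,
    l2 = l2,
    l2_keep = lapply(l2, function(m) rep(TRUE, ncol(m$W))),
    taus_frames = taus_frames,
    adaptation = TRUE,
    coherence = TRUE),
    class = "stream_model")
}

#' @export
print.stream_model <- function(x, ...) {
  cat("<stream_model>\n")
  cat(sprintf("  L1: sparse RBM, %d/%d units active (384-dim patches)\n",
              sum(x$l1_keep), length(x$l1_keep)))
  cat(sprintf("  L2: %d cRBM contexts (%s ms), %d hidden units each\n",
              length(x$l2), paste(x$taus_frames * 10, collapse = ", "),
              ncol(x$l2[[1]]$W)))
  cat(sprintf("  L3: temporal coherence %s (leak %.3f)\n",
              if (x$coherence) "on" else "OFF", x$config$leak))
  if (!x$adaptation) cat("  adaptation: OFF\n")
  invisible(x)
}

#' @export
summary.stream_model <- function(object, ...) {
  print(object)
  cat("\nL1 training log (last epochs):\n")
  print(utils::tail(object$l1$log, 3))
  for (nm in names(object$l2)) {
    cat(sprintf("\n%s cRBM final recon error: %.4g\n", nm,
                utils::tail(object$l2[[nm]]$log$recon_error, 1)))
  }
  invisible(object)
}

#' @export
coef.stream_model <- function(object, ...) {
  list(l1 = object$l1[c("W", "A", "B")],
       l2 = lapply(object$l2, function(m) m[c("W", "A", "B", "C", "D", "tau")]))
}

#' @export
plot.stream_model <- function(x, units = 1:min(16, sum(x$l1_keep)), ...) {
  F <- weights_to_filters(x$l1)
  keep <- which(x$l1_keep)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(units)),
                      mar = c(1, 1, 1, 1))
  on.exit(graphics::par(op))
  for (u in units)
    graphics::image(t(F[, , keep[u]]), axes = FALSE,
                    col = grDevices::hcl.colors(33, "RdBu", rev = TRUE))
  invisible(x)
}

#' Run a signal through the trained hierarchy
#'
#' @param object A `stream_model`.
#' @param signal An `audio_signal` (8 kHz).
#' @param layer Which representation to return: `"final"` (the concatenated
#'   coherence-weighted per-context blocks; the model output), `"l3"`
#'   (same, as a per-context list), `"l2"`, `"l1"` or `"spectrogram"`.
#' @param ... Unused.
#' @return A matrix (frames x units) or list of matrices.
#' @export
predict.stream_model <- function(object, signal,
                                 layer = c("final", "l3", "l2", "l1",
                                           "spectrogram"), ...) {
  layer <- match.arg(layer)
  S <- cochleagram(signal, object$config$peripheral)
  if (layer == "spectrogram") return(S)
  r <- apply_l1(S, object$l1)
  r[r < 0] <- 0
  if (object$adaptation)
    r <- adapt(r, object$config$tau_a, object$config$alpha)$values
  if (layer == "l1") return(r[, object$l1_keep, drop = FALSE])
  rz <- sweep(sweep(r, 2, object$r_center, "-"), 2, object$r_scale, "/")
  # lesioned L1 channels are silenced on the way into L2; when L2 has been
  # retrained on the reduced input, the silenced columns are dropped instead
  rz[, !object$l1_keep] <- 0
  rz <- rz[, object$l2_input_keep, drop = FALSE]
  l2out <- vector("list", length(object$l2))
  names(l2out) <- names(object$l2)
  for (i in seq_along(object$l2)) {
    out <- apply_l2(rz, object$l2[[i]])
    l2out[[i]] <- out[, object$l2_keep[[i]], drop = FALSE]
  }
  if (layer == "l2") return(l2out)
  l3out <- vector("list", length(l2out))
  names(l3out) <- names(l2out)
  for (i in seq_along(l2out)) {
    if (object$coherence) {
      l3out[[i]] <- run_coherence(l2out[[i]], leak = object$config$leak,
                                  window = object$taus_frames[i])$values
    } else {
      l3out[[i]] <- l2out[[i]]
    }
  }
  if (layer == "l3") return(l3out)
  do.call(cbind, l3out)
}

#' Lesion model units or components
#'
#' Removes named L1 (or per-context L2) units from the signal path, or
#' switches off the adaptation / temporal-coherence mechanisms. Unit ids
#' always refer to the *original* (pre-lesion) indices, so lesions compose:
#' `lesion(lesion(m, a), b)` equals `lesion(m, union(a, b))`.
#'
#' Without `retrain_l2`, a lesioned L1 unit is silenced on its way into the
#' (unchanged) L2 bank — its standardized response is pinned to zero so it
#' carries no information — and dropped from the `"l1"` output. With
#' `retrain_l2`, the L2 bank is retrained on the reduced-dimension input and
#' the silenced columns are removed outright.
#'
#' @param model A `stream_model`.
#' @param units Integer ids of units to remove (original indexing).
#' @param layer `"l1"` or `"l2"`.
#' @param context For `layer = "l2"`: which context block(s) to lesion
#'   (default all).
#' @param component Instead of units: `"adaptation"` or `"coherence"` to
#'   switch that mechanism off.
#' @param retrain_l2 After an L1 lesion, retrain the L2 bank on the
#'   reduced-dimension L1 output (same seed and ensemble as the original
#'   training)?
#' @return A lesioned `stream_model`.
#' @export
lesion <- function(model, units = integer(0), layer = c("l1", "l2"),
                   context = NULL, component = NULL, retrain_l2 = FALSE) {
  layer <- match.arg(layer)
  if (!is.null(component)) {
    component <- match.arg(component, c("adaptation", "coherence"))
    if (component == "adaptation") model$adaptation <- FALSE else
      model$coherence <- FALSE
    return(model)
  }
  if (length(units)) {
    if (layer == "l1") {
      if (any(units < 1 | units > length(model$l1_keep)))
        stop("invalid unit ids")
      keep <- model$l1_keep
      keep[units] <- FALSE
      if (!any(keep)) stop("cannot lesion every unit")
      model$l1_keep <- keep
    } else {
      ctx <- if (is.null(context)) seq_along(model$l2) else context
      for (i in ctx) {
        keep <- model$l2_keep[[i]]
        if (any(units < 1 | units > length(keep))) stop("invalid unit ids")
        keep[units] <- FALSE
        if (!any(keep)) stop("cannot lesion every unit")
        model$l2_keep[[i]] <- keep
      }
    }
  }
  if (retrain_l2) model <- retrain_l2_bank(model)
  model
}

# Retrain the L2 bank on the lesioned L1 output, regenerating the original
# training ensemble from the config seed.
retrain_l2_bank <- function(model) {
  config <- model$config
  ensemble <- training_ensemble(config$ensemble_seconds, seed = config$seed)
  specs <- lapply(ensemble, cochleagram, config = config$peripheral)
  resp <- lapply(specs, function(s) {
    r <- apply_l1(s, model$l1)
    r[r < 0] <- 0
    if (model$adaptation) r <- adapt(r, config$tau_a, config$alpha)$values
    r[, model$l1_keep, drop = FALSE]
  })
  allr <- do.call(rbind, resp)
  r_center <- colMeans(allr)
  r_scale <- apply(allr, 2, stats::sd)
  r_scale[r_scale < 1e-8] <- 1
  respz <- lapply(resp, function(r)
    sweep(sweep(r, 2, r_center, "-"), 2, r_scale, "/"))
  l2 <- lapply(seq_along(model$taus_frames), function(i)
    train_l2(respz, tau = model$taus_frames[i], n_hidden = config$n_hidden_l2,
             epochs = config$epochs_l2, batch_size = config$batch_size,
             lr = config$lr, momentum = config$momentum,
             seed = config$seed + i))
  names(l2) <- names(model$l2)
  # full-length centering/scale vectors aligned to original indexing
  rc <- model$r_center; rs <- model$r_scale
  rc[model$l1_keep] <- r_center; rs[model$l1_keep] <- r_scale
  model$r_center <- rc; model$r_scale <- rs
  model$l2 <- l2
  model$l2_input_keep <- model$l1_keep
  model$l2_keep <- lapply(l2, function(m) rep(TRUE, ncol(m$W)))
  model
}

#' Save / load a trained model
#'
#' Thin wrappers over `saveRDS`/`readRDS` kept as named entry points so model
#' artifacts have a stable, documented format (version-stamped list).
#'
#' @param model A `stream_model`.
#' @param path File path (`.rds`).
#' @return `path` / the model.
#' @export
save_stream_model <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_stream_model
#' @export
load_stream_model <- function(path) readRDS(path)
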