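# Small trained models shared across test files (trained once per run).
.model_cache <- new.env(parent = emptyenv())

# minutes-scale config for API/behavior tests
tiny_config <- function(seed = 3) {
  scaled_config(seed = seed, ensemble_seconds = 30, n_hidden_l1 = 16L,
                n_hidden_l2 = 8L, taus_ms = c(60, 120),
                epochs_l1 = 2L, epochs_l2 = 2L)
}

tiny_model <- function() {
  if (is.null(.model_cache$tiny))
    .model_cache$tiny <- train_stream_model(tiny_config())
  .model_cache$tiny
}

# the desk-scale study-condition model used by the acceptance checks
accept_model <- function(seed = 1) {
  key <- paste0("accept_", seed)
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- train_stream_model(scaled_config(seed = seed))
  .model_cache[[key]]
}

accept_characterization <- function(seed = 1) {
  key <- paste0("char_", seed)
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- characterize_model(accept_model(seed), seed = seed)
  .model_cache[[key]]
}
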