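# Shared synthetic benchmark: 8 channels, 3 balanced classes, strong
# coupling (0.9) and light noise (0.1). Cached so expensive fixtures are
# built once per test run.

.bench_cache <- new.env(parent = emptyenv())

bench_spec <- function(seed = 11L) {
  synthetic_spec(n_channels = 8, n_classes = 3, n_trials_per_class = 10,
                 epochs_per_trial = 20, coupling_strength = 0.9,
                 noise_sd = 0.1, seed = seed)
}

bench_dataset <- function(seed = 11L) {
  key <- paste0("ds", seed)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- generate_dataset(bench_spec(seed))
  }
  .bench_cache[[key]]
}

# SPD inputs for one feature kind on the benchmark's trial-wise split
bench_spd <- function(kind, seed = 11L) {
  key <- paste0("spd", kind, seed)
  if (is.null(.bench_cache[[key]])) {
    sp <- split_trials(bench_dataset(seed), 18, 12)
    .bench_cache[[key]] <- list(train = epochs_to_spd(sp$train, kind),
                                test = epochs_to_spd(sp$test, kind))
  }
  .bench_cache[[key]]
}

bench_train_config <- function(seed = 5L, max_epochs = 30L) {
  train_config(batch_size = 32, max_epochs = max_epochs, seed = seed)
}
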