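# End-to-end orchestration: validated run configuration (YAML), seeded
# stage chain simulate -> (preprocess) -> extract -> graphify -> train ->
# evaluate, on-disk containers for intermediates, JSON/TSV results.

#' Build a validated run configuration
#'
#' A run configuration fixes every input of the pipeline: the synthetic
#' data spec, preprocessing parameters, feature kinds and thresholds,
#' rectification floor, training hyperparameters, the feature modes to
#' evaluate, and one global seed from which each stage derives its own
#' named substream (`seed + 1` data generation, `seed + 2` training).
#' Re-running a stored configuration reproduces all outputs bit-for-bit
#' on one thread.
#'
#' @param synthetic named list of [synthetic_spec()] arguments.
#' @param preprocess named list: `apply` (logical; bandpass the epochs),
#'   `low`, `high`, `order`.
#' @param kinds feature kinds to extract.
#' @param thresholds named per-kind edge thresholds (`NULL` = defaults).
#' @param epsilon Laplacian rectification floor.
#' @param binary binary instead of weighted graphs.
#' @param train named list of [train_config()] arguments (its `seed` is
#'   derived from the global seed).
#' @param modes list of feature-kind vectors to evaluate; `"all"` means
#'   every non-empty subset of `kinds`.
#' @param n_train_trials,n_test_trials trial-wise split.
#' @param hidden_dims BiMap dimension chain.
#' @param seed global integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(synthetic = list(), preprocess = list(apply = FALSE),
                       kinds = c("plv", "pcc", "coh", "mi"),
                       thresholds = NULL, epsilon = 1e-4, binary = FALSE,
                       train = list(), modes = list(kinds),
                       n_train_trials = 9, n_test_trials = 6,
                       hidden_dims = c(31, 20, 16, 12), seed = 1L) {
  bad <- setdiff(kinds, c("plv", "pcc", "coh", "mi"))
  if (length(bad)) {
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (identical(modes, "all") || identical(modes, list("all"))) {
    modes <- enumerate_modes(kinds)
  }
  for (m in modes) {
    if (length(setdiff(m, kinds))) {
      stop("mode uses a kind not being extracted: ",
           paste(setdiff(m, kinds), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(thresholds)) thresholds <- default_thresholds()
  cfg <- list(synthetic = synthetic, preprocess = preprocess, kinds = kinds,
              thresholds = thresholds, epsilon = epsilon, binary = binary,
              train = train, modes = modes,
              n_train_trials = n_train_trials,
              n_test_trials = n_test_trials, hidden_dims = hidden_dims,
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$modes <- if (is.null(y$modes)) NULL else
    lapply(y$modes, function(m) unlist(strsplit(m, "[+,]")))
  if (!is.null(y$thresholds)) y$thresholds <- unlist(y$thresholds)
  if (!is.null(y$hidden_dims)) y$hidden_dims <- unlist(y$hidden_dims)
  do.call(run_config, y[!vapply(y, is.null, TRUE)])
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$modes <- vapply(y$modes, paste, "", collapse = "+")
  # yaml drops names of named atomic vectors; a named list keeps the map
  y$thresholds <- as.list(y$thresholds)
  yaml::write_yaml(y, path)
  invisible(path)
}

config_hash <- function(config) rlang::hash(unclass(config))

pkg_version <- function() as.character(utils::packageVersion("spdconn"))

#' Save / load an on-disk container
#'
#' Pipeline intermediates (epoched signals, SPD tensors, fits) are
#' stored as RDS containers stamped with the configuration hash and the
#' package version.
#'
#' @param object any R object.
#' @param path file path.
#' @param config the `run_config` the object came from (for the hash).
#' @return `path`, invisibly.
#' @export
save_container <- function(object, path, config = NULL) {
  saveRDS(list(payload = object,
               config_hash = if (is.null(config)) NA_character_
                             else config_hash(config),
               package_version = pkg_version()), path)
  invisible(path)
}

#' @rdname save_container
#' @return for `load_container`, the stored payload with attributes
#'   `config_hash` and `package_version`.
#' @export
load_container <- function(path) {
  x <- readRDS(path)
  structure(x$payload, config_hash = x$config_hash,
            package_version = x$package_version)
}

log_stage <- function(stage, ...) {
  message(jsonlite::toJSON(
    list(level = "INFO", stage = stage, time = format(Sys.time()), ...),
    auto_unbox = TRUE))
}

#' Run the full pipeline
#'
#' Executes simulate -> (optional bandpass) -> extract -> graphify ->
#' train -> evaluate for every configured feature mode, writing each
#' intermediate container, a JSON results file and a TSV summary table
#' to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (`NULL` = no files written).
#' @param verbose log stage progress.
#' @return tibble with one row per mode: `mode`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) log_stage(...)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  say("simulate", seed = config$seed + 1L)
  spec <- do.call(synthetic_spec,
                  c(config$synthetic, list(seed = config$seed + 1L)))
  epochs <- generate_dataset(spec)
  if (!is.null(out_dir)) {
    save_container(epochs, file.path(out_dir, "epochs.rds"), config)
  }

  if (isTRUE(config$preprocess$apply)) {
    say("preprocess")
    low <- config$preprocess$low %||% 1
    high <- config$preprocess$high %||% 47
    ord <- config$preprocess$order %||% 4
    for (i in seq_len(n_epochs(epochs))) {
      epochs$data[i, , ] <- bandpass_filter(epochs$data[i, , ], epochs$fs,
                                            low, high, ord)
    }
  }

  tcfg_args <- config$train
  tcfg_args$seed <- config$seed + 2L
  tcfg <- do.call(train_config, tcfg_args)

  rows <- lapply(config$modes, function(mode) {
    say("evaluate", mode = mode_label(mode))
    r <- run_mode(epochs, mode, thresholds = config$thresholds,
                  config = tcfg, n_train_trials = config$n_train_trials,
                  n_test_trials = config$n_test_trials,
                  hidden_dims = config$hidden_dims,
                  epsilon = config$epsilon)
    tibble::tibble(mode = mode_label(mode),
                   mean_accuracy = attr(r, "mean"),
                   sd_accuracy = attr(r, "sd"))
  })
  results <- dplyr::bind_rows(rows)

  if (!is.null(out_dir)) {
    meta <- list(config_hash = config_hash(config),
                 package_version = pkg_version(), seed = config$seed,
                 thresholds = as.list(config$thresholds),
                 results = results)
    jsonlite::write_json(meta, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(results, file.path(out_dir, "results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a
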