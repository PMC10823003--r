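# Decision-level fusion across connectivity features, accuracy, the
# feature-combination experiment grid, and the threshold sweep.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Average decision-level fusion
#'
#' Elementwise mean of per-model class-probability matrices (rows =
#' samples). The predicted class is the argmax of the fused
#' probabilities; ties break toward the lowest class index. Averaging is
#' done on probabilities by default; `logits = TRUE` averages log
#' probabilities instead and renormalizes.
#'
#' @param prob_list list of `n x n_classes` probability matrices (or
#'   vectors for a single sample), one per model.
#' @param logits average log-probabilities (geometric mean) instead.
#' @return list with `probs` (fused matrix) and `predicted` (1-based
#'   column index per sample).
#' @export
average_fusion <- function(prob_list, logits = FALSE) {
  if (length(prob_list) == 0) {
    stop("average_fusion needs at least one model output", call. = FALSE)
  }
  prob_list <- lapply(prob_list, function(p) {
    if (is.null(dim(p))) matrix(p, nrow = 1) else p
  })
  d0 <- dim(prob_list[[1]])
  for (p in prob_list) {
    if (!all(dim(p) == d0)) {
      stop("all model outputs must have identical dimensions",
           call. = FALSE)
    }
  }
  fused <- if (logits) {
    s <- Reduce(`+`, lapply(prob_list, function(p) log(pmax(p, 1e-300))))
    e <- exp(s / length(prob_list))
    e / rowSums(e)
  } else {
    Reduce(`+`, prob_list) / length(prob_list)
  }
  list(probs = fused, predicted = max.col(fused, ties.method = "first"))
}

#' Classification accuracy
#'
#' Proportion of correct predictions; for two balanced decision classes
#' this is `(TP + TN) / (TP + FN + FP + TN)`.
#'
#' @param pred,truth equal-length label vectors.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  if (length(pred) == 0) stop("empty label vectors", call. = FALSE)
  mean(pred == truth)
}

#' Enumerate feature-combination modes
#'
#' All non-empty subsets of the given feature kinds: 4 singles, 6 pairs,
#' 4 triples and the full quadruple for the four standard estimators.
#'
#' @param kinds feature kinds.
#' @return list of character vectors, one per mode.
#' @export
enumerate_modes <- function(kinds = c("plv", "pcc", "coh", "mi")) {
  out <- list()
  for (k in seq_along(kinds)) {
    cmb <- utils::combn(kinds, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

mode_label <- function(mode) paste(toupper(mode), collapse = "-")

#' Train and evaluate one feature-combination mode
#'
#' Trains one SPD network per feature kind in `mode` on the training
#' trials, predicts the test trials, and fuses the per-model class
#' probabilities by [average_fusion()] (a single-feature mode bypasses
#' fusion trivially). The split is trial-wise; no test-trial epoch ever
#' reaches training.
#'
#' @param epochs an [epoched_signals()] dataset (or list of them, e.g.
#'   one per subject; accuracies are then reported per element).
#' @param mode character vector of feature kinds, subset of
#'   `c("plv", "pcc", "coh", "mi")`.
#' @param thresholds named threshold vector (`NULL` =
#'   [default_thresholds()]).
#' @param config a [train_config()].
#' @param n_train_trials,n_test_trials trial-wise split sizes.
#' @param hidden_dims BiMap dimensions.
#' @param epsilon Laplacian rectification floor.
#' @param logits fuse on log probabilities instead.
#' @return tibble with one row per dataset (`subject`, `mode`,
#'   `accuracy`) plus attributes `mean` and `sd`; also of class
#'   `experiment_result`.
#' @export
run_mode <- function(epochs, mode, thresholds = NULL,
                     config = train_config(), n_train_trials = 9,
                     n_test_trials = 6, hidden_dims = c(31, 20, 16, 12),
                     epsilon = 1e-4, logits = FALSE) {
  mode <- match.arg(mode, c("plv", "pcc", "coh", "mi"), several.ok = TRUE)
  datasets <- if (inherits(epochs, "epoched_signals")) list(epochs) else epochs
  if (is.null(thresholds)) thresholds <- default_thresholds()
  accs <- numeric(length(datasets))
  for (d in seq_along(datasets)) {
    sp <- split_trials(datasets[[d]], n_train_trials, n_test_trials)
    stopifnot(length(intersect(unique(sp$train$trial_id),
                               unique(sp$test$trial_id))) == 0)
    probs <- vector("list", length(mode))
    for (j in seq_along(mode)) {
      kind <- mode[j]
      tr <- epochs_to_spd(sp$train, kind, thresholds[[kind]], epsilon)
      te <- epochs_to_spd(sp$test, kind, thresholds[[kind]], epsilon)
      fit <- spdnet_train(tr$spd, tr$labels, hidden_dims, config)
      probs[[j]] <- predict(fit, te$spd, type = "prob")
    }
    fused <- average_fusion(probs, logits = logits)
    classes <- sort(unique(datasets[[d]]$labels))
    pred <- classes[fused$predicted]
    accs[d] <- accuracy(pred, sp$test$labels)
  }
  res <- tibble::tibble(subject = seq_along(datasets),
                        mode = mode_label(mode), accuracy = accs)
  structure(res, mean = mean(accs), sd = stats::sd(accs),
            class = c("experiment_result", class(res)))
}

#' Threshold sweep for one feature kind
#'
#' Runs the single-feature pipeline at each threshold with identical
#' data split and seeds, so accuracy differences are attributable to the
#' threshold alone.
#'
#' @inheritParams run_mode
#' @param kind one feature kind.
#' @param thresholds numeric vector of thresholds to sweep. Default grid
#'   is `seq(0.3, 0.9, 0.1)` for PLV/PCC/COH and `seq(0.3, 0.6, 0.05)`
#'   for MI.
#' @return tibble with `threshold`, `mean_accuracy`, `sd_accuracy`.
#' @export
threshold_sweep <- function(epochs, kind, thresholds = NULL,
                            config = train_config(), n_train_trials = 9,
                            n_test_trials = 6,
                            hidden_dims = c(31, 20, 16, 12),
                            epsilon = 1e-4) {
  kind <- match.arg(kind, c("plv", "pcc", "coh", "mi"))
  if (is.null(thresholds)) {
    thresholds <- if (kind == "mi") seq(0.3, 0.6, by = 0.05)
                  else seq(0.3, 0.9, by = 0.1)
  }
  rows <- lapply(thresholds, function(th) {
    thr <- stats::setNames(rep(th, 4), c("plv", "pcc", "coh", "mi"))
    r <- run_mode(epochs, kind, thresholds = thr, config = config,
                  n_train_trials = n_train_trials,
                  n_test_trials = n_test_trials,
                  hidden_dims = hidden_dims, epsilon = epsilon)
    tibble::tibble(threshold = th, mean_accuracy = attr(r, "mean"),
                   sd_accuracy = attr(r, "sd"))
  })
  dplyr::bind_rows(rows)
}

#' Summarize an experiment result
#' @param object an `experiment_result` from [run_mode()].
#' @param ... unused.
#' @return one-row tibble with mode, mean and sd accuracy, n datasets.
#' @method glance experiment_result
#' @export
glance.experiment_result <- function(object, ...) {
  tibble::tibble(mode = object$mode[1], mean_accuracy = attr(object, "mean"),
                 sd_accuracy = attr(object, "sd"), n = nrow(object))
}
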