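# Signal conditioning and the trial-wise partition protocol:
# zero-phase Butterworth bandpass, anti-aliased downsampling,
# non-overlapping 1-s epoching of the trial tail, 9/6 trial split.

#' Epoched multichannel signals
#'
#' Container for segmented EEG: an `epochs x channels x samples` array with
#' sampling rate, per-epoch class labels and trial identity.
#'
#' @param data numeric array, `n_epochs x channels x samples`.
#' @param fs sampling rate in Hz.
#' @param labels integer class label per epoch (0-based).
#' @param trial_id integer trial identity per epoch.
#' @param subject_id,session_id optional identifiers.
#' @return an object of class `epoched_signals`.
#' @export
epoched_signals <- function(data, fs, labels, trial_id,
                            subject_id = NA, session_id = NA) {
  stopifnot(length(dim(data)) == 3, fs > 0)
  n <- dim(data)[1]
  if (length(labels) != n || length(trial_id) != n) {
    stop("labels and trial_id must have one entry per epoch", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, labels = as.integer(labels),
         trial_id = as.integer(trial_id),
         subject_id = subject_id, session_id = session_id),
    class = "epoched_signals"
  )
}

#' @export
print.epoched_signals <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_signals> %d epochs x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs))
  cat(sprintf("  %d trials, %d classes\n",
              length(unique(x$trial_id)), length(unique(x$labels))))
  invisible(x)
}

#' Number of epochs
#' @param x an `epoched_signals` object.
#' @return integer epoch count.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Subset epochs of an `epoched_signals` object
#' @param x an `epoched_signals` object.
#' @param i epoch index vector.
#' @return an `epoched_signals` with the selected epochs.
#' @export
subset_epochs <- function(x, i) {
  epoched_signals(x$data[i, , , drop = FALSE], x$fs, x$labels[i],
                  x$trial_id[i], x$subject_id, x$session_id)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass of the given order forward and backward
#' ([signal::filtfilt()]) so the output is zero-phase; instantaneous-phase
#' estimates downstream (PLV) are undistorted. The effective attenuation
#' order is doubled by the two passes.
#'
#' @param x channels x samples numeric matrix (or vector).
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz.
#' @param order filter order (poles per band edge).
#' @return filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 1, high = 47, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  if (vec) out[1, ] else out
}

#' Downsample with anti-alias filtering
#'
#' Integer decimation uses [signal::decimate()] (8th-order Chebyshev
#' anti-alias filter, applied forward-backward); rational rates use the
#' polyphase FIR resampler [signal::resample()]. Output length is
#' `ceiling(n * fs_out / fs_in)`.
#'
#' @param x channels x samples matrix (or vector).
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return resampled signal.
#' @export
downsample <- function(x, fs_in, fs_out = 200) {
  if (fs_out > fs_in) {
    stop("fs_out must not exceed fs_in", call. = FALSE)
  }
  if (fs_out == fs_in) return(x)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (fs_in %% fs_out == 0) {
    q <- fs_in %/% fs_out
    out <- t(apply(x, 1, function(ch) signal::decimate(ch, q)))
  } else {
    out <- t(apply(x, 1, function(ch) signal::resample(ch, fs_out, fs_in)))
  }
  if (vec) out[1, ] else out
}

#' Segment the tail of a trial into non-overlapping epochs
#'
#' Keeps the final `keep_tail_s` seconds of the trial and cuts them into
#' `keep_tail_s / window_s` non-overlapping windows. Trials shorter than
#' `keep_tail_s` are a hard error; silent truncation would make sample
#' counts differ across trials.
#'
#' @param trial channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param window_s epoch length in seconds.
#' @param keep_tail_s tail length retained, in seconds.
#' @param label class label assigned to every epoch of the trial.
#' @param trial_id trial identifier.
#' @return an `epoched_signals` object.
#' @export
segment_epochs <- function(trial, fs, window_s = 1, keep_tail_s = 120,
                           label = 0L, trial_id = 1L) {
  n <- ncol(trial)
  need <- round(keep_tail_s * fs)
  if (n < need) {
    stop(sprintf(
      "trial %s has %.3f s of data, shorter than the %g s tail required",
      trial_id, n / fs, keep_tail_s), call. = FALSE)
  }
  T_ep <- round(window_s * fs)
  k <- floor(keep_tail_s / window_s)
  tail_x <- trial[, (n - need + 1L):n, drop = FALSE]
  data <- array(0, dim = c(k, nrow(trial), T_ep))
  for (i in seq_len(k)) {
    data[i, , ] <- tail_x[, ((i - 1L) * T_ep + 1L):(i * T_ep)]
  }
  epoched_signals(data, fs, rep(label, k), rep(trial_id, k))
}

#' Combine epoched objects along the epoch axis
#' @param ... `epoched_signals` objects with identical fs, channels, samples.
#' @return one concatenated `epoched_signals`.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) &&
      !inherits(xs[[1]], "epoched_signals")) {
    xs <- xs[[1]]
  }
  d <- dim(xs[[1]]$data)
  data <- array(0, dim = c(sum(vapply(xs, n_epochs, 0L)), d[2], d[3]))
  at <- 0L
  for (x in xs) {
    stopifnot(all(dim(x$data)[2:3] == d[2:3]), x$fs == xs[[1]]$fs)
    data[at + seq_len(n_epochs(x)), , ] <- x$data
    at <- at + n_epochs(x)
  }
  epoched_signals(data, xs[[1]]$fs,
                  unlist(lapply(xs, `[[`, "labels")),
                  unlist(lapply(xs, `[[`, "trial_id")),
                  xs[[1]]$subject_id, xs[[1]]$session_id)
}

#' Trial-wise train/test split
#'
#' Splits by recording trial: the first `n_train_trials` distinct trials
#' (in recording order) form the training set, the next `n_test_trials`
#' the test set. No epoch of one trial ever appears in both sets, so
#' temporally adjacent epochs never straddle the split.
#'
#' @param epochs an `epoched_signals` object.
#' @param n_train_trials,n_test_trials trial counts for each side.
#' @return list with elements `train` and `test` (`epoched_signals`).
#' @export
split_trials <- function(epochs, n_train_trials = 9, n_test_trials = 6) {
  ids <- unique(epochs$trial_id)
  if (length(ids) < n_train_trials + n_test_trials) {
    stop(sprintf("need %d trials, have %d",
                 n_train_trials + n_test_trials, length(ids)), call. = FALSE)
  }
  train_ids <- ids[seq_len(n_train_trials)]
  test_ids <- ids[n_train_trials + seq_len(n_test_trials)]
  list(train = subset_epochs(epochs, epochs$trial_id %in% train_ids),
       test  = subset_epochs(epochs, epochs$trial_id %in% test_ids))
}
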