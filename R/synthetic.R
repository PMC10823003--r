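# Synthetic multichannel EEG with planted, class-conditional coupling.
# Class identity is encoded in WHICH channel pairs share a source, not in
# per-channel power, so a classifier must exploit connectivity structure.

#' Specification of a synthetic EEG dataset
#'
#' Defines the study conditions for the generator: channel count, sampling
#' rate, epoch length, class structure and the coupled channel pairs per
#' class. Coupled pairs share a common source (narrow-band oscillator plus
#' a band-limited broadband component; a squashing nonlinearity is applied
#' to the shared source for `nonlinear_fraction` of the pairs) mixed in at
#' `coupling_strength`; all other channel content is independent noise.
#'
#' @param n_channels number of channels (default 62, a common dense EEG
#'   montage).
#' @param fs sampling rate in Hz.
#' @param epoch_len epoch length in seconds.
#' @param n_classes number of emotion classes.
#' @param n_trials_per_class trials generated per class.
#' @param epochs_per_trial epochs per trial.
#' @param coupling_strength mixing weight of the shared source, in `[0, 1]`;
#'   1 makes coupled channels identical (up to measurement noise).
#' @param coupling_graph list with one element per class, each a 2-column
#'   matrix of 0-based channel pairs. `NULL` uses
#'   [default_coupling_graphs()].
#' @param noise_sd standard deviation of additive white measurement noise,
#'   in units of the unit-variance source signals.
#' @param nonlinear_fraction fraction of coupled pairs whose shared source
#'   passes through a `tanh` squashing nonlinearity.
#' @param seed integer RNG seed; identical seeds give bit-identical data.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_channels = 62, fs = 200, epoch_len = 1,
                           n_classes = 3, n_trials_per_class = 5,
                           epochs_per_trial = 20, coupling_strength = 0.9,
                           coupling_graph = NULL, noise_sd = 0.1,
                           nonlinear_fraction = 0, seed = 1L) {
  if (n_channels < 2 || fs <= 0 || epoch_len <= 0 || n_classes < 2 ||
      n_trials_per_class < 1 || epochs_per_trial < 1) {
    stop("invalid synthetic spec: non-positive or degenerate dimensions",
         call. = FALSE)
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("coupling_strength must lie in [0, 1]", call. = FALSE)
  }
  if (nonlinear_fraction < 0 || nonlinear_fraction > 1) {
    stop("nonlinear_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(coupling_graph)) {
    coupling_graph <- default_coupling_graphs(n_channels, n_classes)
  }
  if (length(coupling_graph) != n_classes) {
    stop("coupling_graph needs one edge set per class", call. = FALSE)
  }
  for (g in coupling_graph) {
    if (length(g) && (any(g < 0) || any(g >= n_channels))) {
      stop("coupling_graph channel indices must be in [0, n_channels)",
           call. = FALSE)
    }
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs, epoch_len = epoch_len,
    n_classes = as.integer(n_classes),
    n_trials_per_class = as.integer(n_trials_per_class),
    epochs_per_trial = as.integer(epochs_per_trial),
    coupling_strength = coupling_strength, coupling_graph = coupling_graph,
    noise_sd = noise_sd, nonlinear_fraction = nonlinear_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Default class-distinctive coupling graphs
#'
#' Class `k` couples the pairs of a greedy distance-`(k+1)` matching on the
#' channel ring, so every class is a perfect or near-perfect matching (each
#' channel in at most one pair) and no two classes share an edge set.
#'
#' @param n_channels channel count.
#' @param n_classes class count.
#' @return list of 2-column 0-based pair matrices, one per class.
#' @export
default_coupling_graphs <- function(n_channels, n_classes) {
  lapply(seq_len(n_classes) - 1L, function(k) {
    used <- logical(n_channels)
    pairs <- NULL
    for (i in seq_len(n_channels) - 1L) {
      j <- (i + k + 1L) %% n_channels
      if (!used[i + 1L] && !used[j + 1L] && i != j) {
        used[c(i, j) + 1L] <- TRUE
        pairs <- rbind(pairs, c(i, j))
      }
    }
    pairs
  })
}

#' Planted adjacency matrix of one class
#'
#' Ground truth for graph-recovery tests: the binary, symmetric,
#' zero-diagonal adjacency of the pairs coupled under `class_id`.
#'
#' @param spec a [synthetic_spec()].
#' @param class_id 0-based class label.
#' @return `n_channels x n_channels` binary matrix.
#' @export
planted_adjacency <- function(spec, class_id) {
  if (class_id < 0 || class_id >= spec$n_classes) {
    stop("unknown class ", class_id, call. = FALSE)
  }
  A <- matrix(0, spec$n_channels, spec$n_channels)
  g <- spec$coupling_graph[[class_id + 1L]]
  if (length(g)) {
    for (r in seq_len(nrow(g))) {
      A[g[r, 1] + 1L, g[r, 2] + 1L] <- 1
      A[g[r, 2] + 1L, g[r, 1] + 1L] <- 1
    }
  }
  A
}

# Band-limited (1-47 Hz) unit-variance noise via FFT masking; exact band
# limits and no filter transients, which keeps epochs statistically
# identical along their length.
bandlimited_noise <- function(T_len, fs, low = 1, high = 47) {
  x <- stats::rnorm(T_len)
  X <- stats::fft(x)
  f <- (seq_len(T_len) - 1) * fs / T_len
  f <- pmin(f, fs - f) # two-sided frequency axis
  X[f < low | f > high] <- 0
  out <- Re(stats::fft(X, inverse = TRUE) / T_len)
  s <- stats::sd(out)
  if (s == 0) out else out / s
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) x - mean(x) else (x - mean(x)) / s
}

# One shared-source realization for a coupled pair.
shared_source <- function(T_len, fs, nonlinear) {
  t_ax <- seq_len(T_len) / fs
  f0 <- stats::runif(1, 8, 12) # alpha-band oscillator
  osc <- sin(2 * pi * f0 * t_ax + stats::runif(1, 0, 2 * pi))
  s <- (osc / stats::sd(osc) + bandlimited_noise(T_len, fs)) / sqrt(2)
  if (nonlinear) s <- standardize(tanh(2 * s))
  s
}

#' Generate a synthetic epoched EEG dataset
#'
#' Draws trials round-robin over classes (trial labels cycle 0, 1, ...,
#' `n_classes - 1` in recording order, so any leading block of trials
#' contains all classes, as in a trial-wise split protocol). Within a
#' class, each coupled pair gets its own shared source per epoch; a
#' channel's signal is the coupling-weighted sum of the sources of its
#' incident edges, plus independent band-limited background and white
#' measurement noise.
#'
#' @param spec a [synthetic_spec()].
#' @return an [epoched_signals()] object with 0-based labels.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  C <- spec$n_channels
  T_len <- round(spec$fs * spec$epoch_len)
  n_trials <- spec$n_trials_per_class * spec$n_classes
  n_ep <- n_trials * spec$epochs_per_trial
  trial_labels <- rep(seq_len(spec$n_classes) - 1L,
                      length.out = n_trials) # round-robin
  data <- array(0, dim = c(n_ep, C, T_len))
  labels <- integer(n_ep)
  trial_id <- integer(n_ep)
  cs <- spec$coupling_strength

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  ep <- 0L
  for (tr in seq_len(n_trials)) {
    y <- trial_labels[tr]
    g <- spec$coupling_graph[[y + 1L]]
    n_edges <- if (length(g)) nrow(g) else 0L
    n_nl <- ceiling(spec$nonlinear_fraction * n_edges)
    for (e in seq_len(spec$epochs_per_trial)) {
      ep <- ep + 1L
      # per-channel source mixes
      mix <- matrix(0, C, T_len)
      deg <- integer(C)
      if (n_edges) {
        for (r in seq_len(n_edges)) {
          s <- shared_source(T_len, spec$fs, nonlinear = r <= n_nl)
          i <- g[r, 1] + 1L; j <- g[r, 2] + 1L
          mix[i, ] <- mix[i, ] + s
          mix[j, ] <- mix[j, ] + s
          deg[c(i, j)] <- deg[c(i, j)] + 1L
        }
        nz <- deg > 0
        mix[nz, ] <- mix[nz, , drop = FALSE] / sqrt(deg[nz])
      }
      private <- t(vapply(seq_len(C),
                          function(cc) bandlimited_noise(T_len, spec$fs),
                          numeric(T_len)))
      # unit variance on every channel: coupled channels trade private
      # background for the shared source, uncoupled keep full background
      w_priv <- sqrt(1 - (cs * (deg > 0))^2)
      x <- cs * mix + w_priv * private
      if (spec$noise_sd > 0) {
        x <- x + spec$noise_sd * matrix(stats::rnorm(C * T_len), C, T_len)
      }
      data[ep, , ] <- x
      labels[ep] <- y
      trial_id[ep] <- tr
    }
  }
  epoched_signals(data, spec$fs, labels, trial_id, subject_id = "synthetic")
}
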