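# Pairwise functional-connectivity estimators and the per-epoch
# channels x channels matrix builder.

CONN_KINDS <- c("plv", "pcc", "coh", "mi")

#' Analytic signal via the frequency-domain Hilbert multiplier
#'
#' Returns `x + i * H(x)` where `H` is the Hilbert transform, computed by
#' zeroing negative frequencies (and doubling positive ones) in the DFT.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

check_pair <- function(x_m, x_n, min_len = 2L) {
  if (length(x_m) != length(x_n)) {
    stop("signals must have equal length", call. = FALSE)
  }
  if (length(x_m) < min_len) {
    stop("signals must have at least ", min_len, " samples", call. = FALSE)
  }
}

check_nonconstant <- function(x, what = "signal") {
  if (stats::sd(x) == 0) {
    stop(what, " has zero variance; estimator undefined", call. = FALSE)
  }
}

# Fraction of samples trimmed from each end of the instantaneous-phase
# series before averaging, to limit Hilbert edge artifacts.
PLV_EDGE_TRIM <- 0.05

phase_trim_idx <- function(n, trim = PLV_EDGE_TRIM) {
  k <- floor(n * trim)
  seq.int(k + 1L, n - k)
}

#' Phase locking value
#'
#' `|mean_t exp(i (phi_m(t) - phi_n(t)))|` with instantaneous phases from
#' the analytic signal. The first and last 5% of samples are excluded from
#' the average to limit Hilbert-transform edge artifacts.
#'
#' @param x_m,x_n numeric signals of equal length.
#' @return scalar in `[0, 1]`; 1 means perfect phase locking.
#' @export
plv <- function(x_m, x_n) {
  check_pair(x_m, x_n)
  check_nonconstant(x_m, "x_m")
  check_nonconstant(x_n, "x_n")
  idx <- phase_trim_idx(length(x_m))
  dphi <- Arg(analytic_signal(x_m))[idx] - Arg(analytic_signal(x_n))[idx]
  min(Mod(mean(exp(1i * dphi))), 1)
}

#' Pearson correlation coefficient between two signals
#'
#' Centered inner product normalized by the product of centered norms.
#'
#' @inheritParams plv
#' @return scalar in `[-1, 1]`.
#' @export
pcc <- function(x_m, x_n) {
  check_pair(x_m, x_n)
  check_nonconstant(x_m, "x_m")
  check_nonconstant(x_n, "x_n")
  stats::cor(x_m, x_n)
}

# Welch cross-spectral estimate for a channels x samples matrix.
# Returns list(freqs, P) with P a C x C x n_freq array of averaged
# cross-periodograms (P[m, n, f] = mean_s F_m conj(F_n)).
welch_cross_spectra <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (is.null(seg_len)) seg_len <- min(n, max(8L, round(fs / 2)))
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1)) # Hann
  nf <- floor(seg_len / 2) + 1L
  C <- nrow(x)
  P <- array(0 + 0i, dim = c(C, C, nf))
  for (s in starts) {
    seg <- x[, s:(s + seg_len - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    Fm <- t(stats::mvfft(t(seg * rep(w, each = C))))[, seq_len(nf), drop = FALSE]
    for (f in seq_len(nf)) {
      P[, , f] <- P[, , f] + Fm[, f] %*% Conj(t(Fm[, f, drop = FALSE]))
    }
  }
  list(freqs = (seq_len(nf) - 1L) * fs / seg_len, P = P / length(starts))
}

#' Band-averaged magnitude-squared coherence
#'
#' Per frequency, `|P_mn(f)|^2 / (P_mm(f) P_nn(f))` from a Welch
#' cross-spectral estimate (0.5-s Hann segments, 50% overlap), then
#' averaged over frequencies inside `band`.
#'
#' @inheritParams plv
#' @param fs sampling rate in Hz.
#' @param band numeric length-2, lower and upper band edge in Hz.
#' @return scalar in `[0, 1]`.
#' @export
coh <- function(x_m, x_n, fs, band = c(1, 47)) {
  check_pair(x_m, x_n, min_len = 8L)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  cs <- welch_cross_spectra(rbind(x_m, x_n), fs)
  sel <- cs$freqs >= band[1] & cs$freqs <= band[2]
  if (!any(sel)) stop("no Welch frequencies inside band", call. = FALSE)
  p11 <- Re(cs$P[1, 1, sel]); p22 <- Re(cs$P[2, 2, sel])
  if (any(p11 <= 0) || any(p22 <= 0)) {
    stop("zero auto-spectrum inside band; coherence undefined", call. = FALSE)
  }
  mean(Mod(cs$P[1, 2, sel])^2 / (p11 * p22))
}

# Equal-width bin indices over a signal's own range.
bin_indices <- function(x, n_bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L
  pmin.int(i, n_bins)
}

mi_from_joint <- function(joint) {
  joint <- joint / sum(joint)
  px <- rowSums(joint)
  py <- colSums(joint)
  ratio <- joint / outer(px, py)
  sum(ifelse(joint > 0, joint * log2(ratio), 0))
}

#' Histogram-based mutual information
#'
#' MI in bits from a joint histogram with `n_bins` equal-width bins per
#' axis spanning each signal's range; `0 log 0` terms contribute zero.
#' Captures nonlinear as well as linear dependence.
#'
#' @inheritParams plv
#' @param n_bins bins per axis (default 16).
#' @return non-negative scalar, in bits.
#' @export
mi <- function(x_m, x_n, n_bins = 16L) {
  check_pair(x_m, x_n)
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  bx <- bin_indices(x_m, n_bins)
  by <- bin_indices(x_n, n_bins)
  tab <- table(factor(bx, levels = seq_len(n_bins)),
               factor(by, levels = seq_len(n_bins)))
  mi_from_joint(unclass(tab))
}

#' Connectivity matrix for one epoch
#'
#' Computes the channels x channels functional-connectivity matrix of one
#' epoch for one estimator. Pairwise values are computed for unordered
#' pairs and mirrored. The diagonal is 1 for PLV/PCC/COH and the
#' per-channel self-MI for MI.
#'
#' @param epoch channels x samples numeric matrix.
#' @param kind one of `"plv"`, `"pcc"`, `"coh"`, `"mi"`.
#' @param fs sampling rate in Hz (needed for `"coh"`).
#' @param band coherence band in Hz.
#' @param n_bins MI histogram bins per axis. The matrix-level default is
#'   8 (not the 16 of [mi()]): on 1-s epochs of a few hundred samples the
#'   8-bin plug-in estimator has a null bias of roughly
#'   `(B-1)^2 / (2 N ln 2)` (about 0.2 bits), keeping independent pairs
#'   well below the 0.3-0.6 MI edge-threshold range, whereas 16 bins
#'   inflate the null above it.
#' @return a symmetric matrix with attributes `kind` (the estimator) of
#'   class `conn_matrix`.
#' @export
connectivity_matrix <- function(epoch, kind = c("plv", "pcc", "coh", "mi"),
                                fs = 200, band = c(1, 47), n_bins = 8L) {
  kind <- match.arg(kind)
  if (!is.matrix(epoch) || nrow(epoch) < 2L) {
    stop("epoch must be a channels x samples matrix with >= 2 channels",
         call. = FALSE)
  }
  C <- nrow(epoch)
  M <- switch(kind,
    plv = {
      idx <- phase_trim_idx(ncol(epoch))
      Z <- t(apply(epoch, 1, function(ch) {
        check_nonconstant(ch, "channel")
        exp(1i * Arg(analytic_signal(ch))[idx])
      }))
      out <- Mod(Z %*% Conj(t(Z))) / length(idx)
      pmin(out, 1)
    },
    pcc = {
      apply(epoch, 1, check_nonconstant, what = "channel")
      stats::cor(t(epoch))
    },
    coh = {
      cs <- welch_cross_spectra(epoch, fs)
      sel <- cs$freqs >= band[1] & cs$freqs <= band[2]
      auto <- vapply(seq_len(C), function(m) Re(cs$P[m, m, sel]),
                     numeric(sum(sel)))
      if (any(auto <= 0)) {
        stop("zero auto-spectrum inside band", call. = FALSE)
      }
      out <- matrix(0, C, C)
      for (f in which(sel)) {
        Pf <- cs$P[, , f]
        out <- out + Mod(Pf)^2 / outer(Re(diag(Pf)), Re(diag(Pf)))
      }
      out / sum(sel)
    },
    mi = {
      B <- t(apply(epoch, 1, bin_indices, n_bins = n_bins))
      out <- matrix(0, C, C)
      for (m in seq_len(C)) {
        for (n in m:C) {
          tab <- table(factor(B[m, ], levels = seq_len(n_bins)),
                       factor(B[n, ], levels = seq_len(n_bins)))
          out[m, n] <- out[n, m] <- mi_from_joint(unclass(tab))
        }
      }
      out
    }
  )
  M <- (M + t(M)) / 2
  if (kind != "mi") diag(M) <- 1
  structure(M, kind = kind, class = c("conn_matrix", class(M)))
}
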