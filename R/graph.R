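# Thresholded connectivity -> undirected graph -> Laplacian -> SPD.
# Eigenvalue rectification of the (always PSD) graph Laplacian is what
# lets connectivity features enter the SPD manifold pipeline.

# Peak-accuracy thresholds per feature from the threshold sweep. The MI
# value is on the 0-0.65 reference scale of the sweep grid; the 8-bin
# per-epoch MI estimator lands on a commensurate scale (see
# connectivity_matrix), so it is applied directly.
DEFAULT_THRESHOLDS <- c(plv = 0.6, pcc = 0.7, mi = 0.35, coh = 0.4)

MI_SCALE_MAX <- 0.65

#' Default per-feature edge thresholds
#'
#' The sweep-optimal values: PLV 0.6, PCC 0.7, MI 0.35, COH 0.4.
#'
#' @param kinds feature kinds to return.
#' @return named numeric vector.
#' @export
default_thresholds <- function(kinds = names(DEFAULT_THRESHOLDS)) {
  DEFAULT_THRESHOLDS[match.arg(kinds, names(DEFAULT_THRESHOLDS),
                               several.ok = TRUE)]
}

#' Threshold a connectivity matrix into an undirected graph
#'
#' Entries with `|value| >= threshold` become edges; by default the edge
#' keeps its magnitude (weighted graph), with `binary = TRUE` it becomes
#' 1. Magnitudes are used so that strong negative correlations (PCC)
#' count as strong connections. The diagonal is ignored (no self-loops).
#'
#' Mutual information has no universal upper bound, so its thresholds
#' are only meaningful relative to an estimator scale. With the default
#' 8-bin per-epoch estimator of [connectivity_matrix()] the observed MI
#' range on 1-s epochs is commensurate with the 0-0.65 reference scale
#' of the MI threshold grid, and thresholds are applied directly. Set
#' `mi_quantile = TRUE` to instead map an MI threshold `t` to the
#' `t / 0.65` quantile of the matrix's off-diagonal values, for MI
#' estimators on a different scale.
#'
#' @param conn connectivity matrix (a `conn_matrix` or plain symmetric
#'   matrix).
#' @param threshold edge threshold.
#' @param binary if `TRUE`, retained edges get weight 1.
#' @param mi_quantile quantile-map MI thresholds (see Details).
#' @return symmetric non-negative adjacency matrix with zero diagonal and
#'   attributes `threshold` and `kind`.
#' @export
threshold_to_adjacency <- function(conn, threshold, binary = FALSE,
                                   mi_quantile = FALSE) {
  kind <- attr(conn, "kind")
  M <- abs(unclass(conn))
  diag(M) <- 0
  thr <- threshold
  if (identical(kind, "mi") && mi_quantile) {
    off <- M[upper.tri(M)]
    thr <- stats::quantile(off, probs = min(1, threshold / MI_SCALE_MAX),
                           names = FALSE, type = 7)
  }
  keep <- (M >= thr) & (M > 0)
  A <- if (binary) keep * 1 else M * keep
  A <- (A + t(A)) / 2
  diag(A) <- 0
  structure(A, threshold = threshold, kind = kind)
}

#' Graph Laplacian
#'
#' `L = D - A` with `D = diag(rowSums(A))`. For any symmetric
#' non-negative `A` the result is symmetric, positive semi-definite, with
#' zero row sums (the constant vector is in the null space).
#'
#' @param A symmetric non-negative adjacency matrix with zero diagonal.
#' @return the Laplacian matrix.
#' @export
graph_laplacian <- function(A) {
  A <- unclass(A)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  diag(rowSums(A)) - A
}

#' Rectify a symmetric PSD matrix into an SPD matrix
#'
#' Eigendecomposes the (symmetrized) input and clamps every eigenvalue
#' below `epsilon` up to `epsilon`, then reconstructs. The output always
#' satisfies [is_spd()] with smallest eigenvalue `>= epsilon`.
#'
#' @param L symmetric matrix (typically a graph Laplacian).
#' @param epsilon eigenvalue floor (default `1e-4`).
#' @return SPD matrix with attribute `epsilon`.
#' @export
rectify_spd <- function(L, epsilon = 1e-4) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  e <- eig_sym(L, "rectify_spd input")
  out <- sym_part(e$vectors %*% (pmax(e$values, epsilon) * t(e$vectors)))
  structure(out, epsilon = epsilon)
}

#' Connectivity epochs to SPD matrices
#'
#' Full graph-construction stage for a set of epochs: per-epoch
#' connectivity, magnitude thresholding, Laplacian, eigenvalue
#' rectification.
#'
#' @param epochs an [epoched_signals()] object.
#' @param kind connectivity estimator, one of `"plv"`, `"pcc"`, `"coh"`,
#'   `"mi"`.
#' @param threshold edge threshold; `NULL` uses [default_thresholds()].
#' @param epsilon rectification floor.
#' @param binary binary instead of weighted edges.
#' @param ... passed to [connectivity_matrix()].
#' @return list with `spd` (`n x C x C` array), `labels`, `trial_id`,
#'   `kind`, `threshold`, `epsilon`.
#' @export
epochs_to_spd <- function(epochs, kind, threshold = NULL, epsilon = 1e-4,
                          binary = FALSE, ...) {
  if (is.null(threshold)) threshold <- default_thresholds(kind)
  n <- n_epochs(epochs)
  C <- dim(epochs$data)[2]
  spd <- array(0, dim = c(n, C, C))
  for (i in seq_len(n)) {
    cm <- connectivity_matrix(epochs$data[i, , ], kind, fs = epochs$fs, ...)
    A <- threshold_to_adjacency(cm, threshold, binary = binary)
    spd[i, , ] <- rectify_spd(graph_laplacian(A), epsilon)
  }
  list(spd = spd, labels = epochs$labels, trial_id = epochs$trial_id,
       kind = kind, threshold = threshold, epsilon = epsilon)
}
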