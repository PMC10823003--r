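# ---- internal helpers -------------------------------------------------------

#' Symmetrize a square matrix
#' @param M square numeric matrix
#' @return `(M + t(M)) / 2`
#' @keywords internal
#' @noRd
sym_part <- function(M) (M + t(M)) / 2

# Eigendecomposition of a symmetrized matrix; stops on non-finite input.
eig_sym <- function(M, what = "matrix") {
  if (!all(is.finite(M))) {
    stop("non-finite entries in ", what, "; cannot eigendecompose",
         call. = FALSE)
  }
  eigen(sym_part(M), symmetric = TRUE)
}

# Apply a scalar function to the spectrum: U f(V) U^t.
spectral_apply <- function(M, f, what = "matrix") {
  e <- eig_sym(M, what)
  sym_part(e$vectors %*% (f(e$values) * t(e$vectors)))
}

assert_spd <- function(S, what = "input", tol = 1e-10) {
  if (!is_spd(S, tol = tol)) {
    stop(what, " must be a symmetric positive definite matrix ",
         "(symmetric within ", format(tol),
         ", all eigenvalues > 1e-12)", call. = FALSE)
  }
}

# ---- public API -------------------------------------------------------------

#' Test whether a matrix is symmetric positive definite
#'
#' A matrix is accepted when it is symmetric within `tol` (elementwise) and
#' its smallest eigenvalue exceeds `1e-12`. Eigenvalues at or below that
#' floor are treated as a domain error by downstream geometry; clamping a
#' semidefinite matrix up to positive definiteness is the job of
#' [rectify_spd()], never of the geometry primitives.
#'
#' @param M square numeric matrix.
#' @param tol symmetry tolerance (maximum absolute difference between `M`
#'   and `t(M)`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_spd(diag(3))
#' is_spd(diag(c(1, -1)))
#' @export
is_spd <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) return(FALSE)
  if (!all(is.finite(M))) stop("non-finite entries in matrix", call. = FALSE)
  if (max(abs(M - t(M))) > tol) return(FALSE)
  ev <- eigen(sym_part(M), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > 1e-12
}

#' Matrix logarithm of an SPD matrix
#'
#' Computes `U log(V) U^t` from the eigendecomposition `S = U V U^t`.
#' The output is exactly symmetrized.
#'
#' @param S SPD matrix.
#' @return symmetric matrix `logm(S)`.
#' @seealso [matrix_exp()], [log_map()]
#' @export
matrix_log <- function(S) {
  assert_spd(S, "matrix_log input")
  spectral_apply(S, log, "matrix_log input")
}

#' Matrix exponential of a symmetric matrix
#'
#' Computes `U exp(V) U^t`; the result is SPD for any symmetric input.
#'
#' @param T_i symmetric matrix.
#' @return SPD matrix `expm(T_i)`.
#' @export
matrix_exp <- function(T_i) {
  if (max(abs(T_i - t(T_i))) > 1e-8) {
    stop("matrix_exp input must be symmetric", call. = FALSE)
  }
  spectral_apply(T_i, exp, "matrix_exp input")
}

# S^(+1/2) and S^(-1/2) in one pass.
spd_sqrt_pair <- function(S) {
  e <- eig_sym(S)
  if (min(e$values) <= 1e-12) {
    stop("matrix square root requires eigenvalues > 1e-12", call. = FALSE)
  }
  r <- sqrt(e$values)
  list(half    = sym_part(e$vectors %*% (r * t(e$vectors))),
       invhalf = sym_part(e$vectors %*% ((1 / r) * t(e$vectors))))
}

#' Logarithmic map on the SPD manifold
#'
#' Projects the SPD matrix `S_i` onto the tangent space at `base` under the
#' affine-invariant metric:
#' `base^{1/2} logm(base^{-1/2} S_i base^{-1/2}) base^{1/2}`.
#'
#' @param base SPD base point.
#' @param S_i SPD matrix to project.
#' @return symmetric tangent-space matrix.
#' @seealso [exp_map()] inverts this map.
#' @export
log_map <- function(base, S_i) {
  assert_spd(base, "log_map base")
  assert_spd(S_i, "log_map point")
  p <- spd_sqrt_pair(base)
  inner <- sym_part(p$invhalf %*% S_i %*% p$invhalf)
  sym_part(p$half %*% spectral_apply(inner, log) %*% p$half)
}

#' Exponential map on the SPD manifold
#'
#' Maps the tangent vector `T_i` at `base` back to the manifold:
#' `base^{1/2} expm(base^{-1/2} T_i base^{-1/2}) base^{1/2}`.
#'
#' @param base SPD base point.
#' @param T_i symmetric tangent matrix.
#' @return SPD matrix.
#' @export
exp_map <- function(base, T_i) {
  assert_spd(base, "exp_map base")
  if (max(abs(T_i - t(T_i))) > 1e-8) {
    stop("exp_map tangent vector must be symmetric", call. = FALSE)
  }
  p <- spd_sqrt_pair(base)
  inner <- sym_part(p$invhalf %*% T_i %*% p$invhalf)
  sym_part(p$half %*% spectral_apply(inner, exp) %*% p$half)
}

#' Affine-invariant geodesic distance between SPD matrices
#'
#' `sqrt(sum(log(lambda_i)^2))` where `lambda_i` are the eigenvalues of
#' `S1^{-1/2} S2 S1^{-1/2}`. Symmetric in its arguments, zero iff the
#' matrices are equal, and invariant under congruence `S -> A^t S A` for
#' any invertible `A`.
#'
#' @param S1,S2 SPD matrices of equal dimension.
#' @return non-negative scalar.
#' @export
geodesic_distance <- function(S1, S2) {
  assert_spd(S1, "geodesic_distance S1")
  assert_spd(S2, "geodesic_distance S2")
  if (!all(dim(S1) == dim(S2))) {
    stop("geodesic_distance requires matrices of equal dimension",
         call. = FALSE)
  }
  p <- spd_sqrt_pair(S1)
  lam <- eigen(sym_part(p$invhalf %*% S2 %*% p$invhalf),
               symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}
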