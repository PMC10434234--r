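#' Maximal canonical correlation between two multivariate signals
#'
#' Computes \eqn{\rho = \max_{w_X, w_Y} \mathrm{corr}(w_X^T X, w_Y^T Y)}, the
#' first canonical correlation between the row spaces of two matrices sharing
#' a sample axis. Both variable sets are mean-centered, orthonormal bases of
#' the centered sample-space columns are taken by thin SVD with effective-rank
#' truncation (singular values below `1e-10` of the largest are dropped, so
#' flat or duplicated channels never crash the solver), and \eqn{\rho} is the
#' largest singular value of the basis cross-product. This QR/SVD route is
#' numerically stabler than explicit covariance inversion; the test suite
#' validates it against an independent covariance-eigendecomposition oracle.
#'
#' @param epoch_data numeric matrix, variables in rows, samples in columns
#'   (an [eeg_epoch] works as-is).
#' @param reference numeric matrix with the same number of columns (samples).
#' @return The maximal canonical correlation, clipped into `[0, 1]`.
#' @examples
#' Y <- make_reference(10, 3, 250, 250)
#' max_canonical_correlation(Y, Y)  # 1
#' @export
max_canonical_correlation <- function(epoch_data, reference) {
  X <- as_plain_matrix(epoch_data)
  Y <- as_plain_matrix(reference)
  if (ncol(X) != ncol(Y))
    stop(sprintf("sample counts differ: %d vs %d", ncol(X), ncol(Y)))
  if (ncol(X) < 2L) stop("need at least 2 samples")
  cca_from_bases(orth_basis(X), orth_basis(Y))
}

as_plain_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("input contains NaN or Inf")
  `attributes<-`(m, list(dim = dim(m)))
}

# Orthonormal basis (samples x rank) of the centered, transposed variable set.
# M: variables x samples. Returns NULL for an all-constant (rank-0) input.
orth_basis <- function(M) {
  A <- t(M)
  A <- sweep(A, 2L, colMeans(A), check.margin = FALSE)
  s <- svd(A, nu = min(dim(A)), nv = 0)
  keep <- s$d > 1e-10 * s$d[1L]
  if (!any(keep)) return(NULL)
  s$u[, keep, drop = FALSE]
}

cca_from_bases <- function(Ux, Uy) {
  if (is.null(Ux) || is.null(Uy)) return(0)
  d <- svd(crossprod(Ux, Uy), nu = 0, nv = 0)$d
  min(max(d[1L], 0), 1)
}
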