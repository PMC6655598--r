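#' Centering matrix
#'
#' Returns the p x p centering (clr) projector \eqn{G = I - \frac{1}{p} 1 1^T}.
#' Multiplying a log-composition vector by \code{G} subtracts its mean, i.e.
#' performs the centered log-ratio transform.  \code{G} is a symmetric
#' idempotent projector with \eqn{G 1 = 0}.
#'
#' @param p Dimension (number of taxa), at least 2.
#' @return A p x p numeric matrix.
#' @examples
#' centering_matrix(3)
#' @export
centering_matrix <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 2 || p != round(p)) {
    stop("`p` must be a single integer >= 2")
  }
  p <- as.integer(p)
  diag(p) - matrix(1 / p, p, p)
}

#' Elementwise soft-thresholding
#'
#' The proximal operator of the (off-diagonal) elementwise l1 norm:
#' \eqn{sign(x) \max(|x| - t, 0)}.  With \code{off_diagonal_only = TRUE} the
#' diagonal passes through unshrunken, matching an off-diagonal-only lasso
#' penalty.
#'
#' @param X Numeric matrix.
#' @param t Nonnegative threshold.
#' @param off_diagonal_only If TRUE, leave the diagonal untouched.
#' @return Matrix of the same shape as \code{X}.
#' @export
soft_threshold <- function(X, t, off_diagonal_only = FALSE) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("threshold `t` must be a single nonnegative number")
  }
  d <- diag(X)
  Y <- sign(X) * pmax(abs(X) - t, 0)
  if (off_diagonal_only) diag(Y) <- d
  Y
}

#' Solve the symmetric half-Sylvester equation (AX + XA)/2 = B
#'
#' This is the closed-form update used by the smooth block of the CDTr ADMM:
#' with the eigendecomposition \eqn{A = U D U^T}, the unique solution is
#' \eqn{X = U [(U^T B U) \circ C] U^T} with \eqn{C_{ij} = 2/(d_i + d_j)}.
#'
#' @param A Symmetric matrix whose eigenvalue pair sums \eqn{d_i + d_j} are
#'   all positive.
#' @param B Right-hand side matrix.
#' @param eig Optional precomputed \code{eigen(A, symmetric = TRUE)}; pass it
#'   when solving repeatedly against the same \code{A}.
#' @return The solution matrix X.
#' @export
half_sylvester_solve <- function(A, B, eig = NULL) {
  if (is.null(eig)) eig <- eigen(A, symmetric = TRUE)
  d <- eig$values
  ss <- outer(d, d, "+")
  if (any(ss <= 0)) {
    stop("operator is singular: some eigenvalue pair sum d_i + d_j <= 0")
  }
  U <- eig$vectors
  U %*% ((crossprod(U, B) %*% U) * (2 / ss)) %*% t(U)
}

#' Solve the weighted linear matrix equation A X B + s X = C
#'
#' Closed-form update used by the quadratic blocks of the DCDTr ADMM.  With
#' \eqn{A = U D_A U^T} and \eqn{B = V D_B V^T}, the unique solution is
#' \eqn{X = U[(U^T C V) \circ W]V^T}, \eqn{W_{ij} = 1/(d_{A,i} d_{B,j} + s)}.
#'
#' @param A,B Symmetric positive semidefinite matrices.
#' @param C Right-hand side matrix.
#' @param s Positive scalar ridge weight.
#' @param eigA,eigB Optional precomputed eigendecompositions of A and B.
#' @return The solution matrix X.
#' @export
weighted_solve <- function(A, B, C, s, eigA = NULL, eigB = NULL) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0) {
    stop("`s` must be a single positive number")
  }
  if (is.null(eigA)) eigA <- eigen(A, symmetric = TRUE)
  if (is.null(eigB)) eigB <- eigen(B, symmetric = TRUE)
  W <- 1 / (outer(eigA$values, eigB$values) + s)
  U <- eigA$vectors
  V <- eigB$vectors
  U %*% ((crossprod(U, C) %*% V) * W) %*% t(V)
}

#' Projection onto the positive semidefinite cone
#'
#' Eigendecomposes a symmetric matrix and floors every eigenvalue at
#' \code{eps}, so the smallest eigenvalue of the result is at least
#' \code{eps}.  With a small positive \code{eps} this keeps ADMM iterates
#' numerically positive definite.
#'
#' @param X Symmetric matrix.
#' @param eps Nonnegative eigenvalue floor.
#' @param sym_tol Tolerance on the allowed asymmetry of \code{X}.
#' @return The projected symmetric matrix.
#' @export
psd_project <- function(X, eps = 0, sym_tol = 1e-8) {
  if (max(abs(X - t(X))) > sym_tol * max(1, max(abs(X)))) {
    stop("`X` must be symmetric")
  }
  e <- eigen((X + t(X)) / 2, symmetric = TRUE)
  v <- pmax(e$values, eps)
  Y <- e$vectors %*% (v * t(e$vectors))
  (Y + t(Y)) / 2
}

## Frobenius norm helper used throughout.
fnorm <- function(X) sqrt(sum(X * X))

## Matrix 1-norm (maximum absolute column sum), the norm used by both BIC
## criteria.
one_norm <- function(X) max(colSums(abs(X)))
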