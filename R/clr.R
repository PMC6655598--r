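#' Sample covariance of log-compositions with its clr-centered form
#'
#' Computes the sample covariance \eqn{\hat\Sigma_{\ln x}} of the row-wise
#' natural-log data and the centered matrix \eqn{G \hat\Sigma_{\ln x} G}.
#' Because \eqn{G \ln x = G \ln z} (the clr bridge: closure only adds a
#' per-sample constant to the logs, which \code{G} annihilates), the centered
#' matrix estimates \eqn{G \Sigma G} of the latent absolute-abundance
#' covariance \eqn{\Sigma} — the only functional of \eqn{\Sigma} that is
#' identifiable from relative abundances.
#'
#' @param x An n x p matrix of strictly positive compositions (rows are
#'   samples), e.g. from [replace_zeros_and_close()] or
#'   [sample_compositions()].  Rows need not sum to one: any per-row positive
#'   rescaling leaves the centered matrix unchanged.
#' @param denominator Either \code{"n-1"} (unbiased, default) or \code{"n"}.
#' @return An object of class \code{"clr_cov"} with components
#'   \item{sigma_lnx}{p x p sample covariance of \eqn{\ln x}.}
#'   \item{centered}{\eqn{G \hat\Sigma_{\ln x} G}, symmetrized.}
#'   \item{n}{number of samples.}
#'   \item{p}{number of taxa.}
#' @examples
#' x <- matrix(rexp(60), 20, 3)
#' x <- x / rowSums(x)
#' cv <- clr_covariance(x)
#' round(rowSums(cv$centered), 12)  # all zero: G projects out the 1-direction
#' @export
clr_covariance <- function(x, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples to form a covariance")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("compositions must be strictly positive and finite; ",
         "replace zeros first (see replace_zeros_and_close())")
  }
  n <- nrow(x)
  p <- ncol(x)
  S <- stats::cov(log(x))
  if (denominator == "n") S <- S * (n - 1) / n
  S <- (S + t(S)) / 2
  G <- centering_matrix(p)
  A <- G %*% S %*% G
  A <- (A + t(A)) / 2
  structure(
    list(sigma_lnx = S, centered = A, n = n, p = p),
    class = "clr_cov"
  )
}

#' @export
print.clr_cov <- function(x, ...) {
  cat("clr covariance: p =", x$p, "taxa, n =", x$n, "samples\n")
  cat("  max |off-diagonal| of centered matrix:",
      signif(max(abs(x$centered[upper.tri(x$centered)])), 4), "\n")
  invisible(x)
}

## Coerce matrix input (a precomputed covariance of log data) for internal
## use; exported fit functions accept either a clr_cov or a raw covariance
## matrix of ln x.
as_clr_cov <- function(cov, n = NULL) {
  if (inherits(cov, "clr_cov")) return(cov)
  S <- as.matrix(cov)
  if (nrow(S) != ncol(S)) stop("covariance must be square")
  p <- nrow(S)
  G <- centering_matrix(p)
  A <- G %*% S %*% G
  A <- (A + t(A)) / 2
  structure(
    list(sigma_lnx = (S + t(S)) / 2, centered = A,
         n = if (is.null(n)) NA_integer_ else n, p = p),
    class = "clr_cov"
  )
}

#' ADMM solver options
#'
#' Collects the tunables shared by [fit_cdtr()], [fit_acdtr()] and
#' [fit_dcdtr()].
#'
#' @param rho Positive augmented-Lagrangian weight (default 1).
#' @param tol Convergence tolerance on the maximum relative Frobenius change
#'   of the primal blocks between iterations (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @param psd_eps Eigenvalue floor for the positive-definite projection
#'   (default 1e-8).
#' @param edge_eps Magnitude above which an off-diagonal entry counts as an
#'   edge (default 1e-8).
#' @param compat_2rhoG If TRUE, the smooth CDTr update builds its operator
#'   from \eqn{G\hat\Sigma G + 2\rho G} instead of \eqn{G\hat\Sigma G +
#'   2\rho I}, with a pseudo-inverse on the null direction.  The default
#'   \code{FALSE} uses \eqn{2\rho I}, which is the exact minimizer of the
#'   ADMM subproblem; see the package vignette.
#' @return A list of class \code{"admm_options"}.
#' @export
admm_options <- function(rho = 1, tol = 1e-6, max_iter = 1000,
                         psd_eps = 1e-8, edge_eps = 1e-8,
                         compat_2rhoG = FALSE) {
  stopifnot(rho > 0, tol > 0, max_iter >= 1, psd_eps >= 0, edge_eps > 0)
  structure(
    list(rho = rho, tol = tol, max_iter = as.integer(max_iter),
         psd_eps = psd_eps, edge_eps = edge_eps,
         compat_2rhoG = isTRUE(compat_2rhoG)),
    class = "admm_options"
  )
}
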