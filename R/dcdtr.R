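#' Empirical DCDTr loss
#'
#' The differential compositional D-trace loss
#' \deqn{L(\Delta) = \frac14\big(\langle A\Delta, \Delta B\rangle +
#'   \langle B\Delta, \Delta A\rangle\big) + \langle\Delta, B' - A'\rangle}
#' with \eqn{A = G\hat\Sigma_{\ln x}G}, \eqn{B = G\hat\Sigma^*_{\ln x}G}
#' and linear target \eqn{G(\hat\Sigma^*_{\ln x}-\hat\Sigma_{\ln x})G}.
#' Its population minimizer under the exchangeable condition is the
#' differential network \eqn{\Delta = \Sigma^{*-1} - \Sigma^{-1}}.
#'
#' @param delta Symmetric p x p matrix.
#' @param cov1,cov2 [clr_covariance()] objects for the two conditions
#'   (condition 1 is the reference; the estimand is precision2 - precision1).
#' @return The scalar loss value.
#' @export
dcdtr_loss <- function(delta, cov1, cov2) {
  cov1 <- as_clr_cov(cov1); cov2 <- as_clr_cov(cov2)
  p <- cov1$p
  if (cov2$p != p) stop("the two covariances must share the same dimension")
  if (!is.matrix(delta) || any(dim(delta) != p)) {
    stop("`delta` must be a ", p, " x ", p, " matrix")
  }
  A <- cov1$centered
  B <- cov2$centered
  D <- B - A
  0.25 * (sum((A %*% delta) * (delta %*% B)) +
          sum((B %*% delta) * (delta %*% A))) + sum(delta * D)
}

#' Fit the DCDTr sparse differential-network estimator
#'
#' Minimizes the lasso-penalized differential loss
#' \deqn{L(\Delta) + \lambda|\Delta|_1}
#' (the l1 penalty covers all entries, diagonal included) over symmetric
#' \eqn{\Delta} by a three-block ADMM.  The two quadratic blocks are solved
#' in closed form by [weighted_solve()] (each carries half of the linear
#' term), and the sparse block is a full-matrix soft threshold.  The blocks
#' are swept in Gauss-Seidel order (each update uses the freshest
#' iterates), which is required for convergence; the parallel (Jacobi)
#' sweep diverges on dense problems.
#'
#' @param cov1,cov2 [clr_covariance()] objects for the two conditions.
#' @param lam Nonnegative penalty.
#' @param opts An [admm_options()] list.
#' @param state Optional warm-start state.
#' @return An object of class \code{"differential_estimate"} with the
#'   symmetrized estimate \code{delta} of precision2 - precision1, logical
#'   off-diagonal \code{support}, penalty, BIC and convergence metadata.
#'   \code{delta} need not be definite in any sense.
#' @export
fit_dcdtr <- function(cov1, cov2, lam, opts = admm_options(), state = NULL) {
  cov1 <- as_clr_cov(cov1); cov2 <- as_clr_cov(cov2)
  p <- cov1$p
  if (cov2$p != p) stop("the two covariances must share the same dimension")
  if (lam < 0) stop("`lam` must be nonnegative")
  A <- cov1$centered
  B <- cov2$centered
  rho <- opts$rho
  D_neg <- A - B   # G(Sigma_hat - Sigma_hat_star)G, the printed C-term
  eigA <- eigen(A, symmetric = TRUE)
  eigB <- eigen(B, symmetric = TRUE)

  if (is.null(state)) {
    d1 <- d2 <- d3 <- matrix(0, p, p)
    l1 <- l2 <- l3 <- matrix(0, p, p)
  } else {
    d1 <- state$d1; d2 <- state$d2; d3 <- state$d3
    l1 <- state$l1; l2 <- state$l2; l3 <- state$l3
  }

  relch <- function(new, old) fnorm(new - old) / max(1, fnorm(old))
  it <- 0L
  converged <- FALSE
  while (it < opts$max_iter) {
    it <- it + 1L
    d1n <- weighted_solve(A, B,
                          2 * rho * d3 + 2 * rho * d2 + D_neg + 2 * l1 - 2 * l3,
                          4 * rho, eigA = eigA, eigB = eigB)
    d2n <- weighted_solve(B, A,
                          2 * rho * d3 + 2 * rho * d1n + D_neg + 2 * l3 - 2 * l2,
                          4 * rho, eigA = eigB, eigB = eigA)
    d3n <- soft_threshold((rho * d1n + rho * d2n - l1 + l2) / (2 * rho),
                          lam / (2 * rho))
    l1 <- l1 + rho * (d3n - d1n)
    l2 <- l2 + rho * (d2n - d3n)
    l3 <- l3 + rho * (d1n - d2n)
    ch <- max(relch(d1n, d1), relch(d2n, d2), relch(d3n, d3))
    res <- max(fnorm(d1n - d3n), fnorm(d2n - d3n)) / max(1, fnorm(d3n))
    d1 <- d1n; d2 <- d2n; d3 <- d3n
    if (ch < opts$tol && res < opts$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("DCDTr ADMM did not converge in ", opts$max_iter, " iterations")
  }
  delta <- (d3 + t(d3)) / 2
  support <- abs(delta) > opts$edge_eps
  diag(support) <- FALSE
  est <- structure(
    list(delta = delta, support = support, lam = lam,
         loss = dcdtr_loss(delta, cov1, cov2), bic = NA_real_,
         n_iter = it, converged = converged,
         asymmetry = fnorm(d3 - t(d3)),
         state = list(d1 = d1, d2 = d2, d3 = d3,
                      l1 = l1, l2 = l2, l3 = l3),
         opts = opts),
    class = "differential_estimate"
  )
  if (!is.na(cov1$n) && !is.na(cov2$n)) {
    est$bic <- bic_dcdtr(est, cov1, cov2, cov1$n, cov2$n)
  }
  est
}

#' BIC for a DCDTr estimate
#'
#' \deqn{BIC = (n + n^*)\,\big\|\tfrac12(B\Delta A + A\Delta B) +
#'   (B - A)\big\|_1 + \log(n + n^*)\,|\Delta|_0}
#' with \eqn{A = G\hat\Sigma G}, \eqn{B = G\hat\Sigma^* G}, the matrix
#' 1-norm, and \eqn{|\Delta|_0} counting upper-triangle nonzeros including
#' the diagonal (the penalized set includes the diagonal; set
#' \code{count_diagonal = FALSE} for the off-diagonal-only count).
#'
#' @param est A \code{"differential_estimate"} or a plain symmetric matrix.
#' @param cov1,cov2 The two [clr_covariance()] objects.
#' @param n1,n2 The two sample sizes.
#' @param count_diagonal Include diagonal nonzeros in the complexity count.
#' @param edge_eps Zero threshold used when \code{est} is a plain matrix.
#' @return The scalar BIC value.
#' @export
bic_dcdtr <- function(est, cov1, cov2, n1, n2, count_diagonal = TRUE,
                      edge_eps = 1e-8) {
  cov1 <- as_clr_cov(cov1); cov2 <- as_clr_cov(cov2)
  if (!is.numeric(n1) || !is.numeric(n2) || n1 < 2 || n2 < 2) {
    stop("sample sizes must be >= 2")
  }
  delta <- if (inherits(est, "differential_estimate")) est$delta else est
  if (inherits(est, "differential_estimate")) edge_eps <- est$opts$edge_eps
  A <- cov1$centered
  B <- cov2$centered
  ntot <- n1 + n2
  fit_term <- one_norm((B %*% delta %*% A + A %*% delta %*% B) / 2 + (B - A))
  nz <- abs(delta) > edge_eps
  k <- sum(nz[upper.tri(nz, diag = count_diagonal)])
  ntot * fit_term + log(ntot) * k
}

#' Penalty grid for DCDTr
#'
#' \eqn{\lambda_{max}} is the largest absolute entry (diagonal included,
#' matching the full-matrix penalty) of
#' \eqn{G(\hat\Sigma^* - \hat\Sigma)G}; at or above it the zero matrix is
#' the exact solution.
#'
#' @inheritParams lambda_grid
#' @param cov1,cov2 The two [clr_covariance()] objects.
#' @return Descending numeric vector of penalties.
#' @export
lambda_grid_differential <- function(cov1, cov2, n_lambda = 40,
                                     min_frac = 0.01) {
  cov1 <- as_clr_cov(cov1); cov2 <- as_clr_cov(cov2)
  lmax <- max(abs(cov2$centered - cov1$centered))
  exp(seq(log(lmax), log(min_frac * lmax), length.out = n_lambda))
}

#' DCDTr penalty path with BIC selection
#'
#' @param cov1,cov2 [clr_covariance()] objects for the two conditions.
#' @param lambdas Descending positive grid; defaults to
#'   [lambda_grid_differential()].
#' @param opts An [admm_options()] list.
#' @return An object of class \code{"dcdtr_path"} with \code{estimates},
#'   \code{lambdas}, \code{bic} and the BIC-minimizing index \code{best}.
#' @export
dcdtr_path <- function(cov1, cov2, lambdas = NULL, opts = admm_options()) {
  cov1 <- as_clr_cov(cov1); cov2 <- as_clr_cov(cov2)
  if (is.null(lambdas)) lambdas <- lambda_grid_differential(cov1, cov2)
  if (length(lambdas) == 0 || any(lambdas <= 0)) {
    stop("`lambdas` must be a nonempty positive grid")
  }
  estimates <- vector("list", length(lambdas))
  state <- NULL
  for (k in seq_along(lambdas)) {
    est <- suppressWarnings(fit_dcdtr(cov1, cov2, lambdas[k], opts,
                                      state = state))
    state <- est$state
    estimates[[k]] <- est
  }
  bic <- vapply(estimates, function(e) e$bic, numeric(1))
  best <- if (all(is.na(bic))) NA_integer_ else which.min(bic)
  structure(
    list(estimates = estimates, lambdas = lambdas, bic = bic, best = best),
    class = "dcdtr_path"
  )
}

#' @export
print.differential_estimate <- function(x, ...) {
  p <- nrow(x$delta)
  cat(sprintf("DCDTr differential estimate: p = %d, lambda = %.4g\n",
              p, x$lam))
  cat(sprintf("  differential edges: %d / %d pairs, BIC = %.6g\n",
              sum(x$support[upper.tri(x$support)]), p * (p - 1) / 2, x$bic))
  cat(sprintf("  ADMM: %d iterations, converged = %s\n",
              x$n_iter, x$converged))
  invisible(x)
}

#' @export
print.dcdtr_path <- function(x, ...) {
  cat(sprintf("DCDTr path over %d penalties; BIC-selected lambda = %.4g (index %d)\n",
              length(x$lambdas), x$lambdas[x$best], x$best))
  invisible(x)
}
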