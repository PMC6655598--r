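#' Empirical CDTr loss
#'
#' The compositional D-trace loss
#' \eqn{L(\Theta) = \frac12 \langle \Theta^2, G\hat\Sigma_{\ln x}G\rangle -
#' \langle \Theta, G\rangle} with \eqn{\langle X, Y\rangle = tr(X Y^T)}.
#' Under the exchangeable condition \eqn{G\Sigma = \Sigma G} its population
#' version is minimized exactly at \eqn{\Theta = \Sigma^{-1}}.
#'
#' @param theta Symmetric p x p matrix.
#' @param cov A [clr_covariance()] object (or a covariance matrix of log
#'   data).
#' @return The scalar loss value.
#' @export
cdtr_loss <- function(theta, cov) {
  cov <- as_clr_cov(cov)
  p <- cov$p
  if (!is.matrix(theta) || any(dim(theta) != p)) {
    stop("`theta` must be a ", p, " x ", p, " matrix")
  }
  A <- cov$centered
  G <- centering_matrix(p)
  0.5 * sum((theta %*% theta) * A) - sum(theta * G)
}

## Shared ADMM engine for CDTr (target = G) and aCDTr (target = I).
## Blocks: Theta (smooth quadratic), Theta0 (off-diagonal lasso prox),
## Theta1 (PSD projection); scaled-dual updates for both constraints
## Theta = Theta0 and Theta = Theta1.
admm_cdtr_engine <- function(A, target, lam, opts, state = NULL) {
  p <- nrow(A)
  rho <- opts$rho
  op_mat <- if (opts$compat_2rhoG) {
    A + 2 * rho * centering_matrix(p)
  } else {
    A + diag(2 * rho, p)
  }
  eig <- eigen(op_mat, symmetric = TRUE)
  ss <- outer(eig$values, eig$values, "+")
  ## compat mode leaves a null pair on the all-ones direction: use the
  ## pseudo-inverse there (the RHS has no component along it)
  Cf <- ifelse(abs(ss) < 1e-12, 0, 2 / ss)
  U <- eig$vectors
  solveH <- function(B) U %*% ((crossprod(U, B) %*% U) * Cf) %*% t(U)

  if (is.null(state)) {
    theta <- theta0 <- theta1 <- diag(p)
    l0 <- l1 <- matrix(0, p, p)
  } else {
    theta <- state$theta; theta0 <- state$theta0; theta1 <- state$theta1
    l0 <- state$l0; l1 <- state$l1
  }

  relch <- function(new, old) fnorm(new - old) / max(1, fnorm(old))
  it <- 0L
  converged <- FALSE
  while (it < opts$max_iter) {
    it <- it + 1L
    theta_n <- solveH(target + rho * theta0 + rho * theta1 - l0 - l1)
    theta0_n <- soft_threshold(theta_n + l0 / rho, lam / rho,
                               off_diagonal_only = TRUE)
    theta1_n <- psd_project(theta_n + l1 / rho, opts$psd_eps, sym_tol = Inf)
    l0 <- l0 + rho * (theta_n - theta0_n)
    l1 <- l1 + rho * (theta_n - theta1_n)
    ch <- max(relch(theta_n, theta), relch(theta0_n, theta0),
              relch(theta1_n, theta1))
    res <- max(fnorm(theta_n - theta0_n), fnorm(theta_n - theta1_n)) /
      max(1, fnorm(theta_n))
    theta <- theta_n; theta0 <- theta0_n; theta1 <- theta1_n
    if (ch < opts$tol && res < opts$tol) { converged <- TRUE; break }
  }
  list(theta = theta, theta0 = theta0, theta1 = theta1,
       l0 = l0, l1 = l1, n_iter = it, converged = converged)
}

make_precision_estimate <- function(state, cov, lam, opts, method) {
  th0 <- (state$theta0 + t(state$theta0)) / 2
  support <- abs(th0) > opts$edge_eps
  diag(support) <- FALSE
  theta <- psd_project(th0, opts$psd_eps, sym_tol = Inf)
  est <- structure(
    list(theta = theta, theta_sparse = th0, support = support,
         lam = lam, method = method,
         loss = NA_real_, bic = NA_real_,
         n_iter = state$n_iter, converged = state$converged,
         primal_residual = max(fnorm(state$theta - state$theta0),
                               fnorm(state$theta - state$theta1)),
         state = state, opts = opts),
    class = "precision_estimate"
  )
  est$loss <- if (method == "acdtr") acdtr_objective_part(th0, cov)
              else cdtr_loss(th0, cov)
  if (!is.na(cov$n)) est$bic <- bic_cdtr(est, cov, cov$n)
  est
}

acdtr_objective_part <- function(theta, cov) {
  0.5 * sum((theta %*% theta) * cov$centered) - sum(diag(theta))
}

#' Fit the CDTr sparse precision-matrix estimator
#'
#' Minimizes the lasso-penalized compositional D-trace objective
#' \deqn{\frac12\langle\Theta^2, G\hat\Sigma_{\ln x}G\rangle -
#'   \langle\Theta, G\rangle + \lambda |\Theta|_{1,off}}
#' over symmetric positive-definite \eqn{\Theta} by a three-block ADMM with
#' closed-form updates: a half-Sylvester solve for the smooth block,
#' off-diagonal soft-thresholding for the sparse block, and an eigenvalue
#' floor for the cone block.
#'
#' @param cov A [clr_covariance()] object, or a covariance matrix of log
#'   abundances.
#' @param lam Nonnegative penalty.
#' @param opts An [admm_options()] list.
#' @param state Optional warm-start state from a previous fit.
#' @return An object of class \code{"precision_estimate"}: the positive
#'   definite estimate \code{theta}, its sparse counterpart
#'   \code{theta_sparse} (carrying the exact zeros from the lasso block, and
#'   the matrix used for the BIC), the logical off-diagonal \code{support},
#'   the penalty, loss, BIC, and convergence metadata.
#' @seealso [cdtr_path()] for a tuned penalty path, [fit_acdtr()] for the
#'   approximation variant, [fit_dcdtr()] for differential networks.
#' @export
fit_cdtr <- function(cov, lam, opts = admm_options(), state = NULL) {
  cov <- as_clr_cov(cov)
  if (any(!is.finite(cov$centered))) stop("covariance has non-finite entries")
  if (lam < 0) stop("`lam` must be nonnegative")
  G <- centering_matrix(cov$p)
  st <- admm_cdtr_engine(cov$centered, G, lam, opts, state)
  if (!st$converged) {
    warning("CDTr ADMM did not converge in ", opts$max_iter, " iterations")
  }
  make_precision_estimate(st, cov, lam, opts, "cdtr")
}

#' Fit the aCDTr estimator
#'
#' Identical to [fit_cdtr()] except that the linear term of the loss is
#' \eqn{-\langle\Theta, I\rangle} rather than \eqn{-\langle\Theta, G\rangle}:
#' the plain D-trace loss applied to the clr-centered covariance, treating
#' \eqn{G\hat\Sigma_{\ln x}G} as an approximation of \eqn{\Sigma}.
#'
#' @inheritParams fit_cdtr
#' @return A \code{"precision_estimate"}; see [fit_cdtr()].
#' @export
fit_acdtr <- function(cov, lam, opts = admm_options(), state = NULL) {
  cov <- as_clr_cov(cov)
  if (any(!is.finite(cov$centered))) stop("covariance has non-finite entries")
  if (lam < 0) stop("`lam` must be nonnegative")
  st <- admm_cdtr_engine(cov$centered, diag(cov$p), lam, opts, state)
  if (!st$converged) {
    warning("aCDTr ADMM did not converge in ", opts$max_iter, " iterations")
  }
  make_precision_estimate(st, cov, lam, opts, "acdtr")
}

#' BIC for a CDTr/aCDTr estimate
#'
#' \deqn{BIC = n\,\|(G\hat\Sigma G\,\Theta + \Theta\,G\hat\Sigma G)/2 -
#'   G\|_1 + \log(n)\,|\Theta|_0}
#' where \eqn{\|\cdot\|_1} is the matrix 1-norm (maximum absolute column
#' sum) and \eqn{|\Theta|_0} counts nonzero entries of the strict upper
#' triangle (the penalized set; the diagonal, which is never penalized and
#' never zero, is excluded — set \code{count_diagonal = TRUE} to include
#' it).
#'
#' @param est A \code{"precision_estimate"} or a plain symmetric matrix.
#' @param cov The [clr_covariance()] used for the fit.
#' @param n Sample size.
#' @param count_diagonal Include diagonal nonzeros in the complexity count.
#' @param edge_eps Zero threshold used when \code{est} is a plain matrix.
#' @return The scalar BIC value.
#' @export
bic_cdtr <- function(est, cov, n, count_diagonal = FALSE, edge_eps = 1e-8) {
  cov <- as_clr_cov(cov)
  if (!is.numeric(n) || n < 2) stop("`n` must be a sample count >= 2")
  theta <- if (inherits(est, "precision_estimate")) est$theta_sparse else est
  if (inherits(est, "precision_estimate")) edge_eps <- est$opts$edge_eps
  A <- cov$centered
  G <- centering_matrix(cov$p)
  fit_term <- one_norm((A %*% theta + theta %*% A) / 2 - G)
  nz <- abs(theta) > edge_eps
  k <- sum(nz[upper.tri(nz, diag = count_diagonal)])
  n * fit_term + log(n) * k
}

#' Default penalty grid
#'
#' Log-spaced descending grid from \eqn{\lambda_{max}} (the largest absolute
#' off-diagonal entry of the centered covariance, above which the CDTr
#' support is essentially empty) down to \code{min_frac} times it.
#'
#' @param cov A [clr_covariance()] object or covariance matrix.
#' @param n_lambda Number of grid points (default 40).
#' @param min_frac Ratio of the smallest to the largest penalty (default
#'   0.01).
#' @return Descending numeric vector of penalties.
#' @export
lambda_grid <- function(cov, n_lambda = 40, min_frac = 0.01) {
  cov <- as_clr_cov(cov)
  A <- cov$centered
  lmax <- max(abs(A[upper.tri(A)]))
  exp(seq(log(lmax), log(min_frac * lmax), length.out = n_lambda))
}

#' CDTr / aCDTr penalty path with BIC selection
#'
#' Fits the estimator along a descending penalty grid with warm starts and
#' scores each fit by [bic_cdtr()].
#'
#' @param cov A [clr_covariance()] object (needs a sample size for the BIC).
#' @param lambdas Descending positive penalty grid; defaults to
#'   [lambda_grid()].
#' @param opts An [admm_options()] list.
#' @param method \code{"cdtr"} or \code{"acdtr"}.
#' @return An object of class \code{"cdtr_path"}: a list with
#'   \code{estimates} (one \code{"precision_estimate"} per penalty),
#'   \code{lambdas}, \code{bic}, and \code{best} (index of the BIC
#'   minimizer).
#' @export
cdtr_path <- function(cov, lambdas = NULL, opts = admm_options(),
                      method = c("cdtr", "acdtr")) {
  method <- match.arg(method)
  cov <- as_clr_cov(cov)
  if (is.null(lambdas)) lambdas <- lambda_grid(cov)
  if (length(lambdas) == 0 || any(lambdas <= 0)) {
    stop("`lambdas` must be a nonempty positive grid")
  }
  fit_fun <- if (method == "cdtr") fit_cdtr else fit_acdtr
  estimates <- vector("list", length(lambdas))
  state <- NULL
  for (k in seq_along(lambdas)) {
    est <- suppressWarnings(fit_fun(cov, lambdas[k], opts, state = state))
    state <- est$state
    estimates[[k]] <- est
  }
  bic <- vapply(estimates, function(e) e$bic, numeric(1))
  best <- if (all(is.na(bic))) NA_integer_ else which.min(bic)
  structure(
    list(estimates = estimates, lambdas = lambdas, bic = bic,
         best = best, method = method),
    class = "cdtr_path"
  )
}

#' @export
print.precision_estimate <- function(x, ...) {
  p <- nrow(x$theta)
  cat(sprintf("%s estimate: p = %d, lambda = %.4g\n",
              toupper(x$method), p, x$lam))
  cat(sprintf("  edges: %d / %d pairs, loss = %.6g, BIC = %.6g\n",
              sum(x$support[upper.tri(x$support)]), p * (p - 1) / 2,
              x$loss, x$bic))
  cat(sprintf("  ADMM: %d iterations, converged = %s\n",
              x$n_iter, x$converged))
  invisible(x)
}

#' @export
print.cdtr_path <- function(x, ...) {
  cat(sprintf("%s path over %d penalties; BIC-selected lambda = %.4g (index %d)\n",
              toupper(x$method), length(x$lambdas),
              x$lambdas[x$best], x$best))
  invisible(x)
}
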