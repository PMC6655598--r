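# Independent convex solvers used as oracles.
#
# The ADMM solvers in the package are checked against generic first-order
# splitting methods that share nothing with them beyond the objective:
# Davis-Yin three-operator splitting for the positive-definite-constrained
# precision objectives, and FISTA for the unconstrained differential
# objective.

cdtr_objective <- function(theta, A, target, lam) {
  0.5 * sum((theta %*% theta) * A) - sum(theta * target) +
    lam * sum(abs(theta[row(theta) != col(theta)]))
}

dcdtr_objective <- function(delta, A, B, lam) {
  D <- B - A
  0.25 * (sum((A %*% delta) * (delta %*% B)) +
          sum((B %*% delta) * (delta %*% A))) +
    sum(delta * D) + lam * sum(abs(delta))
}

# min over PSD symmetric theta of 0.5<theta^2, A> - <theta, target> +
# lam |theta|_1,off  via Davis-Yin splitting.
oracle_cdtr <- function(A, target, lam, iters = 30000) {
  p <- nrow(A)
  L <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  gam <- 1.8 / max(L, 1e-8)
  z <- diag(p)
  xg <- NULL
  for (k in seq_len(iters)) {
    xg <- soft_threshold(z, gam * lam, off_diagonal_only = TRUE)
    grad <- (A %*% xg + xg %*% A) / 2 - target
    xh <- psd_project(2 * xg - z - gam * grad, 0, sym_tol = Inf)
    z <- z + xh - xg
  }
  xg
}

# min over symmetric delta of the DCDTr objective via FISTA.
oracle_dcdtr <- function(A, B, lam, iters = 30000) {
  p <- nrow(A)
  L <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values) *
       max(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
  gam <- 1 / max(L, 1e-8)
  D <- B - A
  x <- y <- matrix(0, p, p)
  tk <- 1
  for (k in seq_len(iters)) {
    grad <- (A %*% y %*% B + B %*% y %*% A) / 2 + D
    xn <- soft_threshold(y - gam * grad, gam * lam)
    xn <- (xn + t(xn)) / 2
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- xn + ((tk - 1) / tn) * (xn - x)
    x <- xn
    tk <- tn
  }
  x
}

# small random clr-centered covariance for oracle tests
random_centered_cov <- function(p, n = 4 * p) {
  Z <- matrix(stats::rnorm(n * p), n, p) %*%
    (diag(p) + 0.3 * matrix(stats::runif(p * p, -1, 1), p, p))
  x <- exp(Z)
  x <- x / rowSums(x)
  clr_covariance(x)
}
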