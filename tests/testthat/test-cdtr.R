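test_that("cdtr loss has its closed forms at 0 and I", {
  set.seed(71)
  cv <- random_centered_cov(6)
  p <- 6
  expect_equal(cdtr_loss(matrix(0, p, p), cv), 0)
  expect_equal(cdtr_loss(diag(p), cv),
               0.5 * sum(diag(cv$centered)) - (p - 1))
})

test_that("population CDTr loss is locally minimal at the true precision", {
  # exchangeable (circulant) truth: plug in the population centered
  # covariance and perturb around the inverse
  truth <- make_ground_truth(graph_spec("band_circular", p = 10, seed = 6))
  G <- centering_matrix(10)
  pop <- as_clr <- G %*% truth$sigma %*% G
  cv <- structure(list(sigma_lnx = truth$sigma, centered = pop,
                       n = NA_integer_, p = 10), class = "clr_cov")
  base <- cdtr_loss(truth$theta, cv)
  set.seed(7)
  for (r in 1:50) {
    E <- matrix(rnorm(100, sd = 1), 10)
    E <- (E + t(E)) / 2
    expect_gte(cdtr_loss(truth$theta + 0.05 * E, cv), base - 1e-10)
  }
})

test_that("large penalties empty the off-diagonal support", {
  set.seed(72)
  truth <- make_ground_truth(graph_spec("band_circular", p = 12))
  cv <- clr_covariance(sample_compositions(truth, 40))
  lam_big <- 10 * max(abs(cv$centered[upper.tri(cv$centered)]))
  est <- fit_cdtr(cv, lam_big)
  expect_equal(sum(est$support), 0)
  expect_true(est$converged)
  esta <- fit_acdtr(cv, lam_big)
  expect_equal(sum(esta$support), 0)
})

test_that("ADMM reaches the convex oracle objective (CDTr and aCDTr)", {
  set.seed(73)
  opts <- admm_options(tol = 1e-8, max_iter = 5000)
  for (p in 3:5) {
    for (r in 1:6) {
      cv <- random_centered_cov(p)
      A <- cv$centered
      # CDTr: any positive penalty is well-posed
      lam <- runif(1, 0.02, 0.15)
      fit <- fit_cdtr(cv, lam, opts)
      ours <- cdtr_objective(fit$theta_sparse, A, centering_matrix(p), lam)
      orac <- cdtr_objective(oracle_cdtr(A, centering_matrix(p), lam,
                                         iters = 20000),
                             A, centering_matrix(p), lam)
      expect_lt(abs(ours - orac) / max(1e-8, abs(orac)), 1e-4)
      # aCDTr: the objective is bounded below only for lam > 1/(p-1)
      # (see the vignette), so the oracle comparison stays in that regime
      lam_a <- runif(1, 1.2, 2) / (p - 1)
      fita <- fit_acdtr(cv, lam_a, opts)
      oursa <- cdtr_objective(fita$theta_sparse, A, diag(p), lam_a)
      oraca <- cdtr_objective(oracle_cdtr(A, diag(p), lam_a, iters = 20000),
                              A, diag(p), lam_a)
      expect_lt(abs(oursa - oraca) / max(1e-8, abs(oraca)), 1e-4)
    }
  }
})

test_that("CDTr and aCDTr differ at finite p", {
  set.seed(74)
  cv <- random_centered_cov(6)
  lam <- 0.3   # above 1/(p-1), where both objectives are well-posed
  a <- fit_cdtr(cv, lam)
  b <- fit_acdtr(cv, lam)
  expect_gt(sqrt(sum((a$theta_sparse - b$theta_sparse)^2)), 0)
})

test_that("smooth-block iterate satisfies its stationarity equation", {
  set.seed(75)
  cv <- random_centered_cov(8)
  opts <- admm_options()
  est <- fit_cdtr(cv, 0.05, opts)
  st <- est$state
  A <- cv$centered
  G <- centering_matrix(8)
  # re-run one smooth update from the converged state and check the
  # half-Sylvester contract of the operator it solves
  rhs <- G + opts$rho * st$theta0 + opts$rho * st$theta1 - st$l0 - st$l1
  M <- A + diag(2 * opts$rho, 8)
  X <- half_sylvester_solve(M, rhs)
  resid <- (M %*% X + X %*% M) / 2 - rhs
  expect_lt(sqrt(sum(resid^2)), 1e-8 * max(1, sqrt(sum(rhs^2))))
  # and the engine's own update agrees with the operator contract
  expect_equal(X, st$theta, tolerance = 1e-4)
})

test_that("converged fits are symmetric positive definite with small primal residuals", {
  set.seed(76)
  truth <- make_ground_truth(graph_spec("random", p = 15, prob = 0.15))
  cv <- clr_covariance(sample_compositions(truth, 80))
  opts <- admm_options()
  for (lam in c(0.02, 0.08)) {
    est <- fit_cdtr(cv, lam, opts)
    expect_true(est$converged)
    expect_equal(est$theta, t(est$theta))
    expect_gte(min(eigen(est$theta, symmetric = TRUE,
                         only.values = TRUE)$values), opts$psd_eps / 2)
    expect_lt(est$primal_residual, 50 * opts$tol)
  }
})

test_that("BIC matches the formula and counts penalized entries", {
  set.seed(77)
  cv <- random_centered_cov(3)
  theta <- matrix(c(1.2, 0.3, 0, 0.3, 0.9, -0.2, 0, -0.2, 1.1), 3, 3)
  n <- 37
  A <- cv$centered
  G <- centering_matrix(3)
  M <- (A %*% theta + theta %*% A) / 2 - G
  expected <- n * max(colSums(abs(M))) + log(n) * 2
  expect_equal(bic_cdtr(theta, cv, n), expected, tolerance = 1e-12)
  # zero matrix: fit term is the 1-norm of G itself
  p <- 3
  expect_equal(bic_cdtr(matrix(0, p, p), cv, n),
               n * (2 * (p - 1) / p), tolerance = 1e-12)
  # one extra off-diagonal pair costs exactly log(n)
  theta2 <- theta
  theta2[1, 3] <- theta2[3, 1] <- 1e-4
  M2 <- (A %*% theta2 + theta2 %*% A) / 2 - G
  expect_equal(bic_cdtr(theta2, cv, n) - bic_cdtr(theta, cv, n),
               n * (max(colSums(abs(M2))) - max(colSums(abs(M)))) + log(n),
               tolerance = 1e-10)
})

test_that("path fits warm-start consistently and select a BIC penalty in range", {
  set.seed(78)
  truth <- make_ground_truth(graph_spec("band_circular", p = 12))
  cv <- clr_covariance(sample_compositions(truth, 60))
  lams <- lambda_grid(cv, n_lambda = 10)
  pa <- cdtr_path(cv, lams)
  expect_length(pa$estimates, 10)
  expect_true(pa$best >= 1 && pa$best <= 10)
  # largest penalty of the default grid empties the support
  expect_equal(sum(pa$estimates[[1]]$support), 0)
  # repeated penalty: warm restart reproduces the same estimate
  pa2 <- cdtr_path(cv, c(lams[5], lams[5]))
  expect_equal(pa2$estimates[[1]]$theta_sparse,
               pa2$estimates[[2]]$theta_sparse, tolerance = 1e-5)
})

test_that("BIC-selected support recovers the band graph at large n", {
  set.seed(90)
  truth <- make_ground_truth(graph_spec("band_circular", p = 50,
                                        strength = c(0.1, 0.1)))
  x <- sample_compositions(truth, 2000)
  pa <- cdtr_path(clr_covariance(x))
  r <- support_rates(pa$estimates[[pa$best]]$support, truth$support)
  expect_gte(r["tpr"], 0.9)
  expect_gte(r["tnr"], 0.9)
})

test_that("near-exact recovery from the population covariance", {
  # feed the population centered covariance of an exchangeable truth with a
  # tiny penalty: the estimate must approach the true precision matrix
  truth <- make_ground_truth(graph_spec("band_circular", p = 10, seed = 8))
  G <- centering_matrix(10)
  pop <- G %*% truth$sigma %*% G
  cv <- structure(list(sigma_lnx = truth$sigma, centered = (pop + t(pop)) / 2,
                       n = NA_integer_, p = 10), class = "clr_cov")
  est <- fit_cdtr(cv, 1e-4, admm_options(tol = 1e-8, max_iter = 5000))
  expect_lt(sqrt(sum((est$theta - truth$theta)^2)) /
            sqrt(sum(truth$theta^2)), 0.05)
})
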