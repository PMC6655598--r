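test_that("band pattern follows the circular two-band design", {
  sp <- graph_spec("band_circular", p = 6)
  A <- make_adjacency(sp)
  d <- abs(outer(1:6, 1:6, "-"))
  expect_true(all(A[d == 1 | d == 5] == 1))
  expect_true(all(A[d == 2 | d == 4] == -1))
  expect_true(all(A[d == 3 | d == 0] == 0))
})

test_that("hub graph is a union of stars", {
  sp <- graph_spec("hub", p = 9, n_groups = 3)
  A <- make_adjacency(sp)
  deg <- rowSums(A != 0)
  expect_equal(sum(A[upper.tri(A)] != 0), 6)
  expect_equal(sort(unique(deg)), c(1, 2))
  expect_equal(sum(deg == 2), 3)  # three hubs of degree 2
})

test_that("scale-free graph attaches one edge per arrival and is connected", {
  set.seed(41)
  sp <- graph_spec("scale_free", p = 50)
  A <- make_adjacency(sp)
  expect_equal(sum(A[upper.tri(A)] != 0), 49)
  # connectivity via iterated neighborhood expansion
  reach <- c(1, numeric(49))
  for (k in 1:50) reach <- pmin(1, reach + as.numeric((A != 0) %*% reach))
  expect_true(all(reach > 0))
})

test_that("cluster graph is block-diagonal rings", {
  sp <- graph_spec("cluster", p = 50)
  A <- make_adjacency(sp)
  grp <- rep(1:5, each = 10)
  expect_true(all(A[outer(grp, grp, "!=")] == 0))
  expect_true(all(rowSums(A != 0) == 2))        # every node sits on a ring
  expect_equal(sum(A[upper.tri(A)] != 0), 50)   # 10 edges per cluster
  # circulant blocks: the constant-strength precision has equal row sums
  expect_true(all(abs(diff(rowSums(A))) == 0))
  expect_error(graph_spec("cluster", p = 49), "divisible")
})

test_that("strength assignment is symmetric with magnitudes in [l, u]", {
  set.seed(42)
  for (structure in c("band_circular", "random", "neighbor")) {
    sp <- graph_spec(structure, p = 20)
    A <- make_adjacency(sp)
    Th <- assign_strengths(A, sp)
    expect_equal(Th, t(Th))
    mags <- abs(Th[upper.tri(Th) & Th != 0])
    expect_true(all(mags >= sp$strength[1] - 1e-12 &
                    mags <= sp$strength[2] + 1e-12))
  }
  # degenerate interval gives exactly constant magnitudes
  sp <- graph_spec("band_circular", p = 10, strength = c(0.1, 0.1))
  Th <- assign_strengths(make_adjacency(sp), sp)
  expect_true(all(abs(Th[Th != 0]) == 0.1))
})

test_that("band4 strengths follow the per-distance intervals", {
  set.seed(43)
  sp <- graph_spec("band4", p = 30)
  Th <- assign_strengths(make_adjacency(sp), sp)
  d <- abs(outer(1:30, 1:30, "-"))
  for (m in 1:4) {
    mags <- abs(Th[d == m])
    expect_true(all(mags >= 0.25 - 0.05 * m - 1e-12 &
                    mags <= 0.3 - 0.05 * m + 1e-12))
  }
  expect_true(all(Th[d > 4] == 0))
})

test_that("diagonal stabilization guarantees smallest eigenvalue >= 0.3", {
  p <- 12
  expect_equal(stabilize_diagonal(matrix(0, p, p)), diag(0.3, p))
  set.seed(44)
  for (r in 1:10) {
    M <- matrix(rnorm(p * p, sd = 0.3), p)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    Th <- stabilize_diagonal(M)
    expect_gte(min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values),
               0.3 - 1e-10)
  }
  expect_error(stabilize_diagonal(diag(2)), "zero diagonal")
})

test_that("exact band and cluster constructions satisfy the exchangeable condition", {
  for (structure in c("band_circular", "cluster")) {
    truth <- make_ground_truth(graph_spec(structure, p = 50, seed = 1))
    expect_lt(truth$dev, 1e-10)
    expect_equal(truth$sigma %*% truth$theta, diag(50), tolerance = 1e-8)
  }
  expect_equal(exchangeability_deviation(diag(5)), 0)
  # equal row sums => commutes with the centering projector
  S <- matrix(0.2, 4, 4) + diag(0.8, 4)
  expect_equal(exchangeability_deviation(S), 0)
})

test_that("ground truths are reproducible from the seed", {
  t1 <- make_ground_truth(graph_spec("random", p = 30, seed = 77))
  t2 <- make_ground_truth(graph_spec("random", p = 30, seed = 77))
  expect_identical(t1$theta, t2$theta)
  expect_identical(t1$mu, t2$mu)
})

test_that("rewiring preserves edge count and flags the toggled pairs", {
  set.seed(45)
  truth <- make_ground_truth(graph_spec("random", p = 40, prob = 0.12))
  n_edges <- sum(truth$support[upper.tri(truth$support)])
  dt <- rewire_differential(truth, ratio = 0.1)
  k <- round(0.1 * n_edges)
  expect_equal(sum(dt$truth2$support[upper.tri(dt$truth2$support)]), n_edges)
  expect_equal(sum(dt$differential_support[upper.tri(dt$differential_support)]),
               2 * k)
  # off-diagonal difference is confined to the toggled pairs
  off <- dt$delta
  diag(off) <- 0
  expect_true(all((off != 0) == dt$differential_support))
  # ratio 0 keeps the off-diagonal untouched
  dt0 <- rewire_differential(truth, ratio = 0)
  o1 <- truth$theta; diag(o1) <- 0
  o2 <- dt0$truth2$theta; diag(o2) <- 0
  expect_equal(o1, o2)
})

test_that("compositions close to one and reproduce the centered covariance", {
  truth <- make_ground_truth(graph_spec("band_circular", p = 10, seed = 5))
  x <- sample_compositions(truth, 40, seed = 9)
  expect_equal(rowSums(x), rep(1, 40), tolerance = 1e-12)
  expect_true(all(x > 0))
  expect_identical(x, sample_compositions(truth, 40, seed = 9))
  # Monte-Carlo consistency of the clr bridge at large n
  xl <- sample_compositions(truth, 50000, seed = 10)
  G <- centering_matrix(10)
  target <- G %*% truth$sigma %*% G
  est <- clr_covariance(xl)$centered
  expect_lt(sqrt(sum((est - target)^2)) / sqrt(sum(target^2)), 0.05)
})
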