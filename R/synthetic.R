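#' Specification of a synthetic ground-truth network
#'
#' Describes one of the eight benchmark graph topologies together with the
#' link-strength distribution used to fill the precision matrix.
#'
#' Structures and their parameters:
#' \describe{
#'   \item{band_circular}{+1 at circular distance 1, -1 at circular distance
#'     2 on the p-cycle (pattern signs are fixed; strengths are positive
#'     draws from \code{[l, u]}).}
#'   \item{cluster}{\code{n_groups} equal clusters with no between-cluster
#'     edges; each cluster is a ring (+1 edges at circular distance 1).
#'     The block is circulant, which is what makes the constant-strength
#'     design exchangeable (see the package vignette for why this
#'     construction is used).  Fixed signs.}
#'   \item{random}{each pair is an edge with probability \code{prob};
#'     random sign.}
#'   \item{band4}{edges at plain distance m = 1..4 with magnitude drawn
#'     from \code{[0.25 - 0.05 m, 0.3 - 0.05 m]} and random sign.}
#'   \item{neighbor}{p points dropped uniformly on (0,1); each connects to
#'     its \code{k_neighbors} nearest; random sign.}
#'   \item{scale_free}{preferential attachment starting from two connected
#'     nodes, one edge per arriving node (p - 1 edges); random sign.}
#'   \item{hub}{\code{n_groups} equal groups, first node of each group is a
#'     hub connected to every non-hub of its group; random sign.}
#'   \item{block}{\code{n_groups} equal blocks; within-block edge
#'     probability \code{prob_within}, between-block \code{prob_between};
#'     random sign.}
#' }
#'
#' @param structure One of the eight structure names above.
#' @param p Number of nodes (taxa), default 50.
#' @param strength Length-2 vector \code{c(l, u)}: link-strength magnitudes
#'   are drawn from U(l, u).  Defaults per structure follow the benchmark:
#'   0.1 exactly for band_circular/cluster, U(0.1, 0.2) for random,
#'   scale_free and hub, U(0.05, 0.15) for neighbor; band4 has its own
#'   per-distance intervals and ignores this argument.
#' @param prob Edge probability for the random graph (default 0.1).
#' @param prob_within,prob_between Block-graph probabilities (defaults 0.3
#'   and 0.1).
#' @param k_neighbors Neighbour count for the neighbor graph (default 5).
#' @param n_groups Number of clusters/groups/blocks (default 5; hub uses 3).
#' @param seed Optional RNG seed stored in the spec and applied by
#'   [make_ground_truth()].
#' @return A list of class \code{"graph_spec"}.
#' @export
graph_spec <- function(structure = c("band_circular", "cluster", "random",
                                     "band4", "neighbor", "scale_free",
                                     "hub", "block"),
                       p = 50, strength = NULL, prob = 0.1,
                       prob_within = 0.3, prob_between = 0.1,
                       k_neighbors = 5, n_groups = NULL, seed = NULL) {
  structure <- match.arg(structure)
  if (p < 2) stop("`p` must be at least 2")
  if (is.null(n_groups)) n_groups <- if (structure == "hub") 3L else 5L
  if (is.null(strength)) {
    strength <- switch(structure,
      band_circular = c(0.1, 0.1),
      cluster       = c(0.1, 0.1),
      random        = c(0.1, 0.2),
      neighbor      = c(0.05, 0.15),
      scale_free    = c(0.1, 0.2),
      hub           = c(0.1, 0.2),
      block         = c(0.1, 0.2),
      band4         = c(0.05, 0.25))  # pooled range; band4 uses per-distance
  }
  if (length(strength) != 2 || strength[1] > strength[2] || strength[1] < 0) {
    stop("`strength` must be c(l, u) with 0 <= l <= u")
  }
  sign_mode <- if (structure %in% c("band_circular", "cluster")) {
    "fixed_pattern"
  } else {
    "random_sign"
  }
  if (structure %in% c("cluster", "hub", "block") && p %% n_groups != 0) {
    stop("`p` must be divisible by `n_groups` for the ", structure, " graph")
  }
  if (prob < 0 || prob > 1 || prob_within < 0 || prob_within > 1 ||
      prob_between < 0 || prob_between > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(
    list(structure = structure, p = as.integer(p), strength = strength,
         sign_mode = sign_mode, prob = prob, prob_within = prob_within,
         prob_between = prob_between, k_neighbors = as.integer(k_neighbors),
         n_groups = as.integer(n_groups), seed = seed),
    class = "graph_spec"
  )
}

#' Signed adjacency pattern of a graph spec
#'
#' Builds the p x p pattern with entries in \{-1, 0, +1\} and zero diagonal.
#' For the two fixed-pattern structures the signs are part of the design;
#' for the random-sign structures the pattern is 0/1 and signs are drawn
#' later by [assign_strengths()].  Random structures consume the current
#' RNG stream.
#'
#' @param spec A [graph_spec()].
#' @return A symmetric integer-valued pattern matrix.
#' @export
make_adjacency <- function(spec) {
  stopifnot(inherits(spec, "graph_spec"))
  p <- spec$p
  A <- matrix(0, p, p)
  d <- abs(outer(seq_len(p), seq_len(p), "-"))
  switch(spec$structure,
    band_circular = {
      A[d == 1 | d == p - 1] <- 1
      A[d == 2 | d == p - 2] <- -1
    },
    cluster = {
      b <- p / spec$n_groups
      if (b < 3) stop("cluster rings need at least 3 nodes per cluster")
      for (g in seq_len(spec$n_groups)) {
        idx <- (g - 1) * b + seq_len(b)
        db <- abs(outer(seq_len(b), seq_len(b), "-"))
        A[idx, idx] <- (db == 1 | db == b - 1) * 1
      }
    },
    random = {
      ut <- which(upper.tri(A), arr.ind = TRUE)
      on <- stats::runif(nrow(ut)) < spec$prob
      A[ut[on, , drop = FALSE]] <- 1
      A <- A + t(A)
    },
    band4 = {
      A[d >= 1 & d <= 4] <- 1
    },
    neighbor = {
      pts <- stats::runif(p)
      for (i in seq_len(p)) {
        nb <- order(abs(pts - pts[i]))[-1][seq_len(spec$k_neighbors)]
        A[i, nb] <- 1
        A[nb, i] <- 1
      }
    },
    scale_free = {
      deg <- integer(p)
      A[1, 2] <- A[2, 1] <- 1
      deg[1:2] <- 1L
      for (i in seq(3, length.out = max(0, p - 2))) {
        j <- sample.int(i - 1L, 1L, prob = deg[seq_len(i - 1L)])
        A[i, j] <- A[j, i] <- 1
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    },
    hub = {
      b <- p / spec$n_groups
      for (g in seq_len(spec$n_groups)) {
        idx <- (g - 1) * b + seq_len(b)
        hub <- idx[1]
        A[hub, idx[-1]] <- 1
        A[idx[-1], hub] <- 1
      }
    },
    block = {
      b <- p / spec$n_groups
      grp <- rep(seq_len(spec$n_groups), each = b)
      ut <- which(upper.tri(A), arr.ind = TRUE)
      pr <- ifelse(grp[ut[, 1]] == grp[ut[, 2]],
                   spec$prob_within, spec$prob_between)
      on <- stats::runif(nrow(ut)) < pr
      A[ut[on, , drop = FALSE]] <- 1
      A <- A + t(A)
    }
  )
  A
}

#' Fill a signed pattern with link strengths
#'
#' Draws one strength per unordered pair and mirrors it, preserving
#' symmetry.  Fixed-pattern structures multiply the pattern sign by a
#' magnitude from U(l, u); random-sign structures draw the magnitude from
#' U(l, u) and an independent fair sign.  The band4 structure draws the
#' magnitude from its per-distance interval \code{[0.25 - 0.05 m,
#' 0.3 - 0.05 m]} for pairs at plain distance m = 1..4 (pairs outside the
#' band, e.g. edges added by rewiring, fall back to the pooled range).
#'
#' @param pattern Symmetric signed pattern from [make_adjacency()].
#' @param spec The [graph_spec()].
#' @return A symmetric matrix of off-diagonal strengths (zero diagonal).
#' @export
assign_strengths <- function(pattern, spec) {
  stopifnot(inherits(spec, "graph_spec"))
  p <- nrow(pattern)
  Th <- matrix(0, p, p)
  ut <- which(upper.tri(pattern) & pattern != 0, arr.ind = TRUE)
  if (nrow(ut) == 0) return(Th)
  val <- vapply(seq_len(nrow(ut)), function(k) {
    i <- ut[k, 1]; j <- ut[k, 2]
    draw_strength(i, j, pattern[i, j], spec)
  }, numeric(1))
  Th[ut] <- val
  Th + t(Th)
}

draw_strength <- function(i, j, sgn, spec) {
  if (spec$structure == "band4") {
    m <- abs(i - j)
    rng <- if (m >= 1 && m <= 4) c(0.25 - 0.05 * m, 0.3 - 0.05 * m)
           else spec$strength
    return(stats::runif(1, rng[1], rng[2]) * sample(c(-1, 1), 1))
  }
  mag <- stats::runif(1, spec$strength[1], spec$strength[2])
  if (spec$sign_mode == "fixed_pattern") sgn * mag
  else mag * sample(c(-1, 1), 1)
}

#' Stabilize the diagonal of an off-diagonal precision skeleton
#'
#' Sets every diagonal element to \eqn{|e| + 0.3}, where e is the smallest
#' eigenvalue of the zero-diagonal skeleton, so the resulting precision
#' matrix is positive definite with smallest eigenvalue at least 0.3.
#'
#' @param theta_off Symmetric matrix with zero diagonal.
#' @return The stabilized precision matrix.
#' @export
stabilize_diagonal <- function(theta_off) {
  if (max(abs(theta_off - t(theta_off))) > 1e-10) {
    stop("`theta_off` must be symmetric")
  }
  if (any(diag(theta_off) != 0)) stop("`theta_off` must have a zero diagonal")
  e <- min(eigen(theta_off, symmetric = TRUE, only.values = TRUE)$values)
  theta_off + diag(abs(e) + 0.3, nrow(theta_off))
}

#' Generate a ground-truth network
#'
#' Runs the full generator: signed pattern, strength assignment, diagonal
#' stabilization, inversion to the covariance, a mean vector drawn from
#' U(-0.5, 0.5), and the exchangeability deviation
#' \eqn{dev = \|G\Sigma - \Sigma G\|_F}.
#'
#' @param spec A [graph_spec()]; if it carries a seed, the RNG is seeded
#'   before any draw.
#' @return A list of class \code{"ground_truth"} with \code{theta},
#'   \code{sigma}, logical off-diagonal \code{support}, \code{mu},
#'   \code{dev} and the \code{spec}.
#' @export
make_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "graph_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pattern <- make_adjacency(spec)
  theta_off <- assign_strengths(pattern, spec)
  theta <- stabilize_diagonal(theta_off)
  sigma <- solve(theta)
  sigma <- (sigma + t(sigma)) / 2
  mu <- stats::runif(spec$p, -0.5, 0.5)
  support <- theta != 0
  diag(support) <- FALSE
  structure(
    list(theta = theta, sigma = sigma, support = support, mu = mu,
         dev = exchangeability_deviation(sigma), spec = spec),
    class = "ground_truth"
  )
}

#' Rewire a ground truth into a differential pair
#'
#' Toggles a fraction of the edges: k = round(ratio x edge count) existing
#' edges are removed and k previously absent pairs become edges with fresh
#' strengths, keeping the total edge count.  Retained edges keep their
#' strengths; the diagonal of the rewired matrix is re-stabilized
#' independently, so the two conditions differ off-diagonally exactly on
#' the toggled pairs.
#'
#' @param truth A [make_ground_truth()] result (condition 1).
#' @param ratio Fraction of edges to toggle; defaults to 0.4 for the sparse
#'   scale_free and hub structures and 0.1 otherwise.
#' @return A list of class \code{"differential_ground_truth"} with
#'   \code{truth1}, \code{truth2}, \code{delta} (theta2 - theta1) and the
#'   logical off-diagonal \code{differential_support} of toggled pairs.
#' @export
rewire_differential <- function(truth, ratio = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  spec <- truth$spec
  if (is.null(ratio)) {
    ratio <- if (spec$structure %in% c("scale_free", "hub")) 0.4 else 0.1
  }
  if (ratio < 0 || ratio > 1) stop("`ratio` must lie in [0, 1]")
  p <- spec$p
  theta_off <- truth$theta
  diag(theta_off) <- 0
  ut <- upper.tri(theta_off)
  edges <- which(ut & theta_off != 0)
  holes <- which(ut & theta_off == 0)
  k <- round(ratio * length(edges))
  if (k > length(holes)) stop("not enough unconnected pairs to rewire into")
  drop_idx <- if (k > 0) sample(edges, k) else integer(0)
  add_idx <- if (k > 0) sample(holes, k) else integer(0)
  off2 <- theta_off
  off2[drop_idx] <- 0
  for (idx in add_idx) {
    ij <- arrayInd(idx, c(p, p))
    off2[idx] <- draw_strength(ij[1], ij[2], sample(c(-1, 1), 1), spec)
  }
  off2[lower.tri(off2)] <- t(off2)[lower.tri(off2)]
  theta2 <- stabilize_diagonal(off2)
  sigma2 <- solve(theta2)
  sigma2 <- (sigma2 + t(sigma2)) / 2
  support2 <- theta2 != 0
  diag(support2) <- FALSE
  truth2 <- structure(
    list(theta = theta2, sigma = sigma2, support = support2,
         mu = stats::runif(p, -0.5, 0.5),
         dev = exchangeability_deviation(sigma2), spec = spec),
    class = "ground_truth"
  )
  dsupp <- matrix(FALSE, p, p)
  dsupp[c(drop_idx, add_idx)] <- TRUE
  dsupp <- dsupp | t(dsupp)
  structure(
    list(truth1 = truth, truth2 = truth2, delta = theta2 - truth$theta,
         rewire_ratio = ratio, differential_support = dsupp),
    class = "differential_ground_truth"
  )
}

#' Sample compositional data from a ground truth
#'
#' Draws log absolute abundances \eqn{\ln z \sim N(\mu, \Theta^{-1})} and
#' closes each sample to a composition \eqn{x_j = z_j / \sum_k z_k}.
#'
#' @param truth A [make_ground_truth()] result.
#' @param n Number of samples.
#' @param seed Optional RNG seed.
#' @return An n x p matrix of strictly positive rows summing to one, with
#'   the latent log-abundance matrix attached as attribute \code{"log_z"}.
#' @export
sample_compositions <- function(truth, n, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  Z <- MASS::mvrnorm(n, truth$mu, truth$sigma)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  X <- exp(Z)
  X <- X / rowSums(X)
  attr(X, "log_z") <- Z
  X
}

#' Deviation from the exchangeable condition
#'
#' \eqn{dev = \|G\Sigma - \Sigma G\|_F}.  Zero exactly when all row sums of
#' \eqn{\Sigma} are equal, which is the condition under which the inverse
#' covariance exactly minimizes the population CDTr loss.
#'
#' @param sigma Symmetric covariance matrix.
#' @return The scalar deviation.
#' @export
exchangeability_deviation <- function(sigma) {
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("`sigma` must be symmetric")
  }
  G <- centering_matrix(nrow(sigma))
  fnorm(G %*% sigma - sigma %*% G)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %s graph, p = %d, %d edges, dev = %.4g\n",
              x$spec$structure, x$spec$p,
              sum(x$support[upper.tri(x$support)]), x$dev))
  invisible(x)
}

#' @export
print.differential_ground_truth <- function(x, ...) {
  cat(sprintf("differential ground truth: %s graph, p = %d, ratio %.2f, %d toggled pairs\n",
              x$truth1$spec$structure, x$truth1$spec$p, x$rewire_ratio,
              sum(x$differential_support[upper.tri(x$differential_support)])))
  invisible(x)
}
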