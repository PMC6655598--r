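#' True positive / true negative rates of support recovery
#'
#' Compares estimated and true edge sets over the p(p-1)/2 unordered
#' off-diagonal pairs.
#'
#' @param est_support,true_support Logical p x p matrices (only the upper
#'   triangle is used) or 2-column index matrices of unordered pairs.
#' @param p Node count (needed when supports are given as pair lists).
#' @return Named vector \code{c(tpr, tnr)}.  \code{tpr} is \code{NaN} with
#'   a warning when the true support is empty.
#' @export
support_rates <- function(est_support, true_support, p = NULL) {
  est <- support_upper(est_support, p)
  tru <- support_upper(true_support, p)
  if (length(est) != length(tru)) stop("supports have different dimensions")
  nt <- sum(tru)
  nn <- sum(!tru)
  tpr <- if (nt == 0) {
    warning("true support is empty; TPR is undefined")
    NaN
  } else {
    sum(est & tru) / nt
  }
  tnr <- if (nn == 0) NaN else sum(!est & !tru) / nn
  c(tpr = tpr, tnr = tnr)
}

## Normalize a support representation to a logical upper-triangle vector.
support_upper <- function(s, p = NULL) {
  if (is.matrix(s) && ncol(s) == 2 && (!is.logical(s))) {
    if (is.null(p)) stop("`p` is required for pair-list supports")
    M <- matrix(FALSE, p, p)
    M[s] <- TRUE
    M <- M | t(M)
    return(M[upper.tri(M)])
  }
  if (!is.matrix(s)) stop("support must be a matrix")
  (s != 0)[upper.tri(s)]
}

#' ROC curve and AUC over a penalty path
#'
#' Scores each estimate of a [cdtr_path()] or [dcdtr_path()] (or any list
#' of estimates carrying a \code{support} matrix) against a true support,
#' anchors the curve at (0,0) and (1,1), keeps the best (highest-TPR)
#' operating point at tied FPR values, and integrates by the trapezoid
#' rule.  Only off-diagonal pairs are
#' scored: diagonal entries are artifacts of the diagonal stabilization,
#' not edges.
#'
#' @param path A path object or list of estimates.
#' @param true_support Logical p x p matrix of true edges.
#' @return A list of class \code{"roc_result"} with \code{lambdas},
#'   \code{tpr}, \code{tnr}, \code{fpr} and \code{auc}.
#' @export
roc_auc <- function(path, true_support) {
  estimates <- if (inherits(path, c("cdtr_path", "dcdtr_path"))) {
    path$estimates
  } else {
    path
  }
  if (length(estimates) == 0) stop("empty path")
  rates <- vapply(estimates,
                  function(e) support_rates(e$support, true_support),
                  numeric(2))
  lambdas <- vapply(estimates, function(e) e$lam, numeric(1))
  tpr <- rates["tpr", ]
  fpr <- 1 - rates["tnr", ]
  pts_f <- c(0, fpr, 1)
  pts_t <- c(0, tpr, 1)
  agg <- tapply(pts_t, pts_f, max)
  f <- as.numeric(names(agg))
  tp <- as.numeric(agg)
  o <- order(f)
  f <- f[o]; tp <- tp[o]
  auc <- sum(diff(f) * (tp[-1] + tp[-length(tp)]) / 2)
  structure(
    list(lambdas = lambdas, tpr = tpr, tnr = rates["tnr", ], fpr = fpr,
         auc = auc),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d penalties: AUC = %.4f\n", length(x$lambdas),
              x$auc))
  invisible(x)
}

#' Edge reproducibility between a reference and a resampled fit
#'
#' Fraction of the reference network's edges that the resampled network
#' retains: \eqn{|ref \cap res| / |ref|}.  Edges are matched by presence,
#' not by sign.
#'
#' @param reference_support,resample_support Logical p x p support matrices
#'   (or pair lists with \code{p} supplied).
#' @param p Node count for pair-list input.
#' @return A fraction in [0, 1]; \code{NaN} with a warning when the
#'   reference is empty.
#' @export
reproducibility <- function(reference_support, resample_support, p = NULL) {
  ref <- support_upper(reference_support, p)
  res <- support_upper(resample_support, p)
  if (sum(ref) == 0) {
    warning("reference support is empty; reproducibility is undefined")
    return(NaN)
  }
  sum(ref & res) / sum(ref)
}

#' Split-half reproducibility of a network estimator
#'
#' Fits a reference network on the full composition matrix, then repeatedly
#' refits on a random half of the samples (floor(n/2), without replacement)
#' and scores [reproducibility()] of the BIC-selected supports.
#'
#' @param x Composition matrix (samples x taxa).
#' @param fit_fun Function taking a composition matrix and returning a
#'   logical support matrix; defaults to the BIC-selected CDTr support.
#' @param n_repeats Number of random half-splits (default 20).
#' @param seed Optional RNG seed.
#' @return List with the per-repeat fractions and their mean.
#' @export
split_half_reproducibility <- function(x, fit_fun = NULL, n_repeats = 20,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit_fun)) {
    fit_fun <- function(xx) {
      pa <- cdtr_path(clr_covariance(xx))
      pa$estimates[[pa$best]]$support
    }
  }
  ref <- fit_fun(x)
  n <- nrow(x)
  fr <- vapply(seq_len(n_repeats), function(r) {
    idx <- sample.int(n, floor(n / 2))
    reproducibility(ref, fit_fun(x[idx, , drop = FALSE]))
  }, numeric(1))
  list(fractions = fr, mean = mean(fr), reference_support = ref)
}

#' Nonzero-density and degree summary by prevalence set
#'
#' Ranks variables by their fraction of nonzero measurements, splits them
#' into \code{n_sets} near-equal ordered sets, and reports each set's mean
#' nonzero fraction and mean node degree in the estimated network.  Used to
#' check whether recovered edges concentrate on rare (zero-heavy) taxa.
#'
#' @param support Logical p x p support matrix.
#' @param counts Raw count matrix (samples x taxa) aligned with the
#'   support's node set.
#' @param n_sets Number of prevalence sets (default 7).
#' @return A data.frame with one row per set: size, mean nonzero density,
#'   mean degree.
#' @export
density_degree_summary <- function(support, counts, n_sets = 7) {
  p <- ncol(counts)
  if (nrow(support) != p) stop("support and counts disagree on taxa count")
  if (n_sets < 1 || n_sets > p) stop("need 1 <= n_sets <= number of taxa")
  dens <- colMeans(counts != 0)
  deg <- rowSums(support != 0)
  o <- order(dens)
  set_id <- rep(seq_len(n_sets), length.out = 0)
  sizes <- rep(p %/% n_sets, n_sets)
  extra <- p %% n_sets
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  set_id <- rep(seq_len(n_sets), times = sizes)
  data.frame(
    set = seq_len(n_sets),
    size = sizes,
    nonzero_density = as.numeric(tapply(dens[o], set_id, mean)),
    mean_degree = as.numeric(tapply(deg[o], set_id, mean))
  )
}
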