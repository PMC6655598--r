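#' Replicated AUC benchmark for network recovery
#'
#' Reruns one cell of the simulation benchmark: generate a fresh ground
#' truth and compositional dataset per replicate, fit the penalty path,
#' and average the ROC AUC of support recovery across replicates.
#'
#' @param structure Graph structure name (see [graph_spec()]).
#' @param n Sample size per condition.
#' @param method \code{"cdtr"}, \code{"acdtr"} or \code{"dcdtr"}.
#' @param n_reps Number of replicate datasets (default 20).
#' @param seed RNG seed for the whole benchmark.
#' @param spec_args Extra arguments passed to [graph_spec()] (e.g.
#'   \code{strength}, \code{prob}).
#' @param rewire_ratio Edge-toggle fraction for the differential benchmark
#'   (default per [rewire_differential()]).
#' @param lambdas Optional penalty grid; defaults per method.
#' @param opts [admm_options()].
#' @return List with \code{mean_auc}, the per-replicate \code{auc} vector,
#'   and the call parameters.
#' @export
benchmark_auc <- function(structure, n, method = c("cdtr", "acdtr", "dcdtr"),
                          n_reps = 20, seed = NULL, spec_args = list(),
                          rewire_ratio = NULL, lambdas = NULL,
                          opts = admm_options()) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  aucs <- vapply(seq_len(n_reps), function(r) {
    spec <- do.call(graph_spec, c(list(structure = structure), spec_args))
    truth <- make_ground_truth(spec)
    if (method == "dcdtr") {
      dtruth <- rewire_differential(truth, rewire_ratio)
      x1 <- sample_compositions(dtruth$truth1, n)
      x2 <- sample_compositions(dtruth$truth2, n)
      cov1 <- clr_covariance(x1)
      cov2 <- clr_covariance(x2)
      pa <- dcdtr_path(cov1, cov2, lambdas = lambdas, opts = opts)
      roc_auc(pa, dtruth$differential_support)$auc
    } else {
      x <- sample_compositions(truth, n)
      pa <- cdtr_path(clr_covariance(x), lambdas = lambdas, opts = opts,
                      method = method)
      roc_auc(pa, truth$support)$auc
    }
  }, numeric(1))
  list(mean_auc = mean(aucs), auc = aucs, structure = structure, n = n,
       method = method, n_reps = n_reps)
}
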