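#' Read an OTU/taxon count table
#'
#' Parses a rectangular TSV/CSV count table with a header row and row
#' names, returning it in samples x taxa orientation.
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @param orientation \code{"samples_by_taxa"} (default) or
#'   \code{"taxa_by_samples"} (transposed on read).
#' @return A list of class \code{"count_table"} with numeric matrix
#'   \code{values} (samples x taxa), \code{sample_ids} and
#'   \code{taxon_ids}.
#' @export
read_counts <- function(path, format = c("tsv", "csv"),
                        orientation = c("samples_by_taxa",
                                        "taxa_by_samples")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop("non-numeric column(s): ", paste(names(df)[bad], collapse = ", "))
  }
  if (orientation == "taxa_by_samples") m <- t(m)
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(m)[ij[1]], colnames(m)[ij[2]]))
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("sample and taxon labels must be unique")
  }
  structure(
    list(values = m, sample_ids = rownames(m), taxon_ids = colnames(m)),
    class = "count_table"
  )
}

#' Prevalence filtering of a count table
#'
#' Drops taxa observed (nonzero) in fewer than \code{taxon_min_frac} of the
#' samples, then drops samples whose number of nonzero retained taxa falls
#' below \code{sample_min_frac} of the retained taxa.
#'
#' @param counts A [read_counts()] table (or bare matrix, samples x taxa).
#' @param taxon_min_frac,sample_min_frac Fractions in [0, 1] (defaults 0.5,
#'   the conventional 50 percent prevalence rule).
#' @return A filtered \code{"count_table"}.
#' @export
filter_prevalence <- function(counts, taxon_min_frac = 0.5,
                              sample_min_frac = 0.5) {
  m <- if (inherits(counts, "count_table")) counts$values else as.matrix(counts)
  if (taxon_min_frac < 0 || taxon_min_frac > 1 ||
      sample_min_frac < 0 || sample_min_frac > 1) {
    stop("fractions must lie in [0, 1]")
  }
  keep_taxa <- colMeans(m != 0) >= taxon_min_frac
  m2 <- m[, keep_taxa, drop = FALSE]
  keep_samples <- rowMeans(m2 != 0) >= sample_min_frac
  m2 <- m2[keep_samples, , drop = FALSE]
  if (nrow(m2) == 0 || ncol(m2) == 0) {
    stop("prevalence filter removed all samples or taxa")
  }
  structure(
    list(values = m2, sample_ids = rownames(m2), taxon_ids = colnames(m2)),
    class = "count_table"
  )
}

#' Replace zeros and close counts to compositions
#'
#' Replaces zero counts by a multiplicative pseudocount and divides each
#' row by its total, yielding strictly positive rows summing to one.
#'
#' @param counts A [read_counts()] table or bare matrix (samples x taxa).
#' @param pseudo Positive pseudocount replacing each zero (default 0.5).
#' @return An n x p composition matrix with dimnames carried over.
#' @export
replace_zeros_and_close <- function(counts, pseudo = 0.5) {
  m <- if (inherits(counts, "count_table")) counts$values else as.matrix(counts)
  if (pseudo <= 0) stop("`pseudo` must be positive")
  if (any(rowSums(m) == 0)) stop("all-zero sample row(s) present")
  m[m == 0] <- pseudo
  m / rowSums(m)
}

#' Write / read a composition matrix as TSV
#'
#' @param x Composition matrix with optional dimnames.
#' @param path Output file path.
#' @return \code{write_compositions} returns \code{path} invisibly;
#'   \code{read_compositions} returns the numeric matrix.
#' @export
write_compositions <- function(x, path) {
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_compositions
#' @param path File to read.
#' @export
read_compositions <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE))
}

#' Serialize an estimated network to an edge list plus JSON metadata
#'
#' Writes the off-diagonal support (and, for differential estimates, the
#' signed weights) as a three-column TSV \code{i, j, weight} of unordered
#' pairs, and a JSON sidecar with the penalty, BIC and convergence
#' metadata.
#'
#' @param est A \code{"precision_estimate"} or \code{"differential_estimate"}.
#' @param path Path of the TSV; the sidecar gets the same path with
#'   \code{.json} appended.
#' @return \code{path}, invisibly.
#' @export
write_edges <- function(est, path) {
  M <- if (inherits(est, "precision_estimate")) est$theta_sparse else est$delta
  sup <- est$support
  idx <- which(sup & upper.tri(sup), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], weight = M[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    class = class(est), lambda = est$lam, bic = est$bic,
    n_iter = est$n_iter, converged = est$converged,
    n_edges = nrow(df), p = nrow(M)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
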