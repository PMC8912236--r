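#' Drop weakly expressed genes
#'
#' Retains exactly the genes whose fraction of samples with TPM at or above
#' `min_tpm` is at least `min_fraction` (boundary inclusive). The sample set
#' is unchanged. Idempotent.
#'
#' @param matrix An [expression_matrix()] on the TPM scale.
#' @param min_tpm Minimum TPM counted as expressed (default 0.1).
#' @param min_fraction Minimum fraction of samples expressed (default 0.8).
#' @return List with `matrix` (filtered) and `dropped` (gene ids removed).
#' @export
filter_low_expression <- function(matrix, min_tpm = 0.1, min_fraction = 0.8) {
  if (expr_scale(matrix) != "TPM")
    stop("filter_low_expression operates on the TPM scale")
  if (nrow(matrix) == 0 || ncol(matrix) == 0)
    stop("filter_low_expression: empty matrix")
  frac <- rowMeans(unclass(matrix) >= min_tpm)
  keep <- frac >= min_fraction
  list(matrix = matrix[keep, , drop = FALSE],
       dropped = rownames(matrix)[!keep])
}

#' Remove outlier samples
#'
#' Two passes over sample expression profiles:
#' 1. isolation-forest anomaly scores; the top `contamination` fraction of
#'    samples is removed;
#' 2. of the remaining samples, the `variation_fraction` (default 1\%) with
#'    the highest variation score — mean absolute deviation from the
#'    per-gene medians — is also removed.
#'
#' Retained values are never altered, only membership. Deterministic for a
#' fixed seed.
#'
#' @param matrix An [expression_matrix()] (any scale; typically LOG2).
#' @param contamination Fraction removed by the isolation forest, in [0, 0.5).
#' @param variation_fraction Fraction removed by the second pass.
#' @param seed Integer seed for the isolation forest.
#' @return List with `matrix` and `removed` (sample ids, in removal order).
#' @export
remove_outlier_samples <- function(matrix, contamination = 0.01,
                                   variation_fraction = 0.01, seed = 1L) {
  assert_number(contamination, "contamination", min = 0)
  if (contamination >= 0.5) abort_field("contamination", "must be < 0.5")
  assert_number(variation_fraction, "variation_fraction", min = 0, max = 1)
  n <- ncol(matrix)
  if (n < 10) stop("remove_outlier_samples needs at least 10 samples")
  removed <- character(0)
  vals <- unclass(matrix)

  n1 <- if (contamination > 0) ceiling(contamination * n) else 0L
  if (n1 >= n) stop("contamination would remove every sample")
  if (n1 > 0) {
    sc <- isolation_forest_scores(t(vals), seed = seed)
    # deterministic tie-break on sample id
    ord <- order(-sc, colnames(vals))
    removed <- colnames(vals)[ord[seq_len(n1)]]
    vals <- vals[, setdiff(colnames(vals), removed), drop = FALSE]
  }

  n2 <- if (variation_fraction > 0) ceiling(variation_fraction * ncol(vals)) else 0L
  if (n2 > 0 && n2 < ncol(vals)) {
    med <- apply(vals, 1, stats::median)
    mad_score <- colMeans(abs(vals - med))
    ord <- order(-mad_score, colnames(vals))
    rm2 <- colnames(vals)[ord[seq_len(n2)]]
    removed <- c(removed, rm2)
    vals <- vals[, setdiff(colnames(vals), rm2), drop = FALSE]
  }

  list(matrix = matrix[, setdiff(colnames(matrix), removed), drop = FALSE],
       removed = removed)
}

#' Drop genes with zero variance
#'
#' Removes genes whose value is identical across all samples. Warns when
#' nothing survives.
#'
#' @param matrix An [expression_matrix()].
#' @return List with `matrix` and `n_removed`.
#' @export
drop_zero_variance <- function(matrix) {
  vals <- unclass(matrix)
  constant <- apply(vals, 1, function(r) all(r == r[1]))
  if (all(constant)) warning("all genes have zero variance; empty matrix returned")
  list(matrix = matrix[!constant, , drop = FALSE],
       n_removed = sum(constant))
}

#' Quantile normalization
#'
#' Forces every sample to share the reference distribution defined by the
#' rank-wise mean across samples: sort each sample, average across samples
#' at each rank, then hand each value the reference value of its rank.
#' Within-sample rank order is preserved; tied values receive the mean of
#' the reference values over their rank span. Idempotent.
#'
#' @param matrix An [expression_matrix()] on the LOG2 scale with >= 2 samples.
#' @return A quantile-normalized [expression_matrix()].
#' @export
quantile_normalize <- function(matrix) {
  if (expr_scale(matrix) != "LOG2")
    stop("quantile_normalize expects LOG2-scale input (preprocess order: log first)")
  if (ncol(matrix) < 2) stop("quantile_normalize needs at least 2 samples")
  vals <- unclass(matrix)
  ref <- rowMeans(apply(vals, 2, sort))
  cumref <- c(0, cumsum(ref))
  out <- apply(vals, 2, function(x) {
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    (cumref[hi + 1] - cumref[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(vals)
  expression_matrix(out, scale = "LOG2")
}

#' Run the full preprocessing stack
#'
#' Stage order: expression filter (TPM scale) -> log2 transform ->
#' outlier-sample removal -> zero-variance gene drop -> quantile
#' normalization. A per-stage log of removal counts and ids is returned and
#' can be written as a JSON sidecar.
#'
#' @param matrix TPM-scale [expression_matrix()].
#' @param min_tpm,min_fraction See [filter_low_expression()].
#' @param pseudocount See [log_transform()].
#' @param contamination,variation_fraction,seed See [remove_outlier_samples()].
#' @param quantile Logical; apply quantile normalization (default TRUE).
#' @return List with `matrix` (LOG2, normalized) and `log` (named list of
#'   per-stage bookkeeping).
#' @export
preprocess_expression <- function(matrix, min_tpm = 0.1, min_fraction = 0.8,
                                  pseudocount = 1, contamination = 0.01,
                                  variation_fraction = 0.01, seed = 1L,
                                  quantile = TRUE) {
  log <- list(n_genes_in = nrow(matrix), n_samples_in = ncol(matrix))
  f <- filter_low_expression(matrix, min_tpm, min_fraction)
  log$low_expression_dropped <- f$dropped
  m <- log_transform(f$matrix, pseudocount)
  o <- remove_outlier_samples(m, contamination, variation_fraction, seed)
  log$outlier_samples_removed <- o$removed
  z <- drop_zero_variance(o$matrix)
  log$zero_variance_removed <- z$n_removed
  m <- if (quantile) quantile_normalize(z$matrix) else z$matrix
  log$n_genes_out <- nrow(m); log$n_samples_out <- ncol(m)
  list(matrix = m, log = log)
}
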