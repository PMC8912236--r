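#' Expression matrix with an explicit scale flag
#'
#' A gene x sample numeric matrix carrying a `scale` attribute, either
#' `"TPM"` (linear, nonnegative) or `"LOG2"` (log2-transformed). The flag
#' lets every downstream operation refuse inputs on the wrong scale instead
#' of silently double-transforming.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must
#'   have unique row and column names (gene ids / sample ids).
#' @param scale `"TPM"` or `"LOG2"`.
#' @return An `expression_matrix` object (a matrix subclass).
#' @examples
#' m <- expression_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), scale = "TPM")
#' expr_scale(m)
#' @export
expression_matrix <- function(values, scale = c("TPM", "LOG2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    abort_field("values", "must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_field("values", "must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values))) abort_field("gene_ids", "must be unique")
  if (anyDuplicated(colnames(values))) abort_field("sample_ids", "must be unique")
  if (anyNA(values) || any(!is.finite(values)))
    abort_field("values", "must be finite with no missing values")
  if (scale == "TPM" && any(values < 0))
    abort_field("values", "TPM scale requires all values >= 0")
  structure(values, scale = scale, class = c("expression_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("not an expression_matrix: missing scale attribute")
  s
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

# Subsetting keeps the class and scale flag (drop is forced off).
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  out <- NextMethod(drop = FALSE)
  structure(out, scale = attr(x, "scale"),
            class = c("expression_matrix", "matrix", "array"))
}

#' log2-transform a TPM matrix
#'
#' Replaces every value by `log2(value + pseudocount)` and flips the scale
#' flag. Refuses to transform a matrix that is already on the log scale.
#' The default pseudocount of 1 keeps zero TPM at zero.
#'
#' @param matrix An `expression_matrix` on the TPM scale.
#' @param pseudocount Positive offset added before taking logs.
#' @return An `expression_matrix` on the LOG2 scale.
#' @export
log_transform <- function(matrix, pseudocount = 1) {
  if (expr_scale(matrix) != "TPM")
    stop("log_transform: input is already LOG2; refusing to double-transform")
  assert_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) abort_field("pseudocount", "must be > 0")
  expression_matrix(log2(unclass(matrix) + pseudocount), scale = "LOG2")
}

#' Read / write the expression TSV dialect
#'
#' Gene x sample tab-separated text: first column `gene_id`, remaining
#' columns one per sample with sample ids in the header.
#'
#' @param matrix An `expression_matrix`.
#' @param path File path.
#' @param scale Scale flag to attach on read (the file itself is scale-free).
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `expression_matrix`.
#' @export
write_expression_tsv <- function(matrix, path) {
  dt <- data.table::data.table(gene_id = rownames(matrix))
  dt <- cbind(dt, data.table::as.data.table(unclass(matrix)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, scale = c("TPM", "LOG2")) {
  scale <- match.arg(scale)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- genes
  expression_matrix(m, scale = scale)
}
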