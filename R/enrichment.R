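#' Gene-set collection
#'
#' Named, non-empty gene-id sets plus a background universe. Sets are
#' intersected with the universe at test time.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of background gene ids.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(universe)) abort_field("universe", "must be non-empty")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == ""))
    abort_field("sets", "must be a uniquely named list")
  if (any(!lengths(sets))) abort_field("sets", "sets must be non-empty")
  structure(list(sets = lapply(sets, unique), universe = unique(universe)),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated gene ids.
#' Duplicate genes within a set are de-duplicated with a warning.
#'
#' @param path GMT file path.
#' @param universe Background universe; defaults to the union of all sets.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: empty collection returned")
    return(structure(list(sets = list(), universe = universe %||% character(0)),
                     class = "gene_set_collection"))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 gene", i))
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) in set '%s' (line %d); de-duplicated", f[1], i))
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
  }
  gene_set_collection(sets, universe %||% sort(unique(unlist(sets))))
}

#' Write a gene-set collection as GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, descriptions[nm] %||% "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of observing
#' at least `k` of the `K` set members in a query of size `n` drawn from a
#' universe of size `N`. Evaluated in log space via [stats::phyper()].
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Set size within the universe.
#' @param N Universe size.
#' @return The raw p-value in (0, 1].
#' @export
hypergeometric_p <- function(k, n, K, N) {
  assert_count(k, "k"); assert_count(n, "n")
  assert_count(K, "K"); assert_count(N, "N")
  if (k > min(n, K) || n > N || K > N)
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()], which implements exactly that).
#'
#' @param pvals Raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Over-representation analysis of a query gene list
#'
#' One-sided (upper-tail) hypergeometric test of the query against every
#' set in the collection, with BH adjustment across sets. Query genes
#' outside the universe are dropped with a warning.
#'
#' @param query Character vector of gene ids (e.g. the
#'   [extract_used_features()] output).
#' @param collection A [gene_set_collection()].
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return An `enrichment_result` data.frame sorted by adjusted p:
#'   `set`, `overlap`, `set_size`, `query_size`, `universe_size`, `p`,
#'   `p_adj`, `significant`, `genes` (comma-joined overlap ids).
#' @export
enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  uni <- collection$universe
  outside <- setdiff(query, uni)
  if (length(outside))
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
  q <- unique(intersect(query, uni))
  if (!length(q)) stop("empty query after intersecting with the universe")
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], uni)
    ov <- intersect(q, s)
    data.frame(set = nm, overlap = length(ov), set_size = length(s),
               query_size = length(q), universe_size = length(uni),
               p = hypergeometric_p(length(ov), length(q), length(s), length(uni)),
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$p, out$set),
             c("set", "overlap", "set_size", "query_size", "universe_size",
               "p", "p_adj", "significant", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
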