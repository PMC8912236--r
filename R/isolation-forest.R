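# Isolation forest anomaly scoring.
#
# Standard construction: trees grown on subsamples by choosing a random
# feature and a random split point uniform in the feature's current range;
# a point's anomaly score is 2^(-E[h(x)]/c(psi)), where h is the path length
# (with the usual average-BST correction at size-limited leaves) and c(psi)
# the expected path length for the subsample size.

c_factor <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

grow_itree <- function(x, depth, max_depth) {
  n <- nrow(x)
  if (n <= 1 || depth >= max_depth) return(list(size = n))
  # pick a random feature with spread in this node (a few tries, then stop)
  for (try in 1:10) {
    f <- sample.int(ncol(x), 1)
    rng <- range(x[, f])
    if (rng[2] > rng[1]) break
    f <- 0L
  }
  if (f == 0L) return(list(size = n))
  s <- stats::runif(1, rng[1], rng[2])
  left <- x[, f] < s
  if (all(left) || !any(left)) return(list(size = n))
  list(feature = f, split = s,
       left = grow_itree(x[left, , drop = FALSE], depth + 1, max_depth),
       right = grow_itree(x[!left, , drop = FALSE], depth + 1, max_depth))
}

path_lengths <- function(tree, x, idx = seq_len(nrow(x)), depth = 0) {
  out <- numeric(length(idx))
  if (is.null(tree$feature)) {
    out[] <- depth + c_factor(tree$size)
    return(out)
  }
  left <- x[idx, tree$feature] < tree$split
  if (any(left))
    out[left] <- path_lengths(tree$left, x, idx[left], depth + 1)
  if (any(!left))
    out[!left] <- path_lengths(tree$right, x, idx[!left], depth + 1)
  out
}

#' Isolation-forest anomaly scores
#'
#' @param x Numeric matrix, one row per observation.
#' @param n_trees Number of isolation trees.
#' @param subsample Subsample size per tree (capped at n).
#' @param seed Integer seed; scoring is deterministic given it.
#' @return Numeric vector of anomaly scores in (0, 1); larger = more anomalous.
#' @export
isolation_forest_scores <- function(x, n_trees = 100, subsample = 256, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  set.seed(stage_seed(seed, "iforest"))
  psi <- min(subsample, nrow(x))
  max_depth <- ceiling(log2(psi))
  h <- matrix(0, nrow(x), n_trees)
  for (t in seq_len(n_trees)) {
    sub <- x[sample.int(nrow(x), psi), , drop = FALSE]
    tree <- grow_itree(sub, 0, max_depth)
    h[, t] <- path_lengths(tree, x)
  }
  2^(-rowMeans(h) / c_factor(psi))
}
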