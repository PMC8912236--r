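# Independent oracles used across the suite. Each reimplements the target
# quantity from its definition, by a different computational route than the
# package.

# AUC as the literal fraction of concordant positive-negative pairs,
# ties counting one half.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

oracle_confusion_metrics <- function(y, s, threshold = 0.5) {
  pred <- ifelse(s >= threshold, 1, 0)
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- tp / (tp + fn)
  list(accuracy = (tp + tn) / length(y),
       precision = prec, recall = rec,
       f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

# OLS by the normal equations, (X'X)^-1 X'y.
oracle_ols <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# Quantile normalization straight from the definition, with the
# mean-over-rank-span tie rule, one value at a time.
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    sorted <- sort(x)
    for (i in seq_along(x)) {
      span <- which(sorted == x[i])
      out[i, j] <- mean(ref[span])
    }
  }
  out
}

# Textbook step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# Exact upper-tail hypergeometric p-values, precomputed with exact rational
# arithmetic (integer combinatorics) and frozen.
hyper_oracle_cases <- list(
  list(N = 20L, K = 5L, n = 5L, k = 3L, p = 0.07262641898864809),
  list(N = 60L, K = 25L, n = 30L, k = 18L, p = 0.004107016902670264),
  list(N = 60L, K = 10L, n = 40L, k = 9L, p = 0.08377902510209558),
  list(N = 55L, K = 20L, n = 20L, k = 12L, p = 0.007037698288466956),
  list(N = 40L, K = 15L, n = 25L, k = 13L, p = 0.01531773709193064),
  list(N = 60L, K = 30L, n = 30L, k = 20L, p = 0.009691594130894984),
  list(N = 33L, K = 7L, n = 11L, k = 5L, p = 0.027437893956247683),
  list(N = 60L, K = 5L, n = 12L, k = 0L, p = 1.0),
  list(N = 50L, K = 25L, n = 10L, k = 10L, p = 0.0003182117876778643))

# --- Shapley oracle -------------------------------------------------------
# Global exhaustive-subset Shapley values for a tree ensemble, with its own
# recursive cover-weighted expectation (independent of the package's
# per-tree enumeration). Feasible for <= 10 features.

oracle_tree_expect <- function(tree, xrow, coalition) {
  walk <- function(node) {
    if (is.na(tree$feature[node])) return(tree$value[node])
    f <- tree$feature[node]
    if (f %in% coalition) {
      if (xrow[f] < tree$split[node]) walk(tree$yes[node]) else walk(tree$no[node])
    } else {
      cy <- tree$cover[tree$yes[node]]; cn <- tree$cover[tree$no[node]]
      (cy * walk(tree$yes[node]) + cn * walk(tree$no[node])) / (cy + cn)
    }
  }
  walk(1)
}

oracle_shapley <- function(trees, xrow, features) {
  m <- length(features)
  v <- function(coal) sum(vapply(trees, oracle_tree_expect, numeric(1),
                                 xrow = xrow, coalition = coal))
  phi <- setNames(numeric(m), features)
  subsets <- lapply(0:(2^m - 1), function(mask)
    features[bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L])
  for (i in seq_len(m)) {
    fi <- features[i]
    for (S in subsets) {
      if (fi %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(m - s - 1) / factorial(m)
      phi[i] <- phi[i] + w * (v(c(S, fi)) - v(S))
    }
  }
  phi
}

# --- fixtures -------------------------------------------------------------

tiny_cohort <- function(n = 120, genes = 200, markers = 10, effect = 1,
                        seed = 42, ...) {
  generate_cohort(cohort_config(n_samples = n, n_genes = genes,
                                n_mv_markers = markers,
                                mv_effect_size = effect,
                                n_ischemic_genes = min(20, genes - markers),
                                seed = seed, ...))
}

aligned_covariates <- function(cov, matrix) {
  out <- cov[match(colnames(matrix), cov$sample_id), ]
  class(out) <- c("sample_covariates", "data.frame")
  out
}
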