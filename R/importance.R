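# Additive (Shapley) feature attribution for tree ensembles.
#
# For a tree ensemble the model is a sum of per-tree games, so Shapley
# values add across trees and each tree's Shapley values involve only the
# features that tree actually splits on (every other feature is a null
# player). With depth <= 3 a tree touches at most 7 distinct features, so
# the per-tree Shapley value is computed *exactly* by enumerating all
# subsets of that tree's own features, with the conditional expectation of
# the tree under a subset estimated by cover-weighted marginalization (the
# tree-SHAP value function): at a split on an out-of-coalition feature,
# both branches are averaged with weights proportional to their training
# cover. Everything is done in double precision on the extracted tree
# table.

# xgboost stores features and thresholds in single precision; rounding the
# feature matrix through float32 makes the double-precision traversal route
# samples exactly as the fitted model does.
round_float32 <- function(v) {
  out <- readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
                 n = length(v), size = 4L)
  if (is.matrix(v)) out <- matrix(out, nrow(v), dimnames = dimnames(v))
  out
}

# Normalized tree table from a gradient-boosting handle:
# one data.frame per tree with columns feature (NA for leaf), split, yes,
# no (row indices), cover, value (leaf).
extract_gbt_trees <- function(model) {
  stopifnot(inherits(model, "ventsig_model"),
            model$family == "gradient_boosting")
  dt <- xgboost::xgb.model.dt.tree(model = model$fit)
  dt <- as.data.frame(dt)
  leaf_col <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  lapply(split(dt, dt$Tree), function(tr) {
    id2row <- stats::setNames(seq_len(nrow(tr)), tr$ID)
    is_leaf <- tr$Feature == "Leaf"
    data.frame(
      feature = ifelse(is_leaf, NA_character_, tr$Feature),
      split = round_float32(ifelse(is_leaf, NA_real_, tr$Split)),
      yes = ifelse(is_leaf, NA_integer_, id2row[tr$Yes]),
      no = ifelse(is_leaf, NA_integer_, id2row[tr$No]),
      cover = tr$Cover,
      value = ifelse(is_leaf, tr[[leaf_col]], NA_real_),
      stringsAsFactors = FALSE)
  })
}

# Cover-weighted conditional expectation of one tree for all samples, with
# the coalition given as a character vector of feature names.
tree_expvalue <- function(tree, x, coalition) {
  rec <- function(node) {
    if (is.na(tree$feature[node])) return(rep(tree$value[node], nrow(x)))
    f <- tree$feature[node]
    yes <- rec(tree$yes[node]); no <- rec(tree$no[node])
    if (f %in% coalition) {
      ifelse(x[, f] < tree$split[node], yes, no)
    } else {
      cy <- tree$cover[tree$yes[node]]; cn <- tree$cover[tree$no[node]]
      (cy * yes + cn * no) / (cy + cn)
    }
  }
  rec(1)
}

# Exact Shapley values of one tree over its own feature set.
tree_shapley <- function(tree, x) {
  feats <- unique(tree$feature[!is.na(tree$feature)])
  m <- length(feats)
  n <- nrow(x)
  base <- tree_expvalue(tree, x, character(0))
  if (m == 0) return(list(phi = NULL, base = base))
  if (m > 14) stop("tree uses too many features for exact subset enumeration")
  n_masks <- bitwShiftL(1L, m)
  V <- matrix(0, n, n_masks)
  for (mask in 0:(n_masks - 1L)) {
    coal <- feats[bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L) == 1L]
    V[, mask + 1L] <- tree_expvalue(tree, x, coal)
  }
  sizes <- vapply(0:(n_masks - 1L), function(mm)
    sum(bitwAnd(bitwShiftR(mm, 0:(m - 1L)), 1L)), numeric(1))
  w <- factorial(0:(m - 1)) * factorial(m - 1 - 0:(m - 1)) / factorial(m)
  phi <- matrix(0, n, m, dimnames = list(NULL, feats))
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(n_masks - 1L), bit) == 0L)
    for (mm in without) {
      s <- sizes[mm]
      phi[, i] <- phi[, i] + w[s + 1] * (V[, mm + bit] - V[, mm])
    }
  }
  list(phi = phi, base = base)
}

#' Exact Shapley attributions for a gradient-boosting model
#'
#' Per-sample, per-gene additive decomposition of the raw model output
#' (the logit margin): `base_value + rowSums(attributions)` equals the
#' model's margin for every sample. Exact per-tree subset enumeration in
#' double precision; for non-tree families use [shap_permutation()].
#'
#' @param model A `ventsig_model` of family `gradient_boosting`.
#' @param features Sample x gene numeric matrix to attribute.
#' @return List with `attributions` (sample x gene matrix, zero for genes
#'   never split on), `base_value` (scalar), and `margin` (the model's raw
#'   output per sample, for additivity checks).
#' @export
shap_values <- function(model, features) {
  if (!inherits(model, "ventsig_model") || model$family != "gradient_boosting")
    stop("exact tree attribution supports gradient_boosting only; ",
         "use shap_permutation() as the model-agnostic fallback")
  x <- round_float32(features[, model$feature_names, drop = FALSE])
  trees <- extract_gbt_trees(model)
  phi <- matrix(0, nrow(x), ncol(x), dimnames = list(rownames(x), colnames(x)))
  tree_base <- 0
  tree_out <- numeric(nrow(x))
  for (tr in trees) {
    res <- tree_shapley(tr, x)
    tree_base <- tree_base + res$base[1]
    if (!is.null(res$phi))
      phi[, colnames(res$phi)] <- phi[, colnames(res$phi), drop = FALSE] + res$phi
    tree_out <- tree_out + tree_expvalue(tr, x, colnames(x))
  }
  margin <- stats::predict(model$fit,
                           xgboost::xgb.DMatrix(x, nthread = 1),
                           outputmargin = TRUE)
  b0 <- stats::median(margin - tree_out)   # global base margin (constant)
  list(attributions = phi, base_value = tree_base + b0, margin = margin)
}

#' Permutation-sampling Shapley fallback for any model family
#'
#' Monte-Carlo estimate of Shapley values with marginal (background-sample)
#' feature replacement. Slower and approximate; intended for the neural-net
#' and random-forest families, or as an independent check.
#'
#' @param model A `ventsig_model`.
#' @param features Sample x gene matrix to attribute.
#' @param background Background matrix defining the reference distribution.
#' @param n_perm Number of sampled feature permutations.
#' @param seed Integer seed.
#' @return As [shap_values()] (with `margin` the score scale of the family).
#' @export
shap_permutation <- function(model, features, background, n_perm = 20, seed = 1L) {
  stopifnot(inherits(model, "ventsig_model"))
  set.seed(stage_seed(seed, "shap_perm"))
  x <- features[, model$feature_names, drop = FALSE]
  bg <- background[, model$feature_names, drop = FALSE]
  p <- ncol(x)
  phi <- matrix(0, nrow(x), p, dimnames = dimnames(x))
  base <- mean(predict_scores(model, bg))
  for (s in seq_len(nrow(x))) {
    for (r in seq_len(n_perm)) {
      ord <- sample.int(p)
      z <- bg
      prev <- mean(predict_scores(model, z))
      for (j in ord) {
        z[, j] <- x[s, j]
        cur <- mean(predict_scores(model, z))
        phi[s, j] <- phi[s, j] + (cur - prev) / n_perm
        prev <- cur
      }
    }
  }
  list(attributions = phi, base_value = base,
       margin = predict_scores(model, x))
}

#' Aggregate per-fold attributions into an importance table
#'
#' Per gene: the mean over folds of the mean absolute attribution over that
#' fold's samples, ranked descending (ties broken by lexicographic gene
#' id). Fold order does not matter.
#'
#' @param fold_attributions List of sample x gene attribution matrices,
#'   one per fold, over an identical gene universe.
#' @param feature_values Optional list of matching feature matrices, used
#'   to add a directionality sign per gene (see [shap_directionality()]).
#' @return An `importance_table` data.frame: `gene_id`, `mean_abs_attr`,
#'   `rank`, `direction`, plus one `fold<i>` column per fold.
#' @export
aggregate_importance <- function(fold_attributions, feature_values = NULL) {
  stopifnot(length(fold_attributions) >= 1)
  genes <- colnames(fold_attributions[[1]])
  for (a in fold_attributions)
    if (!identical(colnames(a), genes))
      stop("fold attributions disagree on the gene universe")
  per_fold <- vapply(fold_attributions, function(a) colMeans(abs(a)),
                     numeric(length(genes)))
  per_fold <- matrix(per_fold, nrow = length(genes),
                     dimnames = list(genes, sprintf("fold%d", seq_along(fold_attributions))))
  score <- rowMeans(per_fold)
  ord <- order(-score, genes)
  rank <- integer(length(genes)); rank[ord] <- seq_along(genes)
  direction <- rep(0, length(genes))
  if (!is.null(feature_values)) {
    allattr <- do.call(rbind, fold_attributions)
    allfeat <- do.call(rbind, lapply(feature_values, function(m) m[, genes, drop = FALSE]))
    direction <- shap_directionality(allattr, allfeat)$direction
  }
  out <- data.frame(gene_id = genes, mean_abs_attr = score, rank = rank,
                    direction = direction, row.names = NULL)
  out <- cbind(out, as.data.frame(per_fold, row.names = NULL))
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Top-k importance table
#'
#' @param table An `importance_table`.
#' @param k How many genes (default 20, the usual reporting depth).
#' @return The k rows with the largest mean absolute attribution, ties
#'   broken by lexicographic gene id.
#' @export
top_importance <- function(table, k = 20) {
  assert_count(k, "k", min = 1L)
  if (k > nrow(table)) abort_field("k", "exceeds the number of genes")
  ord <- order(table$rank)
  out <- table[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribution directionality per gene
#'
#' Pearson correlation between a gene's value and its attribution across
#' samples: positive means high expression pushes the prediction toward
#' the positive (ventilated) class. Zero-variance genes (in value or
#' attribution) get sign 0.
#'
#' @param attributions Sample x gene attribution matrix.
#' @param features Matching sample x gene value matrix.
#' @return data.frame with `gene_id`, `direction` (sign), `correlation`.
#' @export
shap_directionality <- function(attributions, features) {
  stopifnot(identical(dim(attributions), dim(features)))
  corr <- vapply(seq_len(ncol(features)), function(j) {
    a <- attributions[, j]; v <- features[, j]
    if (stats::sd(a) == 0 || stats::sd(v) == 0) return(0)
    stats::cor(v, a)
  }, numeric(1))
  data.frame(gene_id = colnames(features), direction = sign(corr),
             correlation = corr, row.names = NULL)
}

#' Genes used as split variables by tree ensembles
#'
#' The union over folds (and trees) of every gene appearing as a split
#' variable — the study's "marker genes used for the predictions", fed to
#' the enrichment step.
#'
#' @param models A `ventsig_model`, or a list of them (e.g. `cv$models`).
#' @return Sorted character vector of gene ids.
#' @export
extract_used_features <- function(models) {
  if (inherits(models, "ventsig_model")) models <- list(models)
  used <- lapply(models, function(m) {
    switch(m$family,
      gradient_boosting = {
        dt <- xgboost::xgb.model.dt.tree(model = m$fit)
        setdiff(unique(dt$Feature), "Leaf")
      },
      random_forest = {
        unique(unlist(lapply(seq_len(m$fit$num.trees), function(t) {
          ti <- ranger::treeInfo(m$fit, t)
          ti$splitvarName[!is.na(ti$splitvarName)]
        })))
      },
      stop("extract_used_features supports tree-based families only"))
  })
  sort(unique(unlist(used)))
}

#' Out-of-fold attribution across a cross-validation run
#'
#' Attributes each fold's fitted model on that fold's held-out samples, so
#' the aggregated importance is not optimistically biased by training data.
#'
#' @param cv A `cv_result` for the gradient-boosting family.
#' @param features The sample x gene matrix the CV was run on.
#' @return List with `fold_attributions`, `fold_features`, and `table`
#'   (the aggregated `importance_table`).
#' @export
cv_importance <- function(cv, features) {
  stopifnot(inherits(cv, "cv_result"))
  k <- max(cv$folds)
  fa <- vector("list", k); fv <- vector("list", k)
  for (f in seq_len(k)) {
    idx <- cv$folds == f
    sv <- shap_values(cv$models[[f]], features[idx, , drop = FALSE])
    fa[[f]] <- sv$attributions
    fv[[f]] <- features[idx, , drop = FALSE]
  }
  list(fold_attributions = fa, fold_features = fv,
       table = aggregate_importance(fa, fv))
}

#' Write an importance table as TSV
#' @param table An `importance_table`.
#' @param path Output path.
#' @export
write_importance_tsv <- function(table, path) {
  con <- file(path, "w")
  writeLines("# attribution sign convention: positive pushes toward the ventilated class (DTHHRDY==0)", con)
  close(con)
  data.table::fwrite(as.data.frame(table), path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
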