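#' Model family specification
#'
#' Hyperparameters follow the study defaults: 100 estimators of maximum
#' depth 3 for both tree families, learning rate 0.1 for gradient boosting;
#' the neural net is one hidden layer of 100 rectified-linear units with a
#' sigmoid output, binary cross-entropy loss and Adam updates. Random
#' forests have no learning rate; if one is supplied for that family it is
#' ignored with a message, matching the score-emitting (regression-mode)
#' forest used in the study.
#'
#' @param family `"gradient_boosting"`, `"random_forest"` or `"neural_net"`
#'   (aliases `"gbt"`, `"rf"`, `"ann"`).
#' @param n_estimators Trees per ensemble.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Boosting shrinkage (gradient boosting only).
#' @param epochs,batch_size Neural-net training schedule.
#' @param seed Integer seed for the fit.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("gradient_boosting", "random_forest", "neural_net",
                                  "gbt", "rf", "ann"),
                       n_estimators = 100, max_depth = 3, learning_rate = 0.1,
                       epochs = 30, batch_size = 16, seed = 1L) {
  family <- match.arg(family)
  family <- c(gbt = "gradient_boosting", rf = "random_forest",
              ann = "neural_net")[family] %||% family
  if (is.na(family)) family <- match.arg(family)
  assert_count(n_estimators, "n_estimators", min = 1L)
  assert_count(max_depth, "max_depth", min = 1L)
  assert_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) abort_field("learning_rate", "must be > 0")
  assert_count(epochs, "epochs", min = 1L)
  assert_count(batch_size, "batch_size", min = 1L)
  assert_count(seed, "seed")
  if (family == "random_forest" && !missing(learning_rate))
    message("random_forest has no learning rate; ignoring it")
  structure(list(family = family, n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth), learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)), class = "model_spec")
}

#' Stratified k-fold assignment without shuffling
#'
#' Folds preserve the class proportions to within one sample. The
#' assignment is deterministic in the input order: within each class,
#' samples are split in order into k near-equal contiguous blocks, block f
#' going to fold f.
#'
#' @param labels Binary (0/1) label vector.
#' @param k Number of folds (default 10).
#' @return Integer fold assignment (1..k), one entry per sample.
#' @export
make_stratified_folds <- function(labels, k = 10) {
  assert_count(k, "k", min = 2L)
  stopifnot(all(labels %in% c(0, 1)))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf("class %s has %d samples; need at least k = %d",
                   cl, length(idx), k))
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  fold
}

#' Classification metric battery
#'
#' AUC is the fraction of concordant positive-negative score pairs, ties
#' counting one half (computed by the exactly equivalent Mann-Whitney rank
#' formula). Accuracy, precision, recall and F1 come from the confusion
#' table at `threshold`, with the ventilated class as positive. Precision
#' (and F1) are defined as 0 when no positives are predicted.
#'
#' @param y_true Binary 0/1 labels (1 = ventilated).
#' @param scores Predicted scores/probabilities for the positive class.
#' @param threshold Score cut for the confusion table (default 0.5).
#' @return A `metric_set` named list: `auc`, `accuracy`, `f1`, `recall`,
#'   `precision`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0, 1)))
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)                       # average ranks handle ties as 1/2
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y_true == 1); fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1); tn <- sum(pred == 0 & y_true == 0)
  accuracy <- (tp + tn) / length(y_true)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(auc = auc, accuracy = accuracy, f1 = f1,
                 recall = recall, precision = precision), class = "metric_set")
}

# --- model family backends ------------------------------------------------

fit_family <- function(spec, x, y) {
  switch(spec$family,
    gradient_boosting = {
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = spec$max_depth, eta = spec$learning_rate,
                      nthread = 1, seed = spec$seed),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = spec$n_estimators, verbose = 0)
      structure(list(family = spec$family, fit = bst,
                     feature_names = colnames(x), spec = spec),
                class = "ventsig_model")
    },
    random_forest = {
      rf <- ranger::ranger(y = y, x = as.data.frame(x),
                           num.trees = spec$n_estimators,
                           max.depth = spec$max_depth,
                           seed = spec$seed, num.threads = 1,
                           respect.unordered.factors = "order")
      structure(list(family = spec$family, fit = rf,
                     feature_names = colnames(x), spec = spec),
                class = "ventsig_model")
    },
    neural_net = {
      nn <- mlp_fit(x, y, hidden = 100, epochs = spec$epochs,
                    batch_size = spec$batch_size, seed = spec$seed)
      structure(list(family = spec$family, fit = nn,
                     feature_names = colnames(x), spec = spec),
                class = "ventsig_model")
    },
    stop("unknown model family"))
}

#' Positive-class scores from a fitted model
#'
#' @param model A `ventsig_model` handle from [cross_validate()].
#' @param x Sample x gene feature matrix (columns matching the fit).
#' @return Numeric score per sample; probabilities for gradient boosting
#'   and the neural net, regression-on-0/1 output for the random forest.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "ventsig_model"))
  x <- x[, model$feature_names, drop = FALSE]
  switch(model$family,
    gradient_boosting = stats::predict(model$fit,
                                       xgboost::xgb.DMatrix(x, nthread = 1)),
    random_forest = stats::predict(model$fit, as.data.frame(x),
                                   num.threads = 1)$predictions,
    neural_net = mlp_predict(model$fit, x))
}

#' Stratified cross-validated classification
#'
#' For each fold: fit on the other k-1 folds, score the held-out fold,
#' record the metric battery. Aggregates are the arithmetic mean and SD of
#' the per-fold metrics. Fold assignment is deterministic
#' ([make_stratified_folds()]); pass the same `folds` vector to compare
#' model families on identical splits.
#'
#' @param features Sample x gene numeric matrix (stage-2 residuals,
#'   transposed).
#' @param labels Binary 0/1 labels (1 = ventilated).
#' @param spec A [model_spec()].
#' @param k Number of folds (default 10); ignored when `folds` is given.
#' @param folds Optional precomputed fold assignment.
#' @return A `cv_result` list: `fold_metrics` (data.frame, one row per
#'   fold), `mean`, `sd` (named metric vectors), `folds`, `models` (per-fold
#'   `ventsig_model` handles), `scores` (out-of-fold scores per sample),
#'   `positive_class`.
#' @export
cross_validate <- function(features, labels, spec, k = 10, folds = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            inherits(spec, "model_spec"))
  if (is.null(folds)) folds <- make_stratified_folds(labels, k)
  k <- max(folds)
  fold_metrics <- vector("list", k)
  models <- vector("list", k)
  scores <- rep(NA_real_, length(labels))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- tryCatch(
      fit_family(spec, features[!test, , drop = FALSE], labels[!test]),
      error = function(e) stop(sprintf("fold %d failed: %s", f, conditionMessage(e))))
    sc <- predict_scores(fit, features[test, , drop = FALSE])
    fold_metrics[[f]] <- as.data.frame(unclass(compute_metrics(labels[test], sc)))
    models[[f]] <- fit
    scores[test] <- sc
  }
  fm <- do.call(rbind, fold_metrics)
  fm <- cbind(fold = seq_len(k), fm)
  structure(list(
    fold_metrics = fm,
    mean = vapply(fm[-1], mean, numeric(1)),
    sd = vapply(fm[-1], stats::sd, numeric(1)),
    folds = folds, models = models, scores = scores,
    family = spec$family,
    positive_class = "ventilated (DTHHRDY==0)"), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds (positive class: %s)\n",
              x$family, max(x$folds), x$positive_class))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}
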