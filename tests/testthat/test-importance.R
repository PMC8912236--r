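# Small fitted boosters for attribution tests.
toy_model <- function(n = 60, p = 6, nrounds = 8, depth = 2, seed = 4,
                      signal = c(1, -0.8)) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", seq_len(p))))
  y <- as.numeric(x[, 1] * signal[1] + x[, 2] * signal[2] + rnorm(n, 0, 0.3) > 0)
  spec <- model_spec("gbt", n_estimators = nrounds, max_depth = depth, seed = seed)
  list(model = ventsig:::fit_family(spec, x, y), x = x, y = y)
}

test_that("tree attributions are additive to the model margin", {
  tm <- toy_model(n = 80, p = 8, nrounds = 20, depth = 3)
  sv <- shap_values(tm$model, tm$x)
  expect_lt(max(abs(sv$base_value + rowSums(sv$attributions) - sv$margin)), 1e-4)
})

test_that("tree attributions equal the exhaustive-subset Shapley oracle", {
  for (seed in c(4, 9)) {
    tm <- toy_model(n = 50, p = 5, nrounds = 6, depth = 2, seed = seed)
    sv <- shap_values(tm$model, tm$x[1:8, , drop = FALSE])
    trees <- ventsig:::extract_gbt_trees(tm$model)
    x32 <- ventsig:::round_float32(tm$x)   # the precision the model routes at
    for (s in 1:8) {
      phi <- oracle_shapley(trees, x32[s, ], colnames(tm$x))
      expect_equal(unname(sv$attributions[s, ]), unname(phi), tolerance = 1e-10)
    }
  }
})

test_that("constant and unused features get zero attribution", {
  set.seed(2)
  x <- cbind(g1 = rnorm(60), g2 = rnorm(60), const = rep(1, 60))
  y <- as.numeric(x[, "g1"] > 0)
  model <- ventsig:::fit_family(model_spec("gbt", n_estimators = 10, seed = 2), x, y)
  sv <- shap_values(model, x)
  expect_true(all(sv$attributions[, "const"] == 0))
  used <- extract_used_features(model)
  expect_false("const" %in% used)
  expect_true(all(colnames(x)[colSums(sv$attributions != 0) > 0] %in% used))
})

test_that("a single stump's attribution is output minus base, on its one feature", {
  set.seed(3)
  x <- cbind(g1 = c(rep(0, 30), rep(1, 30)), g2 = rnorm(60))
  y <- x[, "g1"]
  model <- ventsig:::fit_family(model_spec("gbt", n_estimators = 1, max_depth = 1, seed = 3), x, y)
  sv <- shap_values(model, x)
  expect_true(all(sv$attributions[, "g2"] == 0))
  # margin comes back through xgboost's float32 accumulation
  expect_equal(sv$attributions[, "g1"], sv$margin - sv$base_value, tolerance = 1e-6)
})

test_that("aggregation averages fold mean-absolute attributions and is fold-order invariant", {
  a1 <- matrix(c(0, 0, 0, 0), 2, 2, dimnames = list(NULL, c("gA", "gB")))
  a2 <- matrix(c(2, 4, 1, 1), 2, 2, dimnames = list(NULL, c("gA", "gB")))
  t12 <- aggregate_importance(list(a1, a2))
  expect_equal(t12$mean_abs_attr[t12$gene_id == "gA"], 1.5)  # (0 + 3)/2
  expect_equal(t12$mean_abs_attr[t12$gene_id == "gB"], 0.5)
  t21 <- aggregate_importance(list(a2, a1))
  expect_equal(t12$mean_abs_attr, t21$mean_abs_attr)
  expect_identical(t12$rank, t21$rank)
  same <- aggregate_importance(list(a2, a2))
  expect_equal(same$mean_abs_attr, colMeans(abs(a2)), ignore_attr = TRUE)
  bad <- matrix(0, 2, 2, dimnames = list(NULL, c("gA", "gX")))
  expect_error(aggregate_importance(list(a1, bad)), "gene universe")
})

test_that("top-k selection respects ranks and the lexicographic tie rule", {
  a <- matrix(c(1, 1, 2, 2, 3, 3), 2, 3, dimnames = list(NULL, c("gC", "gB", "gA")))
  tab <- aggregate_importance(list(a))
  full <- top_importance(tab, 3)
  expect_identical(full$gene_id, c("gA", "gB", "gC"))
  expect_identical(top_importance(tab, 1)$gene_id, "gA")
  # tie: gB and gC share a score; smaller id first
  tied <- matrix(c(5, 5, 5, 5, 9, 9), 2, 3, dimnames = list(NULL, c("gC", "gB", "gA")))
  ttab <- aggregate_importance(list(tied))
  expect_identical(top_importance(ttab, 3)$gene_id, c("gA", "gB", "gC"))
  expect_error(top_importance(ttab, 4), "k")
})

test_that("directionality recovers the sign of injected effects", {
  tm <- toy_model(n = 150, p = 6, nrounds = 30, depth = 3, seed = 21,
                  signal = c(1.5, -1.5))
  sv <- shap_values(tm$model, tm$x)
  dir <- shap_directionality(sv$attributions, tm$x)
  expect_identical(dir$direction[dir$gene_id == "g1"], 1)
  expect_identical(dir$direction[dir$gene_id == "g2"], -1)
  # zero-attribution gene reports sign 0
  zeroed <- sv$attributions; zeroed[, "g6"] <- 0
  dir0 <- shap_directionality(zeroed, tm$x)
  expect_identical(dir0$direction[dir0$gene_id == "g6"], 0)
})

test_that("used-feature extraction covers both tree families and bounds hold", {
  tm <- toy_model(n = 80, p = 10, nrounds = 25, depth = 3, seed = 31)
  used <- extract_used_features(tm$model)
  expect_true(all(c("g1", "g2") %in% used))
  # structural bound: at most 7 internal nodes per depth-3 tree
  expect_lte(length(used), 7 * 25)
  set.seed(31)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- as.numeric(x[, 1] > 0)
  rf <- ventsig:::fit_family(model_spec("rf", n_estimators = 20, seed = 1), x, y)
  used_rf <- extract_used_features(rf)
  expect_true("g1" %in% used_rf)
  ann <- ventsig:::fit_family(model_spec("ann", epochs = 2, seed = 1), x, y)
  expect_error(extract_used_features(ann), "tree-based")
  expect_error(shap_values(ann, x), "permutation")
})

test_that("permutation fallback is additive in expectation and agrees on a stump", {
  set.seed(5)
  x <- cbind(g1 = c(rep(0, 20), rep(1, 20)), g2 = rnorm(40))
  y <- x[, "g1"]
  model <- ventsig:::fit_family(model_spec("gbt", n_estimators = 1, max_depth = 1, seed = 5), x, y)
  sp <- shap_permutation(model, x[c(1, 40), , drop = FALSE], x, n_perm = 10, seed = 5)
  # with a single effective feature the permutation estimate is exact:
  # prob-scale output minus prob-scale base
  probs <- predict_scores(model, x[c(1, 40), , drop = FALSE])
  expect_equal(unname(sp$attributions[, "g1"]), unname(probs - sp$base_value),
               tolerance = 1e-6)
  expect_lt(max(abs(sp$attributions[, "g2"])), 1e-6)
})

test_that("out-of-fold importance places injected markers on top", {
  # noisy enough that no single marker separates, so the ensemble must
  # spread its splits over many markers
  sim <- tiny_cohort(n = 120, genes = 150, markers = 25, effect = 1, seed = 61,
                     noise_sd = 1.2)
  feats <- t(log2(unclass(sim$matrix)))
  labs <- unname(mv_labels(sim$covariates))
  cv <- cross_validate(feats, labs, model_spec("gbt", n_estimators = 40, seed = 6), k = 4)
  imp <- cv_importance(cv, feats)
  top <- top_importance(imp$table, 20)
  hits <- sum(top$gene_id %in% names(sim$truth$mv_markers))
  # enrichment of markers in the top 20 against the hypergeometric null
  p <- hypergeometric_p(hits, 20, 25, 150)
  expect_lt(p, 0.01)
  # additivity holds on every emitted fold matrix
  for (f in 1:4) {
    idx <- cv$folds == f
    sv <- shap_values(cv$models[[f]], feats[idx, , drop = FALSE])
    expect_lt(max(abs(sv$base_value + rowSums(sv$attributions) - sv$margin)), 1e-4)
  }
})
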