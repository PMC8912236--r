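#' Pipeline run configuration
#'
#' A single object driving the end-to-end run: simulate-or-load, preprocess,
#' adjust, cross-validate every requested model family on the same folds,
#' attribute, enrich, and write a report. Every source of randomness derives
#' from `seed`.
#'
#' @param cohort A [cohort_config()] for synthetic input, or `NULL` when
#'   loading from files.
#' @param matrix_path,covariates_path TSV inputs (used when `cohort` is NULL).
#' @param gene_sets_path GMT path; for synthetic runs `NULL` means generate
#'   decoy sets around the injected truth.
#' @param models Families to run, subset of `c("gbt", "rf", "ann")`.
#' @param k Cross-validation folds.
#' @param min_tpm,min_fraction,pseudocount,contamination,variation_fraction
#'   Preprocessing knobs (see [preprocess_expression()]).
#' @param adjustment `"two_step"` (default) or `"joint"` (the rejected
#'   comparator, kept for diagnostics).
#' @param top_k Reporting depth of the importance table.
#' @param alpha Enrichment significance level.
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory for the run artifacts.
#' @return A validated `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), matrix_path = NULL,
                       covariates_path = NULL, gene_sets_path = NULL,
                       models = c("gbt", "rf", "ann"), k = 10,
                       min_tpm = 0.1, min_fraction = 0.8, pseudocount = 1,
                       contamination = 0.01, variation_fraction = 0.01,
                       adjustment = c("two_step", "joint"),
                       top_k = 20, alpha = 0.05, seed = 1L,
                       out_dir = tempfile("ventsig_run_")) {
  adjustment <- match.arg(adjustment)
  if (is.null(cohort)) {
    for (p in c(matrix_path, covariates_path))
      if (!file.exists(p)) abort_field("matrix_path", sprintf("input '%s' does not exist", p))
  } else stopifnot(inherits(cohort, "cohort_config"))
  bad <- setdiff(models, c("gbt", "rf", "ann"))
  if (length(bad)) abort_field("models", paste("unknown family:", bad[1]))
  assert_count(k, "k", min = 2L)
  assert_count(seed, "seed")
  structure(list(cohort = cohort, matrix_path = matrix_path,
                 covariates_path = covariates_path,
                 gene_sets_path = gene_sets_path, models = models,
                 k = as.integer(k), min_tpm = min_tpm,
                 min_fraction = min_fraction, pseudocount = pseudocount,
                 contamination = contamination,
                 variation_fraction = variation_fraction,
                 adjustment = adjustment, top_k = as.integer(top_k),
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

pipeline_stage <- function(report, stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages: simulate-or-load, preprocess, two-step (or joint) adjustment,
#' stratified k-fold cross-validation of every requested family on the
#' *same* folds, out-of-fold Shapley importance for the boosting family,
#' used-feature extraction, over-representation analysis, report writing.
#'
#' All tabular outputs are TSV, summaries JSON; the manifest records the
#' config hash, seed, per-stage gene/sample counts and the fold assignment.
#' Re-running with the same config and seed reproduces the tree-family
#' outputs byte for byte.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `metrics` (per-model aggregate table),
#'   `fold_metrics`, `importance` (top-k table), `enrichment`, `used_features`,
#'   `manifest`, `paths` of all written artifacts, plus the fitted `cv`
#'   objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("ventsig")),
                   seed = config$seed,
                   positive_class = "ventilated (DTHHRDY==0)",
                   adjustment = config$adjustment,
                   stage_counts = list())
  paths <- list()

  # --- input ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$cohort)) {
    sim <- pipeline_stage(manifest, "simulate", generate_cohort(config$cohort))
    mat <- sim$matrix; cov <- sim$covariates; truth <- sim$truth
    paths$matrix <- write_expression_tsv(mat, out("expression_tpm.tsv"))
    paths$covariates <- write_covariates_tsv(cov, out("covariates.tsv"))
    paths$truth <- write_ground_truth(truth, out("ground_truth.json"))
  } else {
    mat <- pipeline_stage(manifest, "load", read_expression_tsv(config$matrix_path, "TPM"))
    cov <- read_covariates_tsv(config$covariates_path)
  }
  cov <- cov[match(colnames(mat), cov$sample_id), ]
  class(cov) <- c("sample_covariates", "data.frame")
  manifest$stage_counts$input <- list(genes = nrow(mat), samples = ncol(mat))

  # --- preprocess ----------------------------------------------------------
  prep <- pipeline_stage(manifest, "preprocess",
    preprocess_expression(mat, config$min_tpm, config$min_fraction,
                          config$pseudocount, config$contamination,
                          config$variation_fraction, seed = config$seed))
  m <- prep$matrix
  cov <- cov[match(colnames(m), cov$sample_id), ]
  class(cov) <- c("sample_covariates", "data.frame")
  manifest$stage_counts$preprocess <- prep$log
  jsonlite::write_json(prep$log, out("preprocess_log.json"), auto_unbox = TRUE)
  paths$preprocess_log <- out("preprocess_log.json")

  # --- adjust --------------------------------------------------------------
  if (config$adjustment == "two_step") {
    adj <- pipeline_stage(manifest, "adjust", adjust_confounders(m, cov))
    resid <- adj$residuals
    paths$ischemic_model <- write_model_tsv(adj$ischemic, out("ischemic_model.tsv"))
  } else {
    adj <- pipeline_stage(manifest, "adjust", joint_adjust_diagnostic(m, cov))
    resid <- adj$residuals
    data.table::fwrite(adj$skew_report, out("skew_report.tsv"), sep = "\t")
    paths$skew_report <- out("skew_report.tsv")
    jsonlite::write_json(list(
      n_genes = nrow(adj$skew_report),
      mean_abs_joint_ischemic_coef = mean(abs(adj$skew_report$joint_ischemic_coef)),
      mean_abs_twostep_ischem_avg = mean(abs(adj$skew_report$twostep_ischem_avg)),
      mean_abs_label_diff_joint = mean(abs(adj$skew_report$label_diff_joint)),
      mean_abs_label_diff_twostep = mean(abs(adj$skew_report$label_diff_twostep))),
      out("skew_summary.json"), auto_unbox = TRUE, digits = NA)
    paths$skew_summary <- out("skew_summary.json")
  }
  paths$residuals <- write_expression_tsv(resid, out("residuals.tsv"))

  # --- classify ------------------------------------------------------------
  features <- t(unclass(resid))
  labels <- mv_labels(cov)
  folds <- make_stratified_folds(labels, config$k)
  manifest$folds <- unname(folds)
  cvs <- list()
  for (fam in config$models) {
    spec <- model_spec(fam, seed = config$seed)
    cvs[[fam]] <- pipeline_stage(manifest, paste0("train_", fam),
                                 cross_validate(features, labels, spec,
                                                folds = folds))
    fm <- cvs[[fam]]$fold_metrics
    data.table::fwrite(fm, out(sprintf("fold_metrics_%s.tsv", fam)), sep = "\t")
    paths[[paste0("fold_metrics_", fam)]] <- out(sprintf("fold_metrics_%s.tsv", fam))
  }
  metrics <- do.call(rbind, lapply(names(cvs), function(fam) {
    data.frame(model = fam, metric = names(cvs[[fam]]$mean),
               mean = unname(cvs[[fam]]$mean), sd = unname(cvs[[fam]]$sd),
               row.names = NULL)
  }))
  data.table::fwrite(metrics, out("metrics_by_model.tsv"), sep = "\t")
  paths$metrics <- out("metrics_by_model.tsv")
  auc_table <- data.frame(model = names(cvs),
                          auc = vapply(cvs, function(cv) cv$mean[["auc"]], numeric(1)),
                          row.names = NULL)
  data.table::fwrite(auc_table, out("auc_by_model.tsv"), sep = "\t")
  paths$auc <- out("auc_by_model.tsv")

  # --- importance (boosting family) ---------------------------------------
  imp_top <- NULL; used <- character(0)
  if ("gbt" %in% names(cvs)) {
    imp <- pipeline_stage(manifest, "explain", cv_importance(cvs$gbt, features))
    imp_top <- top_importance(imp$table, min(config$top_k, nrow(imp$table)))
    paths$importance <- write_importance_tsv(imp$table, out("importance.tsv"))
    paths$importance_top <- write_importance_tsv(imp_top, out("importance_top.tsv"))
    tree_models <- unlist(lapply(cvs[intersect(names(cvs), c("gbt", "rf"))],
                                 function(cv) cv$models), recursive = FALSE)
    used <- extract_used_features(tree_models)
    writeLines(used, out("used_features.txt"))
    paths$used_features <- out("used_features.txt")
  }

  # --- enrichment ----------------------------------------------------------
  enr <- NULL
  collection <- NULL
  if (!is.null(config$gene_sets_path)) {
    collection <- read_gmt(config$gene_sets_path, universe = rownames(resid))
  } else if (!is.null(truth)) {
    collection <- generate_gene_sets(truth, universe = rownames(resid),
                                     seed = config$seed)
    paths$gene_sets <- write_gmt(collection, out("gene_sets.gmt"))
  }
  if (!is.null(collection) && length(used)) {
    enr <- pipeline_stage(manifest, "enrich",
                          enrich(used, collection, config$alpha))
    data.table::fwrite(as.data.frame(enr), out("enrichment.tsv"), sep = "\t")
    paths$enrichment <- out("enrichment.tsv")
  }

  # --- manifest ------------------------------------------------------------
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest$config_hash <- sum(utf8ToInt(paste(deparse(cfg_for_hash), collapse = "")))
  manifest$models <- config$models
  manifest$files <- unname(unlist(lapply(paths, basename)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)
  paths$manifest <- out("manifest.json")

  structure(list(metrics = metrics, auc = auc_table,
                 fold_metrics = lapply(cvs, `[[`, "fold_metrics"),
                 importance = imp_top, enrichment = enr,
                 used_features = used, manifest = manifest,
                 paths = paths, cv = cvs, truth = truth,
                 residuals = resid, covariates = cov),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  models: %s | samples: %d | genes: %d\n",
              paste(names(x$cv), collapse = ", "),
              ncol(x$residuals), nrow(x$residuals)))
  agg <- stats::reshape(x$metrics[c("model", "metric", "mean")],
                        idvar = "model", timevar = "metric", direction = "wide")
  names(agg) <- sub("^mean\\.", "", names(agg))
  print(agg, row.names = FALSE, digits = 3)
  invisible(x)
}
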