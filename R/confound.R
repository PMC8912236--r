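# Two-step confounder residualization.
#
# Ischemic time and ventilation status are strongly correlated (ventilated
# donors die in hospital, so their samples are collected sooner). Putting
# ischemic time into one joint regression therefore lets it absorb part of
# the ventilation signal (omitted-variable skew). The two-step scheme fits
# batch/age/sex first, then estimates the ischemic-time coefficient
# *within each death-type group* — where the label is constant and cannot
# confound the slope — averages the two group slopes per gene, and only
# subtracts the correction when that average is negative (expression decay
# with time since death; a positive average is treated as no ischemic
# response).

#' Build the stage-1 design from covariates
#'
#' Encodes batch as one-hot with the first level as reference, sex as 0/1
#' and the age bracket as its ordinal index, plus an intercept. Ischemic
#' time and death type are deliberately excluded from stage 1: time is
#' handled group-wise in stage 2, and the label must never be regressed out.
#'
#' The returned encoder remembers the batch levels, so applying it to
#' covariates with an unseen batch fails with the offending sample named.
#'
#' @param cov A [sample_covariates()] table.
#' @return A `covariate_design` list: `design` (n x p numeric matrix),
#'   `encoding` (column name -> construction), `batch_levels`.
#' @export
encode_covariates <- function(cov) {
  stopifnot(inherits(cov, "sample_covariates"))
  levels <- sort(unique(cov$batch))
  enc <- structure(list(batch_levels = levels), class = "covariate_encoder")
  design <- apply_encoder(enc, cov)
  encoding <- list("(Intercept)" = "constant 1")
  for (lv in levels[-1])
    encoding[[paste0("batch", lv)]] <- sprintf("1[batch == %s]", lv)
  encoding$age <- "ordinal bracket index 0-5"
  encoding$sex <- "0/1 as recorded"
  structure(list(design = design, encoder = enc, encoding = encoding),
            class = "covariate_design")
}

apply_encoder <- function(enc, cov) {
  unseen <- !(cov$batch %in% enc$batch_levels)
  if (any(unseen))
    stop(sprintf("unseen batch level '%s' for sample '%s'",
                 cov$batch[unseen][1], cov$sample_id[unseen][1]))
  levels <- enc$batch_levels
  n <- nrow(cov)
  cols <- list("(Intercept)" = rep(1, n))
  for (lv in levels[-1]) cols[[paste0("batch", lv)]] <- as.numeric(cov$batch == lv)
  cols$age <- as.numeric(cov$age_bracket)
  cols$sex <- as.numeric(cov$sex)
  design <- do.call(cbind, cols)
  rownames(design) <- cov$sample_id
  design
}

# Drop collinear columns by QR rank detection. Column priority is
# deterministic: intercept, then age/sex, then batch dummies, so batch
# columns are the first to go when redundant.
drop_collinear <- function(design) {
  batch <- grep("^batch", colnames(design))
  pri <- c(which(colnames(design) == "(Intercept)"),
           setdiff(seq_len(ncol(design)),
                   c(which(colnames(design) == "(Intercept)"), batch)),
           batch)
  x <- design[, pri, drop = FALSE]
  qrx <- qr(x)
  keep_pri <- qrx$pivot[seq_len(qrx$rank)]
  kept <- sort(pri[sort(keep_pri)])
  dropped <- setdiff(colnames(design), colnames(design)[kept])
  if (length(dropped))
    warning(sprintf("dropped collinear design column(s): %s",
                    paste(dropped, collapse = ", ")))
  design[, kept, drop = FALSE]
}

#' Fit the stage-1 per-gene regression (batch + age + sex)
#'
#' Ordinary least squares of every gene's log2 expression on the encoded
#' confounder design. Collinear columns are dropped (with a warning) by QR
#' rank detection before fitting.
#'
#' @param matrix LOG2-scale [expression_matrix()].
#' @param design A `covariate_design` from [encode_covariates()] (or a bare
#'   numeric design matrix with an intercept column).
#' @return A `stage1_model`: `coefficients` (gene x column matrix),
#'   `design` (the pruned design actually used).
#' @export
fit_stage1 <- function(matrix, design) {
  x <- if (inherits(design, "covariate_design")) design$design else design
  stopifnot(is.matrix(x), nrow(x) == ncol(matrix))
  x <- drop_collinear(x)
  if (ncol(x) >= nrow(x))
    stop("stage-1 design has as many columns as samples; cannot fit OLS")
  fit <- stats::lm.fit(x, t(unclass(matrix)))
  coefs <- t(fit$coefficients)           # gene x column
  if (anyNA(coefs)) stop("stage-1 fit produced NA coefficients")
  structure(list(coefficients = coefs, design = x), class = "stage1_model")
}

#' Stage-1 residuals
#'
#' `residual0 = observed - design %*% coef` per gene and sample; residuals
#' are orthogonal to every retained design column on the training data, and
#' per-gene centered because the design includes an intercept.
#'
#' @param matrix LOG2-scale [expression_matrix()] the model was fitted on
#'   (or one aligned to the same samples).
#' @param model A `stage1_model`.
#' @return A `residual_matrix` (an [expression_matrix()] subclass with a
#'   `stage` attribute set to `"stage1"`).
#' @export
residualize_stage1 <- function(matrix, model) {
  stopifnot(inherits(model, "stage1_model"))
  if (!identical(rownames(model$design), colnames(matrix)))
    stop("residualize_stage1: samples do not match the fitted design")
  if (!identical(rownames(model$coefficients), rownames(matrix)))
    stop("residualize_stage1: genes do not match the fitted model")
  fitted <- model$coefficients %*% t(model$design)
  res <- unclass(matrix) - fitted
  structure(expression_matrix(res, scale = "LOG2"),
            stage = "stage1",
            class = c("residual_matrix", "expression_matrix", "matrix", "array"))
}

#' Group-wise ischemic-time model
#'
#' For every gene, a simple linear regression (with intercept) of the
#' stage-1 residual on ischemic time is fitted separately within the
#' ventilated and the non-ventilated group. The per-gene correction
#' coefficient is the unweighted average of the two group slopes, clipped
#' at zero from above: `ischem_clipped = min(0, ischem_avg)`. A positive
#' average means no further ischemic adjustment for that gene.
#'
#' @param resid Stage-1 `residual_matrix`.
#' @param cov Matching [sample_covariates()].
#' @return An `ischemic_model` data.frame with columns `gene_id`,
#'   `slope_vent`, `slope_nonvent`, `ischem_avg`, `ischem_clipped`.
#' @export
fit_groupwise_ischemic <- function(resid, cov) {
  stopifnot(identical(colnames(resid), cov$sample_id))
  vals <- unclass(resid)
  slope_in <- function(idx) {
    if (length(idx) < 3)
      stop("each death-type group needs at least 3 samples")
    t <- cov$ischemic_time[idx]
    tc <- t - mean(t)
    den <- sum(tc^2)
    if (den == 0) stop("a death-type group has constant ischemic time")
    r <- vals[, idx, drop = FALSE]
    as.numeric((r - rowMeans(r)) %*% tc) / den
  }
  sv <- slope_in(which(cov$death_type == 0L))
  sn <- slope_in(which(cov$death_type == 1L))
  avg <- (sv + sn) / 2
  structure(data.frame(gene_id = rownames(vals),
                       slope_vent = sv, slope_nonvent = sn,
                       ischem_avg = avg, ischem_clipped = pmin(0, avg),
                       row.names = NULL),
            class = c("ischemic_model", "data.frame"))
}

#' Stage-2 residuals: subtract the clipped ischemic correction
#'
#' `residual_ij = residual0_ij - ischem_clipped_i * time_j`. Genes whose
#' averaged slope is nonnegative pass through unchanged (their clipped
#' coefficient is zero).
#'
#' @param resid Stage-1 `residual_matrix`.
#' @param model An `ischemic_model` from [fit_groupwise_ischemic()].
#' @param cov Matching [sample_covariates()].
#' @return A stage-2 `residual_matrix`.
#' @export
residualize_stage2 <- function(resid, model, cov) {
  stopifnot(inherits(model, "ischemic_model"),
            identical(colnames(resid), cov$sample_id))
  if (!identical(model$gene_id, rownames(resid)))
    stop("residualize_stage2: genes do not match the ischemic model")
  out <- unclass(resid) - outer(model$ischem_clipped, cov$ischemic_time)
  structure(expression_matrix(out, scale = "LOG2"),
            stage = "stage2",
            class = c("residual_matrix", "expression_matrix", "matrix", "array"))
}

#' Full two-step adjustment
#'
#' Convenience wrapper: encode covariates, fit stage 1, residualize, fit the
#' group-wise ischemic model, residualize again.
#'
#' @param matrix LOG2-scale [expression_matrix()].
#' @param cov Matching [sample_covariates()].
#' @return List with `residuals` (stage-2 `residual_matrix`), `stage1`
#'   (`stage1_model`), `ischemic` (`ischemic_model`).
#' @export
adjust_confounders <- function(matrix, cov) {
  stopifnot(identical(colnames(matrix), cov$sample_id))
  design <- encode_covariates(cov)
  s1 <- fit_stage1(matrix, design)
  r1 <- residualize_stage1(matrix, s1)
  im <- fit_groupwise_ischemic(r1, cov)
  r2 <- residualize_stage2(r1, im, cov)
  list(residuals = r2, stage1 = s1, ischemic = im)
}

#' One-step joint adjustment and skew diagnostic
#'
#' The comparator the two-step scheme replaces: a single OLS on
#' batch + age + sex + ischemic time (death type omitted). Because ischemic
#' time is correlated with the label, the joint ischemic coefficient soaks
#' up ventilation signal for marker genes. The skew report puts the joint
#' coefficient, the two-step averaged group slope, and the residual
#' ventilated-vs-non-ventilated mean difference under each scheme side by
#' side, per gene.
#'
#' @param matrix LOG2-scale [expression_matrix()].
#' @param cov Matching [sample_covariates()].
#' @return List with `residuals` (joint-scheme `residual_matrix`, stage flag
#'   `"joint"`) and `skew_report` (data.frame: `gene_id`, `joint_ischemic_coef`,
#'   `twostep_ischem_avg`, `label_diff_joint`, `label_diff_twostep`).
#' @export
joint_adjust_diagnostic <- function(matrix, cov) {
  stopifnot(identical(colnames(matrix), cov$sample_id))
  design <- encode_covariates(cov)$design
  x <- drop_collinear(cbind(design, ischemic_time = cov$ischemic_time))
  if (!"ischemic_time" %in% colnames(x))
    stop("ischemic time column dropped as collinear; diagnostic undefined")
  fit <- stats::lm.fit(x, t(unclass(matrix)))
  coefs <- t(fit$coefficients)
  res_joint <- unclass(matrix) - coefs %*% t(x)
  joint <- structure(expression_matrix(res_joint, scale = "LOG2"),
                     stage = "joint",
                     class = c("residual_matrix", "expression_matrix", "matrix", "array"))
  two <- adjust_confounders(matrix, cov)
  vent <- cov$death_type == 0L
  diff_of <- function(m) rowMeans(unclass(m)[, vent, drop = FALSE]) -
    rowMeans(unclass(m)[, !vent, drop = FALSE])
  report <- data.frame(
    gene_id = rownames(matrix),
    joint_ischemic_coef = coefs[, "ischemic_time"],
    twostep_ischem_avg = two$ischemic$ischem_avg,
    label_diff_joint = diff_of(joint),
    label_diff_twostep = diff_of(two$residuals),
    row.names = NULL)
  list(residuals = joint, skew_report = report, twostep = two)
}

#' Write per-gene model tables
#'
#' TSV writers for `stage1_model` and `ischemic_model` (gene id + named
#' coefficients), matching the shared text dialect.
#'
#' @param model A `stage1_model` or `ischemic_model`.
#' @param path Output path.
#' @export
write_model_tsv <- function(model, path) {
  if (inherits(model, "stage1_model")) {
    dt <- data.table::data.table(gene_id = rownames(model$coefficients))
    dt <- cbind(dt, data.table::as.data.table(model$coefficients))
  } else if (inherits(model, "ischemic_model")) {
    dt <- data.table::as.data.table(model)
  } else stop("unsupported model type")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
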