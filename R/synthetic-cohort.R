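#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort with the statistical structure the analysis assumes:
#' a binary ventilation label, ischemic time negatively associated with
#' ventilation (ventilated donors die in hospital, so their samples are
#' collected sooner), batch/age/sex nuisance effects, a sparse set of true
#' MV marker genes, and genes with a genuine ischemic-time response.
#'
#' All effect sizes are in log2 units; expression is built additively on the
#' log2 scale and exponentiated to TPM. Defaults emulate the post-filter
#' gene universe of a GTEx-style tissue at desk scale.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param frac_ventilated Proportion of ventilated donors, in (0, 1).
#' @param n_mv_markers Number of true ventilation marker genes.
#' @param mv_effect_size log2-units shift added to ventilated samples for
#'   marker genes.
#' @param n_ischemic_genes Number of genes with an ischemic-time slope.
#' @param ischemic_slope log2-units per minute for ischemic genes
#'   (typically negative: expression decays with time since death).
#' @param batch_levels Number of experimental batches (>= 1).
#' @param batch_effect_sd SD of the per-(batch, gene) effect, log2 units.
#' @param age_effect SD of per-gene age slopes (per bracket index), log2 units.
#' @param sex_effect SD of per-gene sex shifts, log2 units.
#' @param ischemic_time_params List with `vent = c(mean, sd)` and
#'   `nonvent = c(mean, sd)` in minutes; times are drawn from normals
#'   truncated at zero (resample-until-valid). Ventilated mean must be
#'   below the non-ventilated mean.
#' @param noise_sd Residual Gaussian noise SD, log2 units.
#' @param baseline_mean_range Interval for per-gene baseline means (log2 TPM).
#' @param seed Integer seed; the same seed reproduces the cohort bit for bit.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 300, n_genes = 2000,
                          frac_ventilated = 0.4,
                          n_mv_markers = 50, mv_effect_size = 1.0,
                          n_ischemic_genes = 100, ischemic_slope = -0.002,
                          batch_levels = 3, batch_effect_sd = 0.3,
                          age_effect = 0.1, sex_effect = 0.2,
                          ischemic_time_params = list(vent = c(300, 100),
                                                      nonvent = c(900, 250)),
                          noise_sd = 0.5,
                          baseline_mean_range = c(4, 10),
                          seed = 1L) {
  assert_count(n_samples, "n_samples", min = 2L)
  assert_count(n_genes, "n_genes", min = 1L)
  assert_number(frac_ventilated, "frac_ventilated")
  if (frac_ventilated <= 0 || frac_ventilated >= 1)
    abort_field("frac_ventilated", "must lie strictly in (0, 1)")
  assert_count(n_mv_markers, "n_mv_markers")
  assert_number(mv_effect_size, "mv_effect_size")
  assert_count(n_ischemic_genes, "n_ischemic_genes")
  assert_number(ischemic_slope, "ischemic_slope")
  assert_count(batch_levels, "batch_levels", min = 1L)
  assert_number(batch_effect_sd, "batch_effect_sd", min = 0)
  assert_number(age_effect, "age_effect", min = 0)
  assert_number(sex_effect, "sex_effect", min = 0)
  assert_number(noise_sd, "noise_sd", min = 0)
  if (n_mv_markers + n_ischemic_genes > n_genes)
    abort_field("n_mv_markers", "n_mv_markers + n_ischemic_genes must be <= n_genes")
  for (grp in c("vent", "nonvent")) {
    p <- ischemic_time_params[[grp]]
    if (is.null(p) || length(p) != 2 || any(!is.finite(p)) || p[2] < 0)
      abort_field("ischemic_time_params", sprintf("`%s` must be c(mean, sd) with sd >= 0", grp))
  }
  if (ischemic_time_params$vent[1] >= ischemic_time_params$nonvent[1])
    abort_field("ischemic_time_params", "ventilated mean time must be below non-ventilated mean")
  if (length(baseline_mean_range) != 2 || diff(baseline_mean_range) < 0)
    abort_field("baseline_mean_range", "must be an increasing interval")
  assert_count(seed, "seed")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    frac_ventilated = frac_ventilated, n_mv_markers = as.integer(n_mv_markers),
    mv_effect_size = mv_effect_size, n_ischemic_genes = as.integer(n_ischemic_genes),
    ischemic_slope = ischemic_slope, batch_levels = as.integer(batch_levels),
    batch_effect_sd = batch_effect_sd, age_effect = age_effect,
    sex_effect = sex_effect, ischemic_time_params = ischemic_time_params,
    noise_sd = noise_sd, baseline_mean_range = as.numeric(baseline_mean_range),
    seed = as.integer(seed)), class = "cohort_config")
}

rtruncnorm0 <- function(n, mean, sd) {
  # resample-until-valid truncation at zero
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Generate a synthetic cohort
#'
#' Builds the log2-scale signal as
#' `baseline_i + batch + age + sex effects + slope_i * time_j (ischemic genes)
#'  + effect_i * 1[ventilated_j] (marker genes) + N(0, noise_sd)`,
#' then exponentiates to the TPM scale (`2^x`). Ischemic time is drawn per
#' death-type group from a zero-truncated normal with group-specific means,
#' which induces the negative association between ischemic time and
#' ventilation status that motivates the two-step adjustment.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `matrix` (TPM-scale [expression_matrix()]),
#'   `covariates` ([sample_covariates()]) and `truth` (a `ground_truth`
#'   list recording exactly which effects were injected where:
#'   `mv_markers` and `ischemic_genes` are named numeric vectors of injected
#'   effect / slope per gene id, `labels` the generated 0/1 ventilation
#'   labels).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples; p <- config$n_genes
  genes <- sprintf("G%04d", seq_len(p))
  samples <- sprintf("S%04d", seq_len(n))

  set.seed(stage_seed(config$seed, "design"))
  n_vent <- max(1L, min(n - 1L, round(config$frac_ventilated * n)))
  vent <- integer(n)
  vent[sample.int(n, n_vent)] <- 1L
  sex <- sample(0:1, n, replace = TRUE)
  age <- sample(0:5, n, replace = TRUE)
  batch <- sprintf("B%02d", sample.int(config$batch_levels, n, replace = TRUE))

  set.seed(stage_seed(config$seed, "times"))
  times <- numeric(n)
  tp <- config$ischemic_time_params
  times[vent == 1L] <- rtruncnorm0(sum(vent == 1L), tp$vent[1], tp$vent[2])
  times[vent == 0L] <- rtruncnorm0(sum(vent == 0L), tp$nonvent[1], tp$nonvent[2])

  set.seed(stage_seed(config$seed, "effects"))
  baseline <- stats::runif(p, config$baseline_mean_range[1], config$baseline_mean_range[2])
  special <- sample.int(p, config$n_mv_markers + config$n_ischemic_genes)
  marker_idx <- special[seq_len(config$n_mv_markers)]
  isch_idx <- special[config$n_mv_markers + seq_len(config$n_ischemic_genes)]
  beta_age <- stats::rnorm(p, 0, config$age_effect)
  beta_sex <- stats::rnorm(p, 0, config$sex_effect)
  batch_eff <- matrix(stats::rnorm(config$batch_levels * p, 0, config$batch_effect_sd),
                      nrow = config$batch_levels)   # batch x gene

  log2sig <- matrix(baseline, nrow = p, ncol = n)
  log2sig <- log2sig + outer(beta_age, age) + outer(beta_sex, sex)
  bi <- as.integer(sub("^B", "", batch))
  log2sig <- log2sig + t(batch_eff[bi, , drop = FALSE])
  if (length(isch_idx))
    log2sig[isch_idx, ] <- log2sig[isch_idx, ] +
      config$ischemic_slope * matrix(times, nrow = length(isch_idx), ncol = n, byrow = TRUE)
  if (length(marker_idx))
    log2sig[marker_idx, vent == 1L] <- log2sig[marker_idx, vent == 1L] + config$mv_effect_size

  set.seed(stage_seed(config$seed, "noise"))
  if (config$noise_sd > 0)
    log2sig <- log2sig + matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)

  tpm <- 2^log2sig
  dimnames(tpm) <- list(genes, samples)

  cov <- sample_covariates(data.frame(
    sample_id = samples,
    death_type = 1L - vent,       # DTHHRDY: 0 = ventilator
    ischemic_time = times, sex = sex, age_bracket = age, batch = batch))

  truth <- structure(list(
    mv_markers = stats::setNames(rep(config$mv_effect_size, length(marker_idx)),
                                 genes[marker_idx]),
    ischemic_genes = stats::setNames(rep(config$ischemic_slope, length(isch_idx)),
                                     genes[isch_idx]),
    labels = stats::setNames(vent, samples),
    config = config), class = "ground_truth")

  list(matrix = expression_matrix(tpm, scale = "TPM"),
       covariates = cov, truth = truth)
}

#' Perturb a few samples into outliers
#'
#' Adds `magnitude`-scaled Gaussian noise to every gene of the chosen
#' samples, producing fixtures for outlier-removal tests. Operates on
#' whichever scale the matrix carries.
#'
#' @param matrix An [expression_matrix()].
#' @param n_outliers How many samples to perturb; must be < n_samples.
#' @param magnitude Noise SD added, log2 units (TPM input is perturbed on
#'   the log2 scale and re-exponentiated, so it stays positive).
#' @param seed Integer seed.
#' @return List with `matrix` (perturbed) and `outlier_ids`.
#' @export
inject_outliers <- function(matrix, n_outliers, magnitude, seed = 1L) {
  assert_count(n_outliers, "n_outliers")
  assert_number(magnitude, "magnitude", min = 0)
  if (n_outliers >= ncol(matrix))
    abort_field("n_outliers", "must be smaller than the number of samples")
  if (n_outliers == 0 || magnitude == 0)
    return(list(matrix = matrix, outlier_ids = character(0)))
  set.seed(stage_seed(seed, "outliers"))
  idx <- sample.int(ncol(matrix), n_outliers)
  vals <- unclass(matrix)
  shift <- matrix(stats::rnorm(nrow(vals) * n_outliers, 0, magnitude),
                  nrow(vals), n_outliers)
  if (expr_scale(matrix) == "TPM") {
    vals[, idx] <- 2^(log2(vals[, idx] + 1) + shift)
  } else {
    vals[, idx] <- vals[, idx] + shift
  }
  list(matrix = expression_matrix(vals, scale = expr_scale(matrix)),
       outlier_ids = colnames(vals)[sort(idx)])
}

#' Generate gene-set fixtures around the injected truth
#'
#' Builds one "true" set holding a stated fraction of the MV marker genes
#' (padded with random genes up to `set_size`) plus `n_random_sets` sets
#' drawn uniformly from the universe — the construction a hypergeometric
#' over-representation test should separate.
#'
#' @param truth A `ground_truth` from [generate_cohort()].
#' @param universe Character vector of background gene ids.
#' @param n_random_sets Number of random decoy sets.
#' @param set_size Genes per set; must be <= length(universe).
#' @param true_fraction Fraction of the true set drawn from the markers.
#' @param seed Integer seed.
#' @return A `gene_set_collection` (see [read_gmt()]).
#' @export
generate_gene_sets <- function(truth, universe, n_random_sets = 20,
                               set_size = 50, true_fraction = 0.5, seed = 1L) {
  if (!length(universe)) abort_field("universe", "must be non-empty")
  assert_count(n_random_sets, "n_random_sets")
  assert_count(set_size, "set_size", min = 1L)
  if (set_size > length(universe))
    abort_field("set_size", "must be <= length(universe)")
  assert_number(true_fraction, "true_fraction", min = 0, max = 1)
  set.seed(stage_seed(seed, "gene_sets"))
  markers <- intersect(names(truth$mv_markers), universe)
  n_true <- min(length(markers), round(true_fraction * set_size), set_size)
  true_set <- c(if (n_true) sample(markers, n_true) else character(0),
                sample(setdiff(universe, markers), set_size - n_true))
  sets <- c(list(MV_TRUE_SET = sort(true_set)),
            stats::setNames(lapply(seq_len(n_random_sets), function(i)
              sort(sample(universe, set_size))),
              if (n_random_sets) sprintf("RANDOM_%03d", seq_len(n_random_sets))))
  gene_set_collection(sets, universe = universe)
}

#' Write ground truth to JSON
#' @param truth A `ground_truth`.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    mv_markers = as.list(truth$mv_markers),
    ischemic_genes = as.list(truth$ischemic_genes),
    labels = as.list(truth$labels),
    positive_class = "ventilated (DTHHRDY==0)"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
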