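#' Per-sample covariate table with GTEx attribute semantics
#'
#' Validates and normalizes a data.frame of donor covariates:
#' \describe{
#'   \item{sample_id}{unique sample identifier (GTEx `SAMPID`)}
#'   \item{death_type}{0 = on ventilator at death, 1 = not on ventilator
#'     (the two retained levels of the four-point Hardy scale, `DTHHRDY`;
#'     ill-donor codes 3-4 are excluded upstream)}
#'   \item{ischemic_time}{minutes between death and sample extraction
#'     (`SMTSISCH`), finite and nonnegative}
#'   \item{sex}{binary category, coded 0/1}
#'   \item{age_bracket}{ordinal decade bracket, integer 0-5 for 20s..70s}
#'   \item{batch}{experimental batch, a categorical label}
#' }
#'
#' @param df data.frame with the columns above (extra columns are dropped).
#' @return A validated `sample_covariates` data.frame.
#' @export
sample_covariates <- function(df) {
  need <- c("sample_id", "death_type", "ischemic_time", "sex", "age_bracket", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_field(miss[1], "missing covariate column")
  out <- df[need]
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) abort_field("sample_id", "must be unique")
  if (!all(out$death_type %in% c(0, 1)))
    abort_field("death_type", "must be 0 (ventilator) or 1 (non-ventilator)")
  if (anyNA(out$ischemic_time) || any(!is.finite(out$ischemic_time)) ||
      any(out$ischemic_time < 0))
    abort_field("ischemic_time", "must be finite minutes >= 0")
  if (!all(out$sex %in% c(0, 1))) abort_field("sex", "must be coded 0/1")
  if (!all(out$age_bracket %in% 0:5))
    abort_field("age_bracket", "must be an integer bracket index 0-5")
  out$death_type <- as.integer(out$death_type)
  out$sex <- as.integer(out$sex)
  out$age_bracket <- as.integer(out$age_bracket)
  out$batch <- as.character(out$batch)
  class(out) <- c("sample_covariates", "data.frame")
  out
}

#' Binary ventilation labels from covariates
#'
#' Returns an integer vector with 1 = ventilated (death_type 0) and
#' 0 = non-ventilated. The ventilated class is the positive class
#' everywhere in this package; every written output records the
#' convention in its header to prevent sign confusion.
#'
#' @param cov A `sample_covariates` table.
#' @return Integer 0/1 vector named by sample id.
#' @export
mv_labels <- function(cov) {
  stats::setNames(as.integer(cov$death_type == 0L), cov$sample_id)
}

#' Read / write the covariate TSV dialect
#'
#' Columns `SAMPID`, `DTHHRDY` (0 = ventilator, 1 = non-ventilator),
#' `SMTSISCH` (minutes), `SEX`, `AGE` (bracket index 0-5), `BATCH`.
#'
#' @param cov A `sample_covariates` table.
#' @param path File path.
#' @export
write_covariates_tsv <- function(cov, path) {
  dt <- data.table::data.table(
    SAMPID = cov$sample_id, DTHHRDY = cov$death_type,
    SMTSISCH = cov$ischemic_time, SEX = cov$sex,
    AGE = cov$age_bracket, BATCH = cov$batch)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  sample_covariates(data.frame(
    sample_id = dt$SAMPID, death_type = dt$DTHHRDY,
    ischemic_time = dt$SMTSISCH, sex = dt$SEX,
    age_bracket = dt$AGE, batch = dt$BATCH))
}
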