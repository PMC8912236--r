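# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a global seed
#'
#' All randomness in the package flows through one user-supplied integer
#' seed; each stage draws from its own deterministic sub-stream so that
#' adding draws to one stage never perturbs another.
#'
#' @param seed Global integer seed.
#' @param stage Character stage tag.
#' @return An integer seed, always within 32-bit range.
#' @keywords internal
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  # cheap string hash, stable across platforms
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != floor(x) || x < min)
    abort_field(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

assert_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max)
    abort_field(field, sprintf("must be a single finite number in [%s, %s]", min, max))
  invisible(as.numeric(x))
}
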