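# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed for (root seed, stratum index, parameter name).
# Keeps each stratum/parameter pair on its own RNG stream so that adding or
# removing a stratum never perturbs the draws of the others. Arithmetic is
# done in doubles (exact below 2^53) and reduced mod 2^31 - 1.
substream_seed <- function(seed, index, parameter) {
  chars <- utf8ToInt(as.character(parameter))
  pid <- sum(chars * seq_along(chars))
  raw <- (as.numeric(seed) %% 1000003) * 2011 +
    as.numeric(index) * 7919 + pid * 104729
  as.integer(raw %% 2147483647)
}

# Evaluate `expr` after seeding the RNG, restoring the caller's RNG state on
# exit so seeded package functions do not disturb user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Half-up rounding to an integer; round() uses round-half-even, which would
# make augmentation targets depend on parity.
round_half_up <- function(x) floor(x + 0.5)

#' Round to the nearest multiple of a unit
#'
#' Display helper used when reporting interval endpoints (e.g. to the nearest
#' 50 persons). Raw values are always retained alongside rounded ones.
#'
#' @param x Numeric vector.
#' @param unit Positive rounding unit (default 50).
#' @return `x` rounded to the nearest multiple of `unit` (ties away from zero).
#' @examples
#' round_to(c(15299.04, 14663.2), 50)
#' @export
round_to <- function(x, unit = 50) {
  if (!is.numeric(unit) || length(unit) != 1L || !is.finite(unit) || unit <= 0) {
    stop("`unit` must be a single positive number", call. = FALSE)
  }
  round_half_up(x / unit) * unit
}

check_count <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric value", name), call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  if (!positive && any(x < 0)) {
    stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)) ||
      any(x <= 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in (0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_flag_scalar <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}
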