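#' Naive benchmark-multiplier estimate of a disease population total
#'
#' The benchmark-multiplier method estimates the total number of persons with
#' a disease by dividing the known size of a well-enumerated subgroup (the
#' *benchmark*, e.g. all persons reimbursed for a disease-modifying therapy
#' in the index year) by that subgroup's share of the whole disease
#' population (the *multiplier*, estimated from a dataset taken to reflect
#' the target population).
#'
#' @param benchmark_count Nonnegative count of persons in the specific
#'   subgroup. Vectorised.
#' @param multiplier_fraction The subgroup's share of the disease population,
#'   in `(0, 1]`. Vectorised.
#' @return Estimated total count (real valued; rounding to whole persons is a
#'   reporting concern, see [round_to()]). Always at least `benchmark_count`.
#' @seealso [bias_corrected_estimate()] for the finite-sample correction,
#'   [per_100k()] for conversion to a rate.
#' @examples
#' naive_estimate(9503, 0.621)
#' @export
naive_estimate <- function(benchmark_count, multiplier_fraction) {
  check_count(benchmark_count, "benchmark_count")
  check_fraction(multiplier_fraction, "multiplier_fraction")
  benchmark_count / multiplier_fraction
}

#' Bias-corrected benchmark-multiplier estimate
#'
#' The plain ratio of two estimated quantities is biased upwards in finite
#' samples. The corrected estimator subtracts a term of order `1/n`:
#' \deqn{\hat{N}/\hat{\pi} - \frac{1}{n}\,\hat{N}\,(1/\hat{\pi} - 1)}
#' where `n` is the sample size of the multiplier dataset. The correction
#' vanishes as `n` grows and is exactly zero when the multiplier is 1 (the
#' subgroup is the whole population).
#'
#' In degenerate regimes (very small `n` together with a very small
#' multiplier) the corrected value could fall below zero; a negative person
#' count is meaningless, so the estimate is floored at 0 with a warning.
#'
#' @inheritParams naive_estimate
#' @param multiplier_sample_size Positive integer `n`, the size of the
#'   dataset the multiplier fraction was estimated from.
#' @return Estimated total count; never exceeds [naive_estimate()].
#' @examples
#' bias_corrected_estimate(9503, 0.621, 1567)
#' @export
bias_corrected_estimate <- function(benchmark_count, multiplier_fraction,
                                    multiplier_sample_size) {
  check_count(benchmark_count, "benchmark_count")
  check_fraction(multiplier_fraction, "multiplier_fraction")
  check_count(multiplier_sample_size, "multiplier_sample_size", positive = TRUE)
  if (any(multiplier_sample_size < 1)) {
    stop("`multiplier_sample_size` must be at least 1", call. = FALSE)
  }
  correction <- (1 / multiplier_sample_size) * benchmark_count *
    (1 / multiplier_fraction - 1)
  est <- benchmark_count / multiplier_fraction - correction
  if (any(est < 0)) {
    warning("bias-corrected estimate fell below zero and was floored at 0",
            call. = FALSE)
    est <- pmax(est, 0)
  }
  est
}

#' Convert a count to a rate per 100,000 persons at risk
#'
#' @param total_count Estimated (or observed) count of affected persons.
#'   Vectorised.
#' @param population_at_risk Positive size of the target population.
#' @return `total_count / population_at_risk * 100000`.
#' @examples
#' per_100k(15299.04, 8420000)
#' @export
per_100k <- function(total_count, population_at_risk) {
  if (!is.numeric(total_count) || anyNA(total_count)) {
    stop("`total_count` must be numeric", call. = FALSE)
  }
  check_count(population_at_risk, "population_at_risk", positive = TRUE)
  total_count / population_at_risk * 100000
}
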