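#' Sampling distribution for an uncertain parameter
#'
#' Describes the distribution a resampled parameter is drawn from: a point
#' value (`center`) with a relative half-width `delta`, so draws fall in
#' `[center * (1 - delta), center * (1 + delta)]`. The uniform family
#' expresses conservative, bounded uncertainty about a parameter whose true
#' value is only known to lie in a plausibility band (e.g. a registry's
#' market share reported as 65--67%); other families are an extension point.
#'
#' @param center Positive point value of the parameter.
#' @param relative_half_width Nonnegative relative half-width `delta`
#'   (default 0.05, i.e. +/- 5%). `0` gives a degenerate distribution.
#' @param family Distribution family; only `"uniform"` is implemented.
#' @return An object of class `uncertainty_spec`.
#' @examples
#' uncertainty_spec(9503, 0.05)
#' @export
uncertainty_spec <- function(center, relative_half_width = 0.05,
                             family = "uniform") {
  check_count(center, "center", positive = TRUE)
  if (length(center) != 1L) stop("`center` must be a single value", call. = FALSE)
  if (!is.numeric(relative_half_width) || length(relative_half_width) != 1L ||
      is.na(relative_half_width) || relative_half_width < 0) {
    stop("`relative_half_width` must be a single nonnegative number",
         call. = FALSE)
  }
  if (!is.character(family) || length(family) != 1L) {
    stop("`family` must be a single string", call. = FALSE)
  }
  if (!family %in% "uniform") {
    stop(sprintf("unsupported distribution family '%s'", family),
         call. = FALSE)
  }
  structure(
    list(center = center, relative_half_width = relative_half_width,
         family = family),
    class = "uncertainty_spec"
  )
}

#' Draw values from an uncertainty specification
#'
#' Uses and deterministically advances R's global random number stream, so a
#' preceding `set.seed()` makes the draws reproducible.
#'
#' @param spec An [uncertainty_spec()].
#' @param n Number of draws (default 1).
#' @return Numeric vector of length `n`, each value inside
#'   `center * (1 +/- relative_half_width)`.
#' @examples
#' set.seed(1)
#' draw_parameter(uncertainty_spec(0.621, 0.05), 5)
#' @export
draw_parameter <- function(spec, n = 1L) {
  if (!inherits(spec, "uncertainty_spec")) {
    stop("`spec` must be an uncertainty_spec object", call. = FALSE)
  }
  delta <- spec$relative_half_width
  stats::runif(n, spec$center * (1 - delta), spec$center * (1 + delta))
}

#' Define a benchmark stratum
#'
#' Estimation can be carried out separately within strata (typically 5-year
#' bands of disease duration) and the stratum estimates summed into the
#' population total. Each stratum carries its own benchmark-size
#' specification and multiplier specification.
#'
#' @param label Unique stratum label, e.g. `"5-9 years"`.
#' @param size_spec [uncertainty_spec()] for the stratum's benchmark count.
#' @param multiplier_spec [uncertainty_spec()] for the stratum's multiplier
#'   fraction; its center must lie in `(0, 1]`.
#' @return An object of class `benchmark_stratum`.
#' @export
benchmark_stratum <- function(label, size_spec, multiplier_spec) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("`label` must be a single string", call. = FALSE)
  }
  if (!inherits(size_spec, "uncertainty_spec") ||
      !inherits(multiplier_spec, "uncertainty_spec")) {
    stop("`size_spec` and `multiplier_spec` must be uncertainty_spec objects",
         call. = FALSE)
  }
  check_fraction(multiplier_spec$center, "multiplier_spec$center")
  structure(
    list(label = label, size_spec = size_spec,
         multiplier_spec = multiplier_spec),
    class = "benchmark_stratum"
  )
}

#' Stratified Monte Carlo resampling of the prevalence estimate
#'
#' For each replicate, draws the benchmark count and the multiplier fraction
#' of every stratum from their uncertainty specifications, computes the
#' bias-corrected estimate per stratum, and sums the strata into a total.
#' Repeating this many times yields an empirical distribution of the total
#' that propagates the stated parameter uncertainty.
#'
#' Two sharing modes are supported. With `"per-stratum-independent"` (the
#' default) every stratum draws both of its parameters independently, so
#' stratum-level deviations partially average out in the sum. With
#' `"shared-across-strata"` one relative deviation per parameter is drawn per
#' replicate and applied to every stratum, modelling a systematic (perfectly
#' correlated) error such as a misjudged registry market share.
#'
#' Random numbers come from deterministic substreams keyed on
#' `(seed, stratum index, parameter)`, so adding a stratum does not perturb
#' the draws of existing strata, and an identical configuration plus seed
#' reproduces the replicate totals exactly. The caller's RNG state is left
#' untouched. Sampled multiplier values are capped at 1 (a share cannot
#' exceed 1).
#'
#' @param strata List of [benchmark_stratum()] objects with unique labels.
#' @param multiplier_sample_size Sample size `n` of the multiplier dataset,
#'   held fixed across replicates and strata.
#' @param replicates Number of Monte Carlo replicates (default 100,000).
#' @param seed Integer root seed.
#' @param sharing_mode `"per-stratum-independent"` or
#'   `"shared-across-strata"`.
#' @param keep_stratum_estimates If `TRUE`, also return the per-stratum
#'   replicate estimates as a `replicates x strata` matrix (for diagnostics).
#' @return An object of class `prevalence_distribution` with elements
#'   `replicate_totals`, `replicates`, `seed`, `sharing_mode`,
#'   `strata_labels`, `draw_summary` (min/mean/max of each drawn parameter,
#'   for audit) and optionally `stratum_estimates`.
#' @examples
#' st <- benchmark_stratum("all",
#'   uncertainty_spec(9503, 0.05), uncertainty_spec(0.621, 0.05))
#' d <- run_resampling(list(st), 1567, replicates = 1000, seed = 7)
#' summarize_distribution(d)
#' @export
run_resampling <- function(strata, multiplier_sample_size,
                           replicates = 100000L, seed = 1L,
                           sharing_mode = c("per-stratum-independent",
                                            "shared-across-strata"),
                           keep_stratum_estimates = FALSE) {
  sharing_mode <- match.arg(sharing_mode)
  if (!is.list(strata) || length(strata) == 0L) {
    stop("`strata` must be a non-empty list of benchmark_stratum objects",
         call. = FALSE)
  }
  if (!all(vapply(strata, inherits, logical(1), "benchmark_stratum"))) {
    stop("every element of `strata` must be a benchmark_stratum", call. = FALSE)
  }
  labels <- vapply(strata, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("stratum labels must be unique", call. = FALSE)
  }
  check_count(replicates, "replicates", positive = TRUE)
  replicates <- as.integer(replicates)
  check_count(multiplier_sample_size, "multiplier_sample_size", positive = TRUE)
  check_flag_scalar(keep_stratum_estimates, "keep_stratum_estimates")

  totals <- numeric(replicates)
  est_mat <- if (keep_stratum_estimates) {
    matrix(NA_real_, nrow = replicates, ncol = length(strata),
           dimnames = list(NULL, labels))
  }
  summaries <- vector("list", length(strata))

  if (sharing_mode == "shared-across-strata") {
    w_size <- with_seed(substream_seed(seed, 0L, "shared-size"),
                        stats::runif(replicates, -1, 1))
    w_mult <- with_seed(substream_seed(seed, 0L, "shared-multiplier"),
                        stats::runif(replicates, -1, 1))
  }

  for (i in seq_along(strata)) {
    st <- strata[[i]]
    if (sharing_mode == "per-stratum-independent") {
      size_draws <- with_seed(substream_seed(seed, i, "size"),
                              draw_parameter(st$size_spec, replicates))
      mult_draws <- with_seed(substream_seed(seed, i, "multiplier"),
                              draw_parameter(st$multiplier_spec, replicates))
    } else {
      size_draws <- st$size_spec$center *
        (1 + w_size * st$size_spec$relative_half_width)
      mult_draws <- st$multiplier_spec$center *
        (1 + w_mult * st$multiplier_spec$relative_half_width)
    }
    mult_draws <- pmin(mult_draws, 1)
    est <- bias_corrected_estimate(size_draws, mult_draws,
                                   multiplier_sample_size)
    totals <- totals + est
    if (keep_stratum_estimates) est_mat[, i] <- est
    summaries[[i]] <- data.frame(
      stratum = st$label,
      parameter = c("benchmark_count", "multiplier_fraction"),
      min = c(min(size_draws), min(mult_draws)),
      mean = c(mean(size_draws), mean(mult_draws)),
      max = c(max(size_draws), max(mult_draws))
    )
  }

  structure(
    list(
      replicate_totals = totals,
      replicates = replicates,
      seed = as.integer(seed),
      sharing_mode = sharing_mode,
      strata_labels = labels,
      multiplier_sample_size = multiplier_sample_size,
      draw_summary = do.call(rbind, summaries),
      stratum_estimates = est_mat
    ),
    class = "prevalence_distribution"
  )
}

#' @export
print.prevalence_distribution <- function(x, ...) {
  cat(sprintf(
    "Prevalence distribution: %d replicates over %d strata (%s, seed %d)\n",
    x$replicates, length(x$strata_labels), x$sharing_mode, x$seed))
  s <- summarize_distribution(x)
  cat(sprintf("  95%% interval %.1f - %.1f, median %.1f\n",
              s$lower, s$upper, s$median))
  invisible(x)
}

#' Percentile interval summary of a replicate distribution
#'
#' Returns the empirical percentile interval (lower, median, upper) of the
#' replicate totals at the stated level, using linear interpolation between
#' order statistics (`stats::quantile` type 7). This is the package's single
#' quantile convention, shared with interquartile ranges in dataset
#' comparisons.
#'
#' @param distribution A `prevalence_distribution` (from [run_resampling()])
#'   or a bare numeric vector of replicate values.
#' @param level Interval level in `(0, 1)` (default 0.95).
#' @return An object of class `interval_summary` with fields `level`,
#'   `lower`, `median`, `upper`.
#' @examples
#' summarize_distribution(1:1000, level = 0.95)
#' @export
summarize_distribution <- function(distribution, level = 0.95) {
  x <- if (inherits(distribution, "prevalence_distribution")) {
    distribution$replicate_totals
  } else if (is.numeric(distribution)) {
    distribution
  } else {
    stop("`distribution` must be a prevalence_distribution or numeric vector",
         call. = FALSE)
  }
  if (length(x) == 0L || anyNA(x)) {
    stop("replicate distribution is empty or contains missing values",
         call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(x, c(alpha, 0.5, 1 - alpha), type = 7, names = FALSE)
  structure(
    list(level = level, lower = q[1], median = q[2], upper = q[3]),
    class = "interval_summary"
  )
}

#' @export
print.interval_summary <- function(x, ...) {
  cat(sprintf("%.0f%% interval: %.2f - %.2f (median %.2f)\n",
              100 * x$level, x$lower, x$upper, x$median))
  invisible(x)
}
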