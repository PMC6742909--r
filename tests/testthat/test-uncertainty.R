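published_stratum <- function(delta = 0.05, size = 9503, mult = 0.621,
                          label = "all") {
  benchmark_stratum(label, uncertainty_spec(size, delta),
                    uncertainty_spec(mult, delta))
}

test_that("uncertainty specs validate their domain", {
  expect_error(uncertainty_spec(-1, 0.05), "center")
  expect_error(uncertainty_spec(0, 0.05), "center")
  expect_error(uncertainty_spec(10, -0.01), "relative_half_width")
  expect_error(uncertainty_spec(10, 0.05, family = "triangular"),
               "unsupported distribution family")
  expect_error(benchmark_stratum("s", uncertainty_spec(10),
                                 uncertainty_spec(1.4)),
               "multiplier")
})

test_that("parameter draws respect the configured bounds", {
  set.seed(1)
  degenerate <- draw_parameter(uncertainty_spec(9503, 0), 1000)
  expect_true(all(degenerate == 9503))

  draws <- draw_parameter(uncertainty_spec(9503, 0.05), 10000)
  expect_true(all(draws >= 9503 * 0.95 & draws <= 9503 * 1.05))
  expect_true(all(draws >= 9027.85 & draws <= 9978.15))

  # law of large numbers: the sample mean converges to the center
  mult <- draw_parameter(uncertainty_spec(0.621, 0.05), 100000)
  expect_lt(abs(mean(mult) - 0.621), 0.001)
})

test_that("degenerate widths collapse every replicate to the point estimate", {
  d <- run_resampling(list(published_stratum(delta = 0)), 1567,
                      replicates = 500, seed = 3)
  point <- bias_corrected_estimate(9503, 0.621, 1567)
  expect_equal(d$replicate_totals, rep(point, 500), tolerance = 1e-12)
  s <- summarize_distribution(d, 0.95)
  expect_equal(s$lower, point, tolerance = 1e-12)
  expect_equal(s$upper, point, tolerance = 1e-12)
})

test_that("resampling is reproducible by seed and sensitive to it", {
  strata <- list(published_stratum(label = "a"),
                 published_stratum(size = 1000, label = "b"))
  d1 <- run_resampling(strata, 1567, replicates = 2000, seed = 42)
  d2 <- run_resampling(strata, 1567, replicates = 2000, seed = 42)
  d3 <- run_resampling(strata, 1567, replicates = 2000, seed = 43)
  expect_identical(d1$replicate_totals, d2$replicate_totals)
  expect_false(identical(d1$replicate_totals, d3$replicate_totals))
})

test_that("adding a stratum does not perturb the draws of existing strata", {
  two <- list(published_stratum(label = "a"), published_stratum(size = 1000, label = "b"))
  three <- c(two, list(published_stratum(size = 2000, label = "c")))
  d2 <- run_resampling(two, 1567, replicates = 1000, seed = 5,
                       keep_stratum_estimates = TRUE)
  d3 <- run_resampling(three, 1567, replicates = 1000, seed = 5,
                       keep_stratum_estimates = TRUE)
  expect_identical(d2$stratum_estimates[, "a"], d3$stratum_estimates[, "a"])
  expect_identical(d2$stratum_estimates[, "b"], d3$stratum_estimates[, "b"])
})

test_that("interval width is non-decreasing in the sampling width", {
  widths <- vapply(c(0, 0.01, 0.05, 0.10), function(delta) {
    d <- run_resampling(list(published_stratum(delta = delta)), 1567,
                        replicates = 5000, seed = 9)
    s <- summarize_distribution(d)
    s$upper - s$lower
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("shared draws across strata give a wider interval than independent draws", {
  strata <- lapply(1:5, function(i) published_stratum(size = 9503 / 5,
                                                  label = paste0("s", i)))
  ind <- summarize_distribution(
    run_resampling(strata, 1567, replicates = 20000, seed = 2,
                   sharing_mode = "per-stratum-independent"))
  sh <- summarize_distribution(
    run_resampling(strata, 1567, replicates = 20000, seed = 2,
                   sharing_mode = "shared-across-strata"))
  expect_gt(sh$upper - sh$lower, ind$upper - ind$lower)
  # shared deviations make the stratified run equivalent to a single stratum
  single <- summarize_distribution(
    run_resampling(list(published_stratum()), 1567, replicates = 20000, seed = 2,
                   sharing_mode = "shared-across-strata"))
  expect_equal((sh$upper - sh$lower) / sh$median,
               (single$upper - single$lower) / single$median,
               tolerance = 0.02)
})

test_that("the percentile summary uses linear interpolation between order statistics", {
  s <- summarize_distribution(as.numeric(1:1000), level = 0.95)
  expect_equal(s$lower, 25.975)
  expect_equal(s$upper, 975.025)
  expect_equal(s$median, 500.5)

  const <- summarize_distribution(rep(7, 100))
  expect_true(const$lower == 7 && const$median == 7 && const$upper == 7)

  expect_error(summarize_distribution(numeric(0)), "empty")
  expect_error(summarize_distribution(1:10, level = 1), "level")
  expect_error(run_resampling(list(), 100), "non-empty")
})

test_that("the median of stratum sums matches the sum of stratum medians", {
  strata <- lapply(1:3, function(i) published_stratum(size = 3000,
                                                  label = paste0("s", i)))
  d <- run_resampling(strata, 1567, replicates = 20000, seed = 13,
                      keep_stratum_estimates = TRUE)
  med_of_sum <- summarize_distribution(d)$median
  sum_of_meds <- sum(apply(d$stratum_estimates, 2, stats::median))
  expect_equal(med_of_sum, sum_of_meds, tolerance = 0.005)
})
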