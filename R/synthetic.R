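# Synthetic multi-source registry generator: a disease population with known
# true size, from which a multiplier sample, an under-covering benchmark and
# a full-coverage reference source are derived. Lets every pipeline stage be
# exercised against a known truth without access to any real registry.

#' Default category marginals for the synthetic population
#'
#' Marginal distributions of the categorical patient variables, patterned on
#' the descriptive statistics of a national MS registry and an augmented
#' treatment registry: sex share, three adult age bands, seven greater
#' regions, disease course mix, and treatment type mix among persons
#' currently on a disease-modifying therapy (DMT). `untreated_status` splits
#' the untreated remainder into never- vs previously-treated. Each marginal
#' is normalised to sum to 1.
#'
#' @return A named list of named probability vectors.
#' @export
default_marginals <- function() {
  norm <- function(p) p / sum(p)
  list(
    sex = norm(c(female = 0.736, male = 0.264)),
    age_band = norm(c("19-49" = 0.555, "50-64" = 0.345, "65+" = 0.101)),
    region = norm(c("Lake Geneva region" = 0.141, "Midlands" = 0.246,
                    "North-western Switzerland" = 0.165,
                    "Eastern Switzerland" = 0.138, "Ticino" = 0.030,
                    "Central Switzerland" = 0.095, "Zurich" = 0.185)),
    disease_type = norm(c(RRMS = 0.722, SPMS = 0.168, PPMS = 0.109)),
    dmt_type = norm(c(injectable = 0.245, oral = 0.583, infusion = 0.157,
                      other = 0.015)),
    untreated_status = norm(c(never = 0.138, past = 0.241))
  )
}

#' Log-normal disease-duration specification
#'
#' Calibrates a log-normal to printed duration summaries (median and
#' quartiles, in years since first symptoms). A log-normal has only two free
#' parameters, so the three quantiles cannot in general be matched exactly;
#' `meanlog` and `sdlog` are fitted by least squares on the log scale over
#' the three target quantiles, which preserves the right skew and the
#' quartile ratio.
#'
#' @param q1,median,q3 Target quartiles/median in years (defaults 3.8, 8.1,
#'   14.2).
#' @return A list with `meanlog`, `sdlog` and the targets.
#' @export
duration_lognormal <- function(q1 = 3.8, median = 8.1, q3 = 14.2) {
  if (!(0 < q1 && q1 < median && median < q3)) {
    stop("duration quantiles must satisfy 0 < q1 < median < q3", call. = FALSE)
  }
  y <- log(c(q1, median, q3))
  z <- stats::qnorm(c(0.25, 0.5, 0.75))
  sdlog <- sum(z * y) / sum(z^2)
  meanlog <- mean(y)
  list(meanlog = meanlog, sdlog = sdlog,
       targets = c(q1 = q1, median = median, q3 = q3))
}

#' Configuration of the synthetic study system
#'
#' Defines the ground truth and the linkage structure of the synthetic
#' sources: the true number of diseased persons, the share currently on a
#' disease-modifying therapy (the true multiplier), the size of the simple
#' random sample standing in for the population-reflecting multiplier
#' dataset, and the benchmark source's coverage of the treated subgroup.
#' Defaults reproduce the scale of the Swiss MS 2016 use case so end-to-end
#' checks run at realistic size in seconds.
#'
#' @param true_total Ground-truth number of diseased persons (default 15,300).
#' @param dmt_share Probability a person is on a DMT in the last 12 months
#'   (default 0.621).
#' @param multiplier_sample_size Size of the multiplier sample (default 1,567).
#' @param benchmark_coverage Probability a treated person's record reaches
#'   the benchmark source (default 0.65).
#' @param marginals Category marginals, see [default_marginals()]. Each must
#'   sum to 1 (tolerance 1e-9).
#' @param duration Disease-duration spec, see [duration_lognormal()].
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_total = 15300L, dmt_share = 0.621,
                             multiplier_sample_size = 1567L,
                             benchmark_coverage = 0.65,
                             marginals = default_marginals(),
                             duration = duration_lognormal(),
                             seed = 1L) {
  check_count(true_total, "true_total", positive = TRUE)
  check_fraction(dmt_share, "dmt_share")
  check_count(multiplier_sample_size, "multiplier_sample_size", positive = TRUE)
  check_fraction(benchmark_coverage, "benchmark_coverage")
  needed <- c("sex", "age_band", "region", "disease_type", "dmt_type",
              "untreated_status")
  if (!is.list(marginals) || !all(needed %in% names(marginals))) {
    stop(sprintf("`marginals` must contain: %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  for (m in needed) {
    p <- marginals[[m]]
    if (!is.numeric(p) || is.null(names(p)) || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("marginal '%s' must be named probabilities summing to 1", m),
           call. = FALSE)
    }
  }
  structure(
    list(true_total = as.integer(true_total), dmt_share = dmt_share,
         multiplier_sample_size = as.integer(multiplier_sample_size),
         benchmark_coverage = benchmark_coverage, marginals = marginals,
         duration = duration, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

age_band_bounds <- list("19-49" = c(19L, 49L), "50-64" = c(50L, 64L),
                        "65+" = c(65L, 84L))

sample_categories <- function(p, n) {
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate the synthetic disease population
#'
#' Draws `true_total` patient records with categorical fields from the
#' configured marginals, treatment status `current-12mo` with probability
#' `dmt_share` independently per record, treatment type conditional on being
#' treated (untreated records get `dmt_type = "none"`), age uniform within
#' the drawn band, and disease duration from the configured log-normal
#' (rounded to 0.1 years). Deterministic given the config's seed; the
#' caller's RNG state is untouched.
#'
#' @param config A [synthetic_config()].
#' @return A [registry_dataset()] named "synthetic population" with exactly
#'   `true_total` records and coverage 1.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be a synthetic_config", call. = FALSE)
  }
  n <- config$true_total
  m <- config$marginals
  with_seed(substream_seed(config$seed, 0L, "population"), {
    band <- sample_categories(m$age_band, n)
    lo <- vapply(age_band_bounds[band], `[[`, integer(1), 1L)
    hi <- vapply(age_band_bounds[band], `[[`, integer(1), 2L)
    age <- lo + floor(stats::runif(n) * (hi - lo + 1L))
    treated <- stats::runif(n) < config$dmt_share
    dmt_status <- ifelse(treated, "current-12mo",
                         sample_categories(m$untreated_status, n))
    dmt_type <- rep("none", n)
    dmt_type[treated] <- sample_categories(m$dmt_type, sum(treated))
    duration <- round(stats::rlnorm(n, config$duration$meanlog,
                                    config$duration$sdlog), 1)
    records <- data.frame(
      person_id = sprintf("P%06d", seq_len(n)),
      sex = sample_categories(m$sex, n),
      age_years = as.integer(age),
      region = sample_categories(m$region, n),
      disease_type = sample_categories(m$disease_type, n),
      dmt_status = dmt_status,
      dmt_type = dmt_type,
      disease_duration_years = duration,
      stringsAsFactors = FALSE
    )
    registry_dataset(records, "synthetic population", coverage = 1)
  })
}

#' Derive the linked synthetic data sources
#'
#' Splits the synthetic population into the three sources the estimation
#' framework consumes:
#' * `multiplier_sample` — a simple random sample of
#'   `multiplier_sample_size` persons (stands in for a population-reflecting
#'   patient registry);
#' * `benchmark` — the treated (DMT) subgroup thinned record-wise with
#'   probability `benchmark_coverage` (an under-covering reimbursement
#'   registry);
#' * `reference` — all treated persons, carrying an `in_benchmark` flag
#'   marking those retained in the benchmark (a source that sees the whole
#'   treated group, enabling coverage estimation).
#'
#' Benchmark and reference are nested in the population by `person_id`.
#' Deterministic given the config's seed.
#'
#' @param population The output of [generate_population()].
#' @param config The same [synthetic_config()].
#' @return A list with elements `multiplier_sample`, `benchmark`,
#'   `reference`, each a [registry_dataset()].
#' @export
derive_sources <- function(population, config) {
  if (!inherits(population, "registry_dataset")) {
    stop("`population` must be a registry_dataset", call. = FALSE)
  }
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be a synthetic_config", call. = FALSE)
  }
  recs <- population$records
  if (config$multiplier_sample_size > nrow(recs)) {
    stop("`multiplier_sample_size` exceeds the population size", call. = FALSE)
  }
  with_seed(substream_seed(config$seed, 1L, "sources"), {
    idx <- sample.int(nrow(recs), config$multiplier_sample_size)
    multiplier_sample <- registry_dataset(
      recs[sort(idx), , drop = FALSE], "synthetic multiplier sample")
    treated <- recs[recs$dmt_status == "current-12mo", , drop = FALSE]
    kept <- stats::runif(nrow(treated)) < config$benchmark_coverage
    benchmark <- registry_dataset(
      treated[kept, , drop = FALSE], "synthetic benchmark",
      coverage = config$benchmark_coverage)
    ref <- treated
    ref$in_benchmark <- kept
    reference <- registry_dataset(ref, "synthetic reference", coverage = 1)
    list(multiplier_sample = multiplier_sample, benchmark = benchmark,
         reference = reference)
  })
}

#' Write a synthetic study system to disk
#'
#' Writes the three derived sources as the CSV format [read_registry()]
#' reads, plus the configuration as YAML, into a directory.
#'
#' @param sources Output of [derive_sources()].
#' @param config The [synthetic_config()] used.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_sources <- function(sources, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    multiplier = file.path(dir, "multiplier.csv"),
    benchmark = file.path(dir, "benchmark.csv"),
    reference = file.path(dir, "reference.csv"),
    config = file.path(dir, "synthetic-config.yaml")
  )
  write_registry(sources$multiplier_sample, paths[["multiplier"]])
  write_registry(sources$benchmark, paths[["benchmark"]])
  write_registry(sources$reference, paths[["reference"]])
  cfg <- unclass(config)
  cfg$marginals <- lapply(cfg$marginals, as.list)
  cfg$duration <- as.list(cfg$duration$targets)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}
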