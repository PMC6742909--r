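# Configuration-driven end-to-end estimation pipeline and report rendering.

#' Default run configuration
#'
#' Returns the pipeline defaults: DMT-in-last-12-months subgroup predicate,
#' region x dmt_type augmentation cells, 5-year disease-duration strata,
#' +/- 5% uniform uncertainty on both the benchmark count and the multiplier
#' fraction, 100,000 replicates with independent per-stratum draws, a 95%
#' percentile interval, and display rounding to the nearest 50 persons.
#'
#' @return A named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    case_definition = "persons with the disease (case definition unspecified)",
    index_period = NA,
    population_at_risk = NULL,
    predicate = "dmt_last_12mo",
    multiplier_path = NULL,
    benchmark_path = NULL,
    reference_path = NULL,
    augment = TRUE,
    strata_vars = c("region", "dmt_type"),
    stratify_by = "disease_duration_years",
    band_width = 5,
    delta_benchmark = 0.05,
    delta_multiplier = 0.05,
    replicates = 100000L,
    seed = 1L,
    sharing_mode = "per-stratum-independent",
    level = 0.95,
    round_to = 50,
    comparison_variables = c("sex", "age_years", "disease_type", "dmt_type",
                             "region", "disease_duration_years"),
    population_table = NULL,
    allocation = NULL,
    output_dir = NULL
  )
}

#' Read a run configuration file
#'
#' Reads a YAML key-value file and merges it over [default_run_config()].
#' Keys present in the file override the defaults; unknown keys are an error
#' (they are usually typos).
#'
#' @param path Path to a YAML configuration file.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(user)] <- user
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Build disease-duration strata from a benchmark dataset
#'
#' Splits the benchmark count into bands of disease duration (default 5-year
#' bands: 0-4, 5-9, ...), records with unknown duration forming their own
#' band. Each stratum gets the band's count as its benchmark-size center and
#' a common multiplier center (the subgroup share estimated from the
#' multiplier dataset), each wrapped in a uniform [uncertainty_spec()].
#'
#' @param benchmark A [registry_dataset()] (typically the augmented benchmark).
#' @param multiplier_center Multiplier fraction center, in `(0, 1]`.
#' @param band_width Band width in years (default 5).
#' @param delta_benchmark,delta_multiplier Relative half-widths of the
#'   uniform sampling distributions (default 0.05 each).
#' @return A list of [benchmark_stratum()] objects whose size centers sum to
#'   the benchmark record count.
#' @export
duration_strata <- function(benchmark, multiplier_center, band_width = 5,
                            delta_benchmark = 0.05, delta_multiplier = 0.05) {
  if (!inherits(benchmark, "registry_dataset")) {
    stop("`benchmark` must be a registry_dataset", call. = FALSE)
  }
  check_fraction(multiplier_center, "multiplier_center")
  check_count(band_width, "band_width", positive = TRUE)
  dur <- benchmark$records$disease_duration_years
  band_lo <- floor(dur / band_width) * band_width
  label <- ifelse(is.na(dur), "unknown duration",
                  sprintf("%g-%g years", band_lo, band_lo + band_width - 1))
  counts <- table(label)
  ord <- order(suppressWarnings(as.numeric(sub("-.*", "", names(counts)))),
               na.last = TRUE)
  counts <- counts[ord]
  lapply(names(counts), function(lb) {
    benchmark_stratum(
      lb,
      uncertainty_spec(as.numeric(counts[[lb]]), delta_benchmark),
      uncertainty_spec(multiplier_center, delta_multiplier)
    )
  })
}

#' Run the full estimation pipeline
#'
#' Executes the framework end to end: read the multiplier, benchmark and
#' reference tables (or take them pre-loaded), compare multiplier and
#' benchmark over the configured key disease characteristics, augment the
#' benchmark by reference-estimated inverse coverage, extract the subgroup
#' share (the multiplier fraction) from the multiplier dataset, build
#' disease-duration strata, propagate the parameter uncertainty by
#' stratified Monte Carlo resampling, and summarize the replicate
#' distribution as a percentile interval, in persons and per 100,000 at
#' risk. If an age x sex population table is configured, an age/sex-specific
#' rates table is produced as well.
#'
#' Any stage error is re-raised prefixed with the stage name, and no outputs
#' are written on failure. If `config$output_dir` is set, the report bundle
#' is written there (via [write_report()]) only after every stage succeeded.
#'
#' @param config A configuration list (see [default_run_config()]), a YAML
#'   path, or a list with a `datasets` element holding pre-loaded
#'   `multiplier`, `benchmark` and (optionally) `reference`
#'   [registry_dataset()] objects in place of file paths.
#' @return An object of class `prevalence_report`: point estimate, replicate
#'   distribution, raw and display-rounded intervals, rate interval per
#'   100,000, the comparison report, the rates table (or `NULL`), and a run
#'   log with the seed and all resolved parameters.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  if (!is.list(config)) {
    stop("`config` must be a configuration list or a YAML path", call. = FALSE)
  }
  cfg <- default_run_config()
  extra <- setdiff(names(config), c(names(cfg), "datasets"))
  if (length(extra) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  cfg[names(config)] <- config

  datasets <- pipeline_stage("data_prep", {
    ds <- cfg$datasets
    if (is.null(ds)) {
      for (role in c("multiplier", "benchmark")) {
        p <- cfg[[paste0(role, "_path")]]
        if (is.null(p)) {
          stop(sprintf("no %s dataset: set %s_path or supply datasets$%s",
                       role, role, role))
        }
      }
      ds <- list(
        multiplier = read_registry(cfg$multiplier_path, "multiplier"),
        benchmark = read_registry(cfg$benchmark_path, "benchmark"),
        reference = if (!is.null(cfg$reference_path)) {
          read_registry(cfg$reference_path, "reference")
        }
      )
    }
    ds
  })

  comparison <- pipeline_stage("data_prep", {
    compare_datasets(datasets$multiplier, datasets$benchmark,
                     cfg$comparison_variables)
  })

  benchmark <- pipeline_stage("data_prep", {
    if (isTRUE(cfg$augment) && !is.null(datasets$reference)) {
      augment_benchmark(datasets$benchmark, datasets$reference,
                        cfg$strata_vars)
    } else {
      datasets$benchmark
    }
  })

  extraction <- pipeline_stage("data_prep", {
    extract_subgroup(datasets$multiplier, cfg$predicate)
  })

  strata <- pipeline_stage("uncertainty_engine", {
    duration_strata(benchmark, extraction$share, cfg$band_width,
                    cfg$delta_benchmark, cfg$delta_multiplier)
  })

  distribution <- pipeline_stage("uncertainty_engine", {
    run_resampling(strata, extraction$n, replicates = cfg$replicates,
                   seed = cfg$seed, sharing_mode = cfg$sharing_mode)
  })

  benchmark_total <- nrow(benchmark$records)
  point <- bias_corrected_estimate(benchmark_total, extraction$share,
                                   extraction$n)
  interval <- summarize_distribution(distribution, cfg$level)

  if (is.null(cfg$population_at_risk)) {
    stop("[reporting] `population_at_risk` must be set in the configuration",
         call. = FALSE)
  }
  rate <- pipeline_stage("reporting", {
    lapply(interval[c("lower", "median", "upper")],
           per_100k, population_at_risk = cfg$population_at_risk)
  })

  rates_table <- pipeline_stage("reporting", {
    if (!is.null(cfg$population_table)) {
      pop_tab <- cfg$population_table
      if (is.character(pop_tab)) {
        pop_tab <- utils::read.csv(pop_tab, stringsAsFactors = FALSE)
      }
      alloc <- cfg$allocation %||% allocation_from_dataset(datasets$multiplier)
      age_sex_rates(interval$median, alloc, pop_tab)
    }
  })

  report <- structure(
    list(
      point_estimate = point,
      distribution = distribution,
      interval = interval,
      interval_rounded = lapply(interval[c("lower", "median", "upper")],
                                round_to, unit = cfg$round_to),
      rate_per_100k = rate,
      comparison = comparison,
      rates_table = rates_table,
      pi_hat = extraction$share,
      n_multiplier = extraction$n,
      benchmark_total = benchmark_total,
      log = list(
        case_definition = cfg$case_definition,
        index_period = cfg$index_period,
        population_at_risk = cfg$population_at_risk,
        predicate = cfg$predicate,
        seed = cfg$seed,
        replicates = cfg$replicates,
        sharing_mode = cfg$sharing_mode,
        level = cfg$level,
        delta_benchmark = cfg$delta_benchmark,
        delta_multiplier = cfg$delta_multiplier,
        band_width = cfg$band_width,
        strata_vars = cfg$strata_vars,
        augmented = isTRUE(cfg$augment) && !is.null(datasets$reference),
        n_excluded_from_multiplier = extraction$n_excluded,
        strata = data.frame(
          label = vapply(strata, `[[`, character(1), "label"),
          size_center = vapply(strata, function(s) s$size_spec$center,
                               numeric(1))
        ),
        draw_summary = distribution$draw_summary
      )
    ),
    class = "prevalence_report"
  )

  if (!is.null(cfg$output_dir)) {
    write_report(report, cfg$output_dir)
  }
  report
}

#' @export
print.prevalence_report <- function(x, ...) {
  iv <- x$interval
  rd <- x$interval_rounded
  cat("Benchmark-multiplier prevalence estimate\n")
  cat(sprintf("  benchmark count: %d   multiplier: %.4f (n = %d)\n",
              x$benchmark_total, x$pi_hat, x$n_multiplier))
  cat(sprintf("  point estimate: %.1f persons (%.0f rounded)\n",
              x$point_estimate, round_half_up(x$point_estimate)))
  cat(sprintf("  %.0f%% interval: %.1f - %.1f persons (display: %g - %g)\n",
              100 * iv$level, iv$lower, iv$upper, rd$lower, rd$upper))
  cat(sprintf("  rate per 100,000: %.1f - %.1f (median %.1f)\n",
              x$rate_per_100k$lower, x$rate_per_100k$upper,
              x$rate_per_100k$median))
  cat(sprintf("  seed %d, %d replicates, %s\n",
              x$log$seed, x$log$replicates, x$log$sharing_mode))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes `summary.json` (point estimate, raw and rounded interval, rate
#' interval, multiplier, seed and resolved parameters), `comparison.csv`,
#' `rates.csv` (if present) and `replicates.csv` (the raw replicate totals).
#'
#' @param report A `prevalence_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "prevalence_report")) {
    stop("`report` must be a prevalence_report", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    point_estimate = report$point_estimate,
    interval = report$interval[c("level", "lower", "median", "upper")],
    interval_rounded = report$interval_rounded,
    rate_per_100k = report$rate_per_100k,
    pi_hat = report$pi_hat,
    n_multiplier = report$n_multiplier,
    benchmark_total = report$benchmark_total,
    log = report$log[setdiff(names(report$log),
                             c("strata", "draw_summary"))]
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(as.data.frame(report$comparison),
                   file.path(dir, "comparison.csv"), row.names = FALSE)
  utils::write.csv(report$log$draw_summary,
                   file.path(dir, "draw-summary.csv"), row.names = FALSE)
  if (!is.null(report$rates_table)) {
    utils::write.csv(report$rates_table, file.path(dir, "rates.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(replicate = seq_along(report$distribution$replicate_totals),
               total = report$distribution$replicate_totals),
    file.path(dir, "replicates.csv"), row.names = FALSE)
  invisible(dir)
}

age_band_breaks <- c(0, 19, 50, 65, Inf)
age_band_labels <- c("0-18", "19-49", "50-64", "65+")

age_band_of <- function(age_years) {
  as.character(cut(age_years, breaks = age_band_breaks,
                   labels = age_band_labels, right = FALSE))
}

#' Empirical age x sex allocation from a dataset
#'
#' The fraction of a dataset's records in each (age band, sex) cell, used to
#' allocate the estimated total across cells when producing age/sex-specific
#' rates. Records with missing age or sex are excluded.
#'
#' @param dataset A [registry_dataset()].
#' @return A data frame with columns `age_band`, `sex`, `proportion` (summing
#'   to 1).
#' @export
allocation_from_dataset <- function(dataset) {
  if (!inherits(dataset, "registry_dataset")) {
    stop("`dataset` must be a registry_dataset", call. = FALSE)
  }
  recs <- dataset$records
  ok <- !is.na(recs$age_years) & !is.na(recs$sex) & recs$sex != "unknown"
  if (!any(ok)) {
    stop("no records with known age and sex to build an allocation from",
         call. = FALSE)
  }
  band <- age_band_of(recs$age_years[ok])
  tab <- table(band, recs$sex[ok])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("age_band", "sex", "count")
  df <- df[df$count > 0, , drop = FALSE]
  df$proportion <- df$count / sum(df$count)
  df$count <- NULL
  rownames(df) <- NULL
  df
}

#' Age- and sex-specific prevalence rates
#'
#' Allocates an estimated total count across (age band, sex) cells by the
#' given proportions and divides by the cell populations to obtain rates per
#' 100,000.
#'
#' @param total Estimated total count (typically the interval median).
#' @param allocation Data frame with columns `age_band`, `sex`, `proportion`;
#'   proportions must sum to 1 (tolerance 1e-6).
#' @param population_table Data frame with columns `age_band`, `sex`,
#'   `population` covering every allocation cell with positive population.
#' @return A data frame of class `rates_table` with columns `age_band`,
#'   `sex`, `estimated_count`, `population`, `rate_per_100k`. Counts sum to
#'   `total` up to rounding.
#' @export
age_sex_rates <- function(total, allocation, population_table) {
  check_count(total, "total")
  need_a <- c("age_band", "sex", "proportion")
  need_p <- c("age_band", "sex", "population")
  if (!is.data.frame(allocation) || !all(need_a %in% names(allocation))) {
    stop("`allocation` must have columns age_band, sex, proportion",
         call. = FALSE)
  }
  if (!is.data.frame(population_table) ||
      !all(need_p %in% names(population_table))) {
    stop("`population_table` must have columns age_band, sex, population",
         call. = FALSE)
  }
  if (abs(sum(allocation$proportion) - 1) > 1e-6) {
    stop("allocation proportions must sum to 1", call. = FALSE)
  }
  merged <- merge(allocation, population_table, by = c("age_band", "sex"),
                  all.x = TRUE)
  if (anyNA(merged$population)) {
    missing <- merged[is.na(merged$population), c("age_band", "sex")]
    stop(sprintf("population table is missing cell(s): %s",
                 paste(paste(missing$age_band, missing$sex), collapse = "; ")),
         call. = FALSE)
  }
  if (any(merged$population <= 0)) {
    stop("population table contains non-positive cell population(s)",
         call. = FALSE)
  }
  merged$estimated_count <- total * merged$proportion
  merged$rate_per_100k <- per_100k(merged$estimated_count, merged$population)
  out <- merged[order(merged$sex, merged$age_band),
                c("age_band", "sex", "estimated_count", "population",
                  "rate_per_100k")]
  rownames(out) <- NULL
  class(out) <- c("rates_table", "data.frame")
  out
}

#' Render a comparison for review
#'
#' Formats either a [compare_datasets()] report or a pair of rates tables
#' (e.g. the current estimate against user-supplied external or historical
#' rates) as aligned text with a difference column. Inputs are not modified.
#'
#' @param x A `comparison_report`, or a `rates_table`/data frame when `y` is
#'   given.
#' @param y Optional second rates table with the same `(age_band, sex)` keys.
#' @param labels Length-2 column labels used for the two rates tables.
#' @return A character vector of formatted lines (for a comparison report) or
#'   a data frame with `value_a`, `value_b` and `difference` columns (for two
#'   rates tables: `value_b - value_a`).
#' @export
render_comparison <- function(x, y = NULL, labels = c("a", "b")) {
  if (inherits(x, "comparison_report")) {
    lines <- c(sprintf("Comparison: %s vs %s", x$dataset_a, x$dataset_b))
    for (v in names(x$variables)) {
      e <- x$variables[[v]]
      lines <- c(lines, sprintf("%s (missing: %d vs %d)", v,
                                e$n_missing[["a"]], e$n_missing[["b"]]))
      if (e$type == "categorical") {
        lines <- c(lines, sprintf(
          "  %-28s %7.1f%% %7.1f%%  diff %5.1f pp",
          e$levels, 100 * e$prop_a, 100 * e$prop_b, 100 * e$abs_diff))
      } else {
        lines <- c(lines, sprintf(
          "  median (IQR)                 %s  vs  %s",
          sprintf("%.1f (%.1f-%.1f)", e$a[["median"]], e$a[["q1"]], e$a[["q3"]]),
          sprintf("%.1f (%.1f-%.1f)", e$b[["median"]], e$b[["q1"]], e$b[["q3"]])))
      }
    }
    return(lines)
  }
  if (is.null(y)) {
    stop("`x` must be a comparison_report, or supply two rates tables",
         call. = FALSE)
  }
  need <- c("age_band", "sex", "rate_per_100k")
  for (tab in list(x, y)) {
    if (!is.data.frame(tab) || !all(need %in% names(tab))) {
      stop("rates tables must have columns age_band, sex, rate_per_100k",
           call. = FALSE)
    }
  }
  key_x <- paste(x$age_band, x$sex)
  key_y <- paste(y$age_band, y$sex)
  mismatched <- c(setdiff(key_x, key_y), setdiff(key_y, key_x))
  if (length(mismatched) > 0L) {
    stop(sprintf("mismatched row key(s): %s",
                 paste(unique(mismatched), collapse = "; ")), call. = FALSE)
  }
  merged <- merge(
    x[, c("age_band", "sex", "rate_per_100k")],
    y[, c("age_band", "sex", "rate_per_100k")],
    by = c("age_band", "sex"), suffixes = c("_a", "_b"))
  names(merged)[names(merged) == "rate_per_100k_a"] <- paste0("value_", labels[1])
  names(merged)[names(merged) == "rate_per_100k_b"] <- paste0("value_", labels[2])
  merged$difference <- merged[[paste0("value_", labels[2])]] -
    merged[[paste0("value_", labels[1])]]
  merged[order(merged$sex, merged$age_band), , drop = FALSE]
}
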