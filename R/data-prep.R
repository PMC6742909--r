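# Registry tables: reading, subgroup extraction, benchmark augmentation and
# dataset comparison.

registry_required_cols <- c(
  "person_id", "sex", "age_years", "region", "disease_type",
  "dmt_status", "dmt_type", "disease_duration_years"
)

registry_levels <- list(
  sex = c("female", "male", "unknown"),
  disease_type = c("RRMS", "SPMS", "PPMS", "CIS", "other", "unknown"),
  dmt_status = c("never", "past", "current-12mo"),
  dmt_type = c("none", "injectable", "oral", "infusion", "other")
)

#' Construct a registry dataset
#'
#' A registry dataset is a patient-level table (one row per person) plus
#' source metadata: the source's name and, if known, its assumed coverage of
#' its target group (the fraction of that group the source actually
#' contains, e.g. a reimbursement registry's market share).
#'
#' Required columns: `person_id` (unique, non-missing), `sex`
#' (female/male/unknown), `age_years`, `region`, `disease_type`
#' (RRMS/SPMS/PPMS/CIS/other/unknown), `dmt_status`
#' (never/past/current-12mo), `dmt_type` (none/injectable/oral/infusion/
#' other) and `disease_duration_years`. `dmt_type` must be `"none"` exactly
#' for persons whose `dmt_status` is `never` or `past`. Extra columns (e.g. a
#' reference source's `in_benchmark` membership flag) are preserved.
#'
#' @param records A data frame of patient-level rows.
#' @param source_name Name of the data source.
#' @param coverage Fraction of its target group the source contains, in
#'   `(0, 1]`, or `NA` if unknown.
#' @return An object of class `registry_dataset` with elements `records`,
#'   `source_name`, `coverage`.
#' @export
registry_dataset <- function(records, source_name, coverage = NA_real_) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(registry_required_cols, names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf("records are missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.character(source_name) || length(source_name) != 1L) {
    stop("`source_name` must be a single string", call. = FALSE)
  }
  if (!is.na(coverage)) check_fraction(coverage, "coverage")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  ids <- records$person_id
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("`person_id` must be unique and non-missing within a dataset",
         call. = FALSE)
  }
  for (col in names(registry_levels)) {
    vals <- records[[col]]
    bad <- !is.na(vals) & !(vals %in% registry_levels[[col]])
    if (any(bad)) {
      stop(sprintf("column `%s` contains invalid value(s): %s", col,
                   paste(unique(vals[bad]), collapse = ", ")), call. = FALSE)
    }
  }
  untreated <- records$dmt_status %in% c("never", "past")
  known <- !is.na(records$dmt_status) & !is.na(records$dmt_type)
  inconsistent <- known & (untreated != (records$dmt_type == "none"))
  if (any(inconsistent)) {
    stop("`dmt_type` must be 'none' exactly for records with `dmt_status` never/past",
         call. = FALSE)
  }
  structure(
    list(records = records, source_name = source_name,
         coverage = as.numeric(coverage)),
    class = "registry_dataset"
  )
}

#' @export
print.registry_dataset <- function(x, ...) {
  cov <- if (is.na(x$coverage)) "unknown" else sprintf("%.1f%%", 100 * x$coverage)
  cat(sprintf("Registry dataset '%s': %d records (assumed coverage %s)\n",
              x$source_name, nrow(x$records), cov))
  invisible(x)
}

#' Read a registry table from a delimited file
#'
#' Expects a comma-separated, UTF-8 file with a header row and the column
#' dictionary documented in [registry_dataset()]. An optional logical
#' `in_benchmark` column (accepted as TRUE/FALSE or 1/0) marks, in a
#' reference source, which records are also in the benchmark's covered
#' universe.
#'
#' @param path Path to the CSV file.
#' @param source_name Source name; defaults to the file name.
#' @param coverage Assumed coverage in `(0, 1]`, or `NA`.
#' @return A [registry_dataset()].
#' @export
read_registry <- function(path, source_name = NULL, coverage = NA_real_) {
  if (!file.exists(path)) {
    stop(sprintf("registry file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character"),
                        fileEncoding = "UTF-8")
  if ("in_benchmark" %in% names(df) && !is.logical(df$in_benchmark)) {
    df$in_benchmark <- as.logical(df$in_benchmark)
  }
  registry_dataset(df, source_name %||% basename(path), coverage)
}

#' Write a registry dataset to a delimited file
#'
#' @param dataset A [registry_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(dataset, path) {
  if (!inherits(dataset, "registry_dataset")) {
    stop("`dataset` must be a registry_dataset", call. = FALSE)
  }
  utils::write.csv(dataset$records, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Built-in subgroup predicates. Each takes the records data frame and returns
# a logical vector; NA marks records on which the predicate is undecidable.
subgroup_predicates <- list(
  # persons on a disease-modifying therapy within the last 12 months
  dmt_last_12mo = function(records) {
    ifelse(is.na(records$dmt_status), NA, records$dmt_status == "current-12mo")
  }
)

#' Extract a subgroup and its share of a dataset
#'
#' Applies a subgroup predicate (by built-in name or as a function of the
#' records data frame returning a logical vector) and returns the matching
#' subgroup together with the multiplier fraction: the subgroup's share of
#' the dataset. Records on which the predicate is undecidable (missing
#' fields) are excluded from both numerator and denominator and counted in
#' `n_excluded`.
#'
#' @param dataset A non-empty [registry_dataset()].
#' @param predicate Name of a built-in predicate (currently
#'   `"dmt_last_12mo"`) or a function `records -> logical`.
#' @return A list of class `subgroup_extraction`: `subgroup` (a
#'   [registry_dataset()] inheriting the source metadata), `share`
#'   (subgroup count / decidable records), `n` (decidable records) and
#'   `n_excluded`. `share * n` equals the subgroup size exactly.
#' @examples
#' pop <- generate_population(synthetic_config(true_total = 500, seed = 1))
#' extract_subgroup(pop, "dmt_last_12mo")$share
#' @export
extract_subgroup <- function(dataset, predicate = "dmt_last_12mo") {
  if (!inherits(dataset, "registry_dataset")) {
    stop("`dataset` must be a registry_dataset", call. = FALSE)
  }
  if (nrow(dataset$records) == 0L) {
    stop("cannot extract a subgroup from an empty dataset", call. = FALSE)
  }
  if (is.character(predicate)) {
    fn <- subgroup_predicates[[predicate]]
    if (is.null(fn)) {
      stop(sprintf("unknown subgroup predicate '%s'", predicate), call. = FALSE)
    }
  } else if (is.function(predicate)) {
    fn <- predicate
  } else {
    stop("`predicate` must be a predicate name or a function", call. = FALSE)
  }
  match <- fn(dataset$records)
  if (!is.logical(match) || length(match) != nrow(dataset$records)) {
    stop("predicate must return one logical per record", call. = FALSE)
  }
  n_excluded <- sum(is.na(match))
  decidable <- !is.na(match)
  n <- sum(decidable)
  if (n == 0L) {
    stop("predicate is undecidable on every record", call. = FALSE)
  }
  count <- sum(match[decidable])
  if (count == 0L) {
    warning("predicate matched zero records; the resulting share is unusable as a multiplier",
            call. = FALSE)
  }
  subgroup <- registry_dataset(
    dataset$records[decidable & match, , drop = FALSE],
    source_name = dataset$source_name,
    coverage = dataset$coverage
  )
  structure(
    list(subgroup = subgroup, share = count / n, n = n,
         n_excluded = n_excluded),
    class = "subgroup_extraction"
  )
}

#' @export
print.subgroup_extraction <- function(x, ...) {
  cat(sprintf("Subgroup: %d of %d decidable records (share %.3f, %d excluded)\n",
              nrow(x$subgroup$records), x$n, x$share, x$n_excluded))
  invisible(x)
}

cell_key <- function(records, strata_vars) {
  if (length(strata_vars) == 0L) {
    return(rep("(all)", nrow(records)))
  }
  vals <- lapply(strata_vars, function(v) {
    x <- as.character(records[[v]])
    x[is.na(x)] <- "(missing)"
    x
  })
  do.call(paste, c(vals, sep = "\r"))
}

#' Augment an under-covering benchmark with pseudo-records
#'
#' A benchmark source that captures only part of its target group (e.g. a
#' reimbursement registry serving insurers with a 65--67% market share)
#' understates the benchmark count. This routine scales the benchmark up by
#' estimated inverse coverage, per cell of a cross-classification: a
#' reference source that sees the whole target group carries a logical
#' `in_benchmark` flag marking which of its records fall inside the
#' benchmark's covered universe, so each cell's coverage is
#' `flagged / total` among reference records in that cell, and the cell's
#' benchmark count is brought up to `round(observed / coverage)` by adding
#' replicated copies of its own records (pseudo-records, marked
#' `synthetic = TRUE`).
#'
#' Replication is deterministic: within a cell, records ordered by
#' `person_id` are copied round-robin, with any remainder going to the lowest
#' ids first. Cells present in the benchmark but absent from the reference
#' fall back to the reference's global coverage with a warning; a nonempty
#' cell whose estimated coverage is zero is an error.
#'
#' @param benchmark The under-covering [registry_dataset()].
#' @param reference A [registry_dataset()] covering the benchmark's whole
#'   target group, with a logical `in_benchmark` column.
#' @param strata_vars Column names defining the coverage cells (default
#'   `c("region", "dmt_type")`); `character(0)` uses a single global cell.
#' @return An augmented [registry_dataset()] (coverage 1) whose records carry
#'   a logical `synthetic` provenance column; size is at least the input
#'   size and equals the sum of per-cell `round(observed / coverage)`.
#' @export
augment_benchmark <- function(benchmark, reference,
                              strata_vars = c("region", "dmt_type")) {
  if (!inherits(benchmark, "registry_dataset") ||
      !inherits(reference, "registry_dataset")) {
    stop("`benchmark` and `reference` must be registry_dataset objects",
         call. = FALSE)
  }
  ref <- reference$records
  if (!"in_benchmark" %in% names(ref) || !is.logical(ref$in_benchmark) ||
      anyNA(ref$in_benchmark)) {
    stop("`reference` must carry a complete logical `in_benchmark` membership flag",
         call. = FALSE)
  }
  bad_vars <- setdiff(strata_vars,
                      intersect(names(benchmark$records), names(ref)))
  if (length(bad_vars) > 0L) {
    stop(sprintf("strata variable(s) absent from both datasets' columns: %s",
                 paste(bad_vars, collapse = ", ")), call. = FALSE)
  }

  bm <- benchmark$records
  bm$synthetic <- if ("synthetic" %in% names(bm)) bm$synthetic else FALSE
  bm$synthetic[is.na(bm$synthetic)] <- FALSE

  ref_key <- cell_key(ref, strata_vars)
  cov_by_cell <- tapply(ref$in_benchmark, ref_key, mean)
  global_cov <- mean(ref$in_benchmark)
  if (global_cov == 0) {
    stop("reference implies zero coverage: no reference record is flagged as in the benchmark",
         call. = FALSE)
  }

  bm_key <- cell_key(bm, strata_vars)
  pseudo <- list()
  for (key in unique(bm_key)) {
    rows <- which(bm_key == key)
    cov <- cov_by_cell[key]
    if (is.na(cov)) {
      warning(sprintf(
        "benchmark cell '%s' has no reference records; using global coverage %.4f",
        gsub("\r", " / ", key), global_cov), call. = FALSE)
      cov <- global_cov
    }
    if (cov == 0) {
      stop(sprintf("estimated coverage is zero in nonempty benchmark cell '%s'",
                   gsub("\r", " / ", key)), call. = FALSE)
    }
    target <- round_half_up(length(rows) / cov)
    extras <- target - length(rows)
    if (extras <= 0) next
    ord <- rows[order(bm$person_id[rows])]
    k <- length(ord)
    copies <- rep(extras %/% k, k) + (seq_len(k) <= extras %% k)
    src <- rep(ord, copies)
    if (length(src) == 0L) next
    new <- bm[src, , drop = FALSE]
    new$person_id <- paste0(new$person_id, "-s", sequence(copies[copies > 0]))
    new$synthetic <- TRUE
    pseudo[[key]] <- new
  }

  out <- rbind(bm, do.call(rbind, unname(pseudo)))
  rownames(out) <- NULL
  registry_dataset(out, paste0(benchmark$source_name, " (augmented)"),
                   coverage = 1)
}

numeric_registry_vars <- c("age_years", "disease_duration_years")

#' Compare two registry datasets over named variables
#'
#' Produces the descriptive side-by-side review used when assessing candidate
#' data sources: for each categorical variable, the category proportions in
#' both datasets (over non-missing values) and their absolute difference; for
#' each numeric variable, the median and interquartile range in each dataset
#' (linear-interpolation quartiles). Missing-value counts are reported per
#' variable.
#'
#' @param a,b [registry_dataset()] objects.
#' @param variables Character vector of column names present in both.
#' @return An object of class `comparison_report`; see
#'   [as.data.frame.comparison_report()] for a tabular rendering and
#'   [render_comparison()] for a human-readable one.
#' @export
compare_datasets <- function(a, b, variables) {
  if (!inherits(a, "registry_dataset") || !inherits(b, "registry_dataset")) {
    stop("`a` and `b` must be registry_dataset objects", call. = FALSE)
  }
  if (length(variables) == 0L) {
    stop("`variables` must name at least one column", call. = FALSE)
  }
  for (v in variables) {
    if (!v %in% names(a$records) || !v %in% names(b$records)) {
      stop(sprintf("variable '%s' is absent from at least one dataset", v),
           call. = FALSE)
    }
  }
  entries <- lapply(variables, function(v) {
    xa <- a$records[[v]]
    xb <- b$records[[v]]
    miss <- c(a = sum(is.na(xa)), b = sum(is.na(xb)))
    xa <- xa[!is.na(xa)]
    xb <- xb[!is.na(xb)]
    if (v %in% numeric_registry_vars || (is.numeric(xa) && is.numeric(xb))) {
      qa <- stats::quantile(xa, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      qb <- stats::quantile(xb, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      list(type = "numeric",
           a = c(q1 = qa[1], median = qa[2], q3 = qa[3]),
           b = c(q1 = qb[1], median = qb[2], q3 = qb[3]),
           n_missing = miss)
    } else {
      levels <- sort(unique(c(as.character(xa), as.character(xb))))
      pa <- as.numeric(table(factor(xa, levels = levels))) / length(xa)
      pb <- as.numeric(table(factor(xb, levels = levels))) / length(xb)
      list(type = "categorical", levels = levels,
           prop_a = stats::setNames(pa, levels),
           prop_b = stats::setNames(pb, levels),
           abs_diff = stats::setNames(abs(pa - pb), levels),
           n_missing = miss)
    }
  })
  structure(
    list(dataset_a = a$source_name, dataset_b = b$source_name,
         variables = stats::setNames(entries, variables)),
    class = "comparison_report"
  )
}

#' Flatten a comparison report to a long data frame
#'
#' One row per category (categorical variables) or per summary statistic
#' (numeric variables), with the two datasets' values and, for categories,
#' the absolute difference in proportions.
#'
#' @param x A `comparison_report`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data frame with columns `variable`, `item`, `value_a`,
#'   `value_b`, `abs_diff`.
#' @export
as.data.frame.comparison_report <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  rows <- lapply(names(x$variables), function(v) {
    e <- x$variables[[v]]
    if (e$type == "categorical") {
      data.frame(variable = v, item = e$levels,
                 value_a = as.numeric(e$prop_a),
                 value_b = as.numeric(e$prop_b),
                 abs_diff = as.numeric(e$abs_diff))
    } else {
      items <- c("q1", "median", "q3")
      data.frame(variable = v, item = items,
                 value_a = as.numeric(e$a[items]),
                 value_b = as.numeric(e$b[items]),
                 abs_diff = abs(as.numeric(e$a[items]) - as.numeric(e$b[items])))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(paste(render_comparison(x), collapse = "\n"), "\n")
  invisible(x)
}
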