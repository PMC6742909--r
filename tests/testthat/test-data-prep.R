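test_that("registry datasets enforce their record invariants", {
  ok <- make_registry(5)
  expect_s3_class(ok, "registry_dataset")

  dup <- ok$records
  dup$person_id[2] <- dup$person_id[1]
  expect_error(registry_dataset(dup, "dup"), "unique")

  bad_level <- ok$records
  bad_level$sex[1] <- "f"
  expect_error(registry_dataset(bad_level, "bad"), "invalid value")

  inconsistent <- ok$records
  inconsistent$dmt_status[1] <- "never"  # dmt_type stays "oral"
  expect_error(registry_dataset(inconsistent, "bad"), "dmt_type")

  expect_error(registry_dataset(ok$records, "x", coverage = 1.5), "coverage")
})

test_that("registry tables round-trip through CSV including membership flags", {
  ref <- make_reference(20, flagged = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(ref, path)
  back <- read_registry(path, "reference", coverage = 1)
  expect_equal(back$records$person_id, ref$records$person_id)
  expect_identical(back$records$in_benchmark, ref$records$in_benchmark)
  expect_error(read_registry(file.path(tempdir(), "no-such-file.csv")),
               "no-such-file")
})

test_that("subgroup extraction computes the share over decidable records", {
  # 6 of 16 records on current treatment, counted by hand
  ds <- make_registry(16, dmt_current = rep(c(TRUE, FALSE), c(6, 10)))
  ex <- extract_subgroup(ds, "dmt_last_12mo")
  expect_equal(ex$share, 0.375)
  expect_identical(ex$n, 16L)
  expect_identical(nrow(ex$subgroup$records), 6L)
  expect_equal(ex$share * ex$n, nrow(ex$subgroup$records))

  all_match <- extract_subgroup(make_registry(8, dmt_current = TRUE))
  expect_equal(all_match$share, 1.0)

  none <- make_registry(4, dmt_current = FALSE)
  expect_warning(extract_subgroup(none), "zero records")
  expect_error(extract_subgroup(make_registry(0)), "empty")
})

test_that("a multiplier-registry-scale fixture reproduces the printed share", {
  smsr <- make_registry(1567, dmt_current = rep(c(TRUE, FALSE), c(973, 594)),
                        source_name = "multiplier fixture")
  ex <- extract_subgroup(smsr)
  expect_equal(round(ex$share, 3), 0.621)
  expect_identical(ex$n, 1567L)
})

test_that("records with missing predicate fields are excluded and tallied", {
  ds <- make_registry(10, dmt_current = rep(c(TRUE, FALSE), c(4, 6)))
  ds$records$dmt_status[9:10] <- NA
  ds$records$dmt_type[9:10] <- NA
  ds <- registry_dataset(ds$records, "with-missing")
  ex <- extract_subgroup(ds)
  expect_identical(ex$n_excluded, 2L)
  expect_identical(ex$n, 8L)
  expect_equal(ex$share, 4 / 8)
  expect_equal(ex$share * ex$n, nrow(ex$subgroup$records))
})

test_that("augmentation replicates records by inverse per-cell coverage", {
  # full coverage: output identical to input
  bm <- make_registry(10, id_prefix = "B")
  ref <- make_reference(10, flagged = 10)
  out <- augment_benchmark(bm, ref, strata_vars = character(0))
  expect_identical(nrow(out$records), 10L)
  expect_true(all(!out$records$synthetic))

  # single cell at the published scale: 6,057 observed, implied coverage
  # 6,057/9,503 -> exactly 9,503 records after augmentation
  bm_big <- make_registry(6057, id_prefix = "B")
  ref_big <- make_reference(9503, flagged = 6057)
  aug <- augment_benchmark(bm_big, ref_big, strata_vars = character(0))
  expect_identical(nrow(aug$records), 9503L)
  expect_identical(sum(!aug$records$synthetic), 6057L)
  expect_false(anyDuplicated(aug$records$person_id) > 0)
  expect_equal(aug$coverage, 1)

  # two cells with coverages 0.5 and 1.0 and 10 records each: 10/0.5 + 10/1
  bm2 <- make_registry(20, region = rep(c("Zurich", "Ticino"), each = 10),
                       id_prefix = "B")
  ref2 <- make_registry(30, region = rep(c("Zurich", "Ticino"), c(20, 10)),
                        source_name = "reference", id_prefix = "R")
  ref2$records$in_benchmark <- c(rep(c(TRUE, FALSE), each = 10), rep(TRUE, 10))
  out2 <- augment_benchmark(bm2, ref2, strata_vars = "region")
  expect_identical(nrow(out2$records), 30L)
  counts <- table(out2$records$region)
  expect_identical(as.integer(counts[["Zurich"]]), 20L)
  expect_identical(as.integer(counts[["Ticino"]]), 10L)
})

test_that("augmentation is idempotent once coverage is 1 and conserves cell targets", {
  bm <- make_registry(120, region = rep(c("Zurich", "Ticino", "Midlands"),
                                        c(60, 40, 20)), id_prefix = "B")
  ref <- make_registry(200, region = rep(c("Zurich", "Ticino", "Midlands"),
                                         c(100, 60, 40)),
                       source_name = "reference", id_prefix = "R")
  ref$records$in_benchmark <- c(rep(c(TRUE, FALSE), c(60, 40)),
                                rep(c(TRUE, FALSE), c(40, 20)),
                                rep(c(TRUE, FALSE), c(20, 20)))
  aug <- augment_benchmark(bm, ref, strata_vars = "region")
  # per-cell conservation: round(observed / coverage) summed over cells
  expect_identical(nrow(aug$records),
                   as.integer(round(60 / 0.6) + round(40 / (40 / 60)) +
                                round(20 / 0.5)))

  # re-augmenting its own output with coverage recomputed there is a no-op
  ref2 <- aug
  ref2$records$in_benchmark <- TRUE
  again <- augment_benchmark(aug, ref2, strata_vars = "region")
  expect_identical(nrow(again$records), nrow(aug$records))
  expect_identical(sum(again$records$synthetic), sum(aug$records$synthetic))
})

test_that("augmentation falls back to global coverage and rejects zero coverage", {
  bm <- make_registry(12, region = rep(c("Zurich", "Ticino"), c(10, 2)),
                      id_prefix = "B")
  ref <- make_reference(20, flagged = 10, region = "Zurich")
  expect_warning(out <- augment_benchmark(bm, ref, strata_vars = "region"),
                 "global coverage")
  # Ticino cell used global coverage 0.5: 2 -> 4; Zurich 10 -> 20
  expect_identical(nrow(out$records), 24L)

  ref_zero <- make_reference(20, flagged = 0)
  expect_error(augment_benchmark(bm, ref_zero, strata_vars = character(0)),
               "zero coverage")
  expect_error(augment_benchmark(bm, make_registry(5), "region"),
               "in_benchmark")
})

test_that("dataset comparison aligns proportions, differences and quartiles", {
  a <- make_registry(1000, sex = rep(c("female", "male"), c(780, 220)),
                     source_name = "A")
  b <- make_registry(1000, sex = rep(c("female", "male"), c(713, 287)),
                     source_name = "B", id_prefix = "G")
  rep_ab <- compare_datasets(a, b, "sex")
  e <- rep_ab$variables$sex
  expect_equal(sum(e$prop_a), 1, tolerance = 1e-9)
  expect_equal(sum(e$prop_b), 1, tolerance = 1e-9)
  expect_equal(unname(e$abs_diff[["female"]]), 0.067, tolerance = 1e-12)

  # identical datasets: all differences vanish
  same <- compare_datasets(a, a, c("sex", "age_years"))
  expect_true(all(as.data.frame(same)$abs_diff == 0))

  # numeric summary pins the linear-interpolation quartile convention
  num <- make_registry(5, duration = c(1, 2, 3, 4, 100))
  rep_n <- compare_datasets(num, num, "disease_duration_years")
  expect_equal(unname(rep_n$variables$disease_duration_years$a),
               c(2, 3, 4))

  # symmetric up to the sign of differences
  ab <- as.data.frame(compare_datasets(a, b, "sex"))
  ba <- as.data.frame(compare_datasets(b, a, "sex"))
  expect_equal(ab$abs_diff, ba$abs_diff)
  expect_equal(ab$value_a, ba$value_b)

  expect_error(compare_datasets(a, b, "edss"), "edss")
})
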