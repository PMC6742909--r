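# Programmatic fixtures: small registry datasets built in code.

make_registry <- function(n, source_name = "fixture", coverage = NA_real_,
                          sex = "female", age = 40L, region = "Zurich",
                          disease_type = "RRMS", dmt_current = TRUE,
                          duration = 8, id_prefix = "F") {
  dmt_current <- rep_len(dmt_current, n)
  records <- data.frame(
    person_id = sprintf("%s%05d", id_prefix, seq_len(n)),
    sex = rep_len(sex, n),
    age_years = as.integer(rep_len(age, n)),
    region = rep_len(region, n),
    disease_type = rep_len(disease_type, n),
    dmt_status = ifelse(dmt_current, "current-12mo", "never"),
    dmt_type = ifelse(dmt_current, "oral", "none"),
    disease_duration_years = rep_len(duration, n),
    stringsAsFactors = FALSE
  )
  registry_dataset(records, source_name, coverage)
}

# A reference dataset marking `flagged` of its records as in the benchmark.
make_reference <- function(n, flagged, ...) {
  ref <- make_registry(n, source_name = "reference", ...)
  ref$records$in_benchmark <- seq_len(n) <= flagged
  ref
}
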