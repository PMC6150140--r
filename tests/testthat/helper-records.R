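# In-code fixtures: tiny admission tables built to order.

# n blank admissions: register fields filled, every documentation cell absent
blank_records <- function(n, version = "revised2014",
                          adm = as.Date("2015-03-01")) {
  dict <- nar_dictionary()
  rec <- tibble::tibble(
    record_id = sprintf("T%03d", seq_len(n)),
    adm_date = rep(as.Date(adm), length.out = n),
    dob = rep(as.Date(adm), length.out = n),
    disch_date = rep(as.Date(adm), length.out = n) + 3,
    vital_status = "alive",
    sex = "female",
    weight_kg = 3.0,
    gest_weeks = 38,
    diagnoses = "prematurity",
    schema_version = rep(version, length.out = n),
    full_dataset = TRUE
  )
  for (v in dict$name) rec[[v]] <- NA_character_
  rec
}

# set one documentation cell
set_doc <- function(records, row, variable, value) {
  records[[variable]][row] <- value
  records
}

# random small cohort for property tests: each applicable cell documented
# independently with probability p (value "x"), on a mix of form versions
random_small_cohort <- function(n, p = 0.5, mixed_versions = TRUE) {
  versions <- if (mixed_versions) {
    sample(nar_versions(), n, replace = TRUE)
  } else {
    rep("revised2014", n)
  }
  rec <- blank_records(n)
  rec$schema_version <- versions
  rec$adm_date <- as.Date("2013-02-01") +
    ifelse(versions == "baseline", 0, 600)
  rec$dob <- rec$adm_date
  rec$disch_date <- rec$adm_date + 2
  dict <- nar_dictionary()
  for (i in seq_len(nrow(dict))) {
    v <- dict$name[i]
    applicable <- dict$introduced_in[i] == "baseline" |
      versions == "revised2014"
    doc <- applicable & stats::runif(n) < p
    rec[[v]][doc] <- "x"
  }
  rec
}

# brute-force pooled completeness: explicit double loop over records and
# domain variables, the oracle for domain_completeness
brute_force_domain <- function(records, domain, schema) {
  vars <- schema$dictionary[schema$dictionary$domain == domain, ]
  x <- 0L
  n <- 0L
  for (i in seq_len(nrow(records))) {
    for (j in seq_len(nrow(vars))) {
      if (vars$introduced_in[j] == "revised2014" &&
          records$schema_version[i] == "baseline") {
        next
      }
      n <- n + 1L
      val <- records[[vars$name[j]]][i]
      if (!is.na(val) && trimws(val) != "") x <- x + 1L
    }
  }
  c(x = x, n = n)
}
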