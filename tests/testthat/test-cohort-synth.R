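# Cohort sizes here are scaled down from the acceptance-suite settings to
# keep the unit run fast; the criterion-level recovery checks live in
# test-acceptance.R.

small_params <- function(...) {
  cohort_params(start_date = "2014-06-01", end_date = "2015-05-31",
                admissions_per_month = 80, ...)
}

test_that("identical seed and parameters reproduce the cohort exactly", {
  a <- simulate_cohort(small_params(seed = 101))
  b <- simulate_cohort(small_params(seed = 101))
  expect_identical(a$records, b$records)
  expect_identical(a$prescriptions, b$prescriptions)
  c3 <- simulate_cohort(small_params(seed = 102))
  expect_false(identical(a$records, c3$records))
})

test_that("degenerate documentation probabilities are honoured", {
  dp <- tibble::tibble(variable = c("temperature", "stridor"),
                       p_start = c(1, 0), p_end = c(1, 0))
  co <- simulate_cohort(small_params(doc_prob = dp, seed = 5))
  s <- load_schema("revised2014")
  expect_true(all(doc_indicator(co$records, "temperature", s) == 1L))
  ind <- doc_indicator(co$records, "stridor", s)
  expect_true(all(ind[!is.na(ind)] == 0L))
})

test_that("parameter validation rejects impossible worlds", {
  expect_error(cohort_params(sepsis_prevalence = 1.2), "probabilities")
  expect_error(cohort_params(start_date = "2015-01-01",
                             end_date = "2014-01-01"), "date span")
  expect_error(cohort_params(weight_bounds = c(2, 1)), "weight bounds")
  expect_error(cohort_params(dose_error = list(overdose_rate = 0.6,
                                               underdose_rate = 0.5,
                                               magnitude_sdlog = 0.2)),
               "< 1")
  expect_error(cohort_params(doc_prob = tibble::tibble(
    variable = "nope", p_start = 0.5, p_end = 0.5)), "unknown variables")
})

test_that("form version partitions records at the revision date", {
  co <- simulate_cohort(cohort_params(start_date = "2013-10-01",
                                      end_date = "2014-09-30",
                                      admissions_per_month = 60, seed = 7))
  rec <- co$records
  expect_true(all(rec$schema_version[rec$adm_date < as.Date("2014-04-01")] ==
                    "baseline"))
  expect_true(all(rec$schema_version[rec$adm_date >= as.Date("2014-04-01")] ==
                    "revised2014"))
  # revision-era variables are never documented on baseline forms
  s <- load_schema("revised2014")
  old <- rec[rec$schema_version == "baseline", ]
  expect_true(all(is.na(old$stridor)))
})

test_that("cohorts round-trip through CSV losslessly", {
  co <- simulate_cohort(small_params(seed = 31))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$records, co$records)
  expect_equal(back$prescriptions, co$prescriptions)
})

test_that("an empty cohort writes and reads as header-only files", {
  co <- simulate_cohort(cohort_params(admissions_per_month = 0, seed = 1))
  expect_identical(nrow(co$records), 0L)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_identical(length(readLines(file.path(dir, "records.csv"))), 1L)
  back <- read_cohort(dir)
  expect_identical(nrow(back$records), 0L)
  expect_identical(names(back$records), names(co$records))
})

test_that("marginal rates are recovered at moderate n", {
  co <- simulate_cohort(cohort_params(start_date = "2014-06-01",
                                      end_date = "2015-05-31",
                                      admissions_per_month = 420, seed = 43))
  rec <- co$records
  n <- nrow(rec)
  expect_gt(n, 4000)
  # full-data flag within 3 binomial standard errors of 0.6
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(mean(rec$full_dataset) - 0.6), 3 * se)
  # sepsis prevalence inside its own Wilson 95% interval around 0.167
  x <- sum(grepl("neonatal sepsis", rec$diagnoses, fixed = TRUE))
  ci <- wilson_interval(x, n)
  expect_true(ci$ci_low <= 0.167 && 0.167 <= ci$ci_high)
  # birth weight mean within 3 sd/sqrt(n) of 2.88 (truncation shift is
  # negligible with bounds 4 sd out)
  expect_lt(abs(mean(rec$weight_kg) - 2.88), 3 * 0.6 / sqrt(n))
})

test_that("dose-error rates are planted exactly outside/inside the margin", {
  co <- simulate_cohort(cohort_params(
    start_date = "2014-06-01", end_date = "2015-05-31",
    admissions_per_month = 300,
    dose_error = list(overdose_rate = 0.4, underdose_rate = 0.1,
                      magnitude_sdlog = 0.25),
    seed = 47
  ))
  aud <- audit_prescriptions(co$prescriptions)
  assessable <- aud[aud$class != "unassessable", ]
  k <- nrow(assessable)
  expect_gt(k, 800)
  # accuracy ~ 50%: planted rate within the Wilson 99% interval
  x <- sum(assessable$class == "correct")
  ci <- wilson_interval(x, k, conf_level = 0.99)
  expect_true(ci$ci_low <= 0.5 && 0.5 <= ci$ci_high)
  xo <- sum(assessable$class == "overdose")
  cio <- wilson_interval(xo, k, conf_level = 0.99)
  expect_true(cio$ci_low <= 0.4 && 0.4 <= cio$ci_high)
})

test_that("marginals stay inside Wilson 99% intervals across seeds", {
  # scaled-down version of the many-seed recovery property: 30 seeds,
  # ~1000 records each, 4 marginals; expect >= 95% of checks to pass
  params <- cohort_params(start_date = "2014-06-01", end_date = "2015-05-31",
                          admissions_per_month = 85)
  hits <- 0L
  total <- 0L
  for (seed in 1:30) {
    co <- simulate_cohort(params, seed = seed)
    rec <- co$records
    n <- nrow(rec)
    checks <- c(
      sepsis = sum(grepl("neonatal sepsis", rec$diagnoses, fixed = TRUE)),
      mortality = sum(rec$vital_status == "dead"),
      full = sum(rec$full_dataset),
      female = sum(rec$sex == "female")
    )
    target <- c(0.167, 0.09, 0.6, 0.46)
    ci <- wilson_interval(unname(checks), n, conf_level = 0.99)
    hits <- hits + sum(ci$ci_low <= target & target <= ci$ci_high)
    total <- total + 4L
  }
  expect_gte(hits / total, 0.95)
})
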