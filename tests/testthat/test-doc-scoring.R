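test_that("doc indicator is 1/0/NA by presence and form version", {
  s <- load_schema("revised2014")
  rec <- blank_records(2)
  rec <- set_doc(rec, 1, "temperature", "36.8")
  rec <- set_doc(rec, 2, "temperature", "   ")   # whitespace is not documented
  expect_identical(doc_indicator(rec, "temperature", s), c(1L, 0L))

  # a 2014-revision variable queried on a baseline-version record
  old <- blank_records(1, version = "baseline", adm = as.Date("2013-05-01"))
  expect_identical(doc_indicator(old, "stridor", s), NA_integer_)
  expect_identical(doc_indicator(old, "temperature", s), 0L)
  expect_error(doc_indicator(rec, "no_such_variable", s), "unknown variable")
})

test_that("pooled domain completeness counts documented slots", {
  s <- load_schema("revised2014")
  # 2 records x 4 vital-sign variables = 8 slots; document 6
  rec <- blank_records(2)
  for (v in c("temperature", "respiratory_rate", "heart_rate")) {
    rec <- set_doc(rec, 1, v, "50")
    rec <- set_doc(rec, 2, v, "50")
  }
  expect_equal(
    domain_completeness(rec, "vital signs", s)[, c("x", "n", "point")],
    tibble::tibble(x = 6L, n = 8L, point = 0.75),
    ignore_attr = TRUE
  )
  rec2 <- set_doc(set_doc(rec, 1, "oxygen_saturation", "95"),
                  2, "oxygen_saturation", "95")
  expect_equal(domain_completeness(rec2, "vital signs", s)$point, 1)
})

test_that("mixed-version denominators exclude not-applicable slots", {
  s <- load_schema("revised2014")
  old <- blank_records(1, version = "baseline", adm = as.Date("2013-05-01"))
  new <- blank_records(1)
  rec <- dplyr::bind_rows(old, new)
  # other physical examination: 18 variables, 7 added in 2014 -> 11 + 18
  got <- domain_completeness(rec, "other physical examination", s)
  expect_identical(got$n, 29L)
  # an all-baseline cohort has no applicable maternal-history slots
  expect_error(domain_completeness(old, "maternal history", s),
               "no applicable slots")
})

test_that("per-patient completeness is documented over applicable", {
  s <- load_schema("revised2014")
  rec <- blank_records(1)
  expect_equal(patient_completeness(rec, s)$fraction, 0)
  all_doc <- rec
  for (v in nar_dictionary()$name) all_doc <- set_doc(all_doc, 1, v, "x")
  pc <- patient_completeness(all_doc, s)
  expect_equal(pc$fraction, 1)
  expect_identical(pc$applicable, 50L)
  half <- rec
  for (v in nar_dictionary()$name[1:25]) half <- set_doc(half, 1, v, "x")
  expect_equal(patient_completeness(half, s)$fraction, 0.5)
  # baseline records are scored out of their own 36 variables
  old <- blank_records(1, version = "baseline", adm = as.Date("2013-05-01"))
  expect_identical(patient_completeness(old, s)$applicable, 36L)
})

test_that("stratification thresholds and boundaries", {
  s <- load_schema("revised2014")
  # 10, 25, 30, 50 and 51 of 100 records documented
  for (case in list(c(10, "very_poor"), c(25, "poor"), c(30, "poor"),
                    c(50, "poor"), c(51, "adequate"))) {
    k <- as.integer(case[1])
    rec <- blank_records(100)
    for (i in seq_len(k)) rec <- set_doc(rec, i, "temperature", "37")
    got <- stratify_variable(rec, "temperature", s)
    expect_identical(as.character(got$stratum), case[2])
    expect_equal(got$documented_fraction, k / 100)
  }
  # strata partition [0, 1]: every fraction gets exactly one stratum
  fr <- seq(0, 1, by = 0.01)
  strata <- naraudit:::stratum_of(fr)
  expect_true(all(strata %in% c("very_poor", "poor", "adequate")))
  expect_identical(naraudit:::stratum_of(0.25), "poor")
  expect_identical(naraudit:::stratum_of(0.50), "poor")
  expect_identical(naraudit:::stratum_of(0.2499), "very_poor")
  expect_identical(naraudit:::stratum_of(0.5001), "adequate")
})

test_that("stratifying a variable with no applicable records errors", {
  s <- load_schema("revised2014")
  old <- blank_records(2, version = "baseline", adm = as.Date("2013-05-01"))
  expect_error(stratify_variable(old, "stridor", s), "no applicable records")
  expect_warning(strata <- stratify_variables(old, s), "dropped")
  expect_false("stridor" %in% strata$variable)
})

test_that("filling in one absent value never decreases completeness", {
  s <- load_schema("revised2014")
  withr::local_seed(11)
  for (rep in 1:5) {
    rec <- random_small_cohort(n = sample(5:30, 1), p = 0.4)
    comp0 <- purrr::map_dbl(nar_domains()[-1], function(d) {
      domain_completeness(rec, d, s)$point
    })
    pat0 <- patient_completeness(rec, s)$fraction
    # pick one absent applicable cell and fill it
    dict <- nar_dictionary()
    repeat {
      i <- sample(nrow(rec), 1)
      v <- sample(dict$name, 1)
      applicable <- dict$introduced_in[dict$name == v] == "baseline" ||
        rec$schema_version[i] == "revised2014"
      if (applicable && is.na(rec[[v]][i])) break
    }
    rec2 <- set_doc(rec, i, v, "now documented")
    comp1 <- purrr::map_dbl(nar_domains()[-1], function(d) {
      domain_completeness(rec2, d, s)$point
    })
    pat1 <- patient_completeness(rec2, s)$fraction
    expect_true(all(comp1 >= comp0 - 1e-12))
    expect_true(all(pat1 >= pat0 - 1e-12))
    expect_true(sum(comp1) > sum(comp0))   # exactly one domain moved up
  }
})

test_that("pooled counts equal the brute-force double loop", {
  s <- load_schema("revised2014")
  withr::local_seed(13)
  for (rep in 1:5) {
    rec <- random_small_cohort(n = sample(10:50, 1), p = runif(1, 0.2, 0.9))
    for (d in nar_domains()) {
      oracle <- brute_force_domain(rec, d, s)
      if (oracle["n"] == 0) {
        expect_error(domain_completeness(rec, d, s), "no applicable slots")
      } else {
        got <- domain_completeness(rec, d, s)
        expect_identical(got$x, unname(oracle["x"]))
        expect_identical(got$n, unname(oracle["n"]))
      }
    }
  }
})

test_that("completeness recovers a constant generating probability", {
  s <- load_schema("revised2014")
  withr::local_seed(17)
  p <- 0.65
  rec <- random_small_cohort(300, p = p, mixed_versions = FALSE)
  # 300 records x 4 vital-sign slots = 1200 slots
  got <- domain_completeness(rec, "vital signs", s,
                             period_config(conf_level = 0.95))
  ci <- wilson_interval(got$x, got$n, conf_level = 0.95)
  expect_gt(got$n, 1000)
  expect_true(ci$ci_low <= p && p <= ci$ci_high)
})

test_that("completeness table fills every populated domain-period cell", {
  s <- load_schema("revised2014")
  cfg <- period_config()
  withr::local_seed(19)
  rec <- random_small_cohort(40)
  tab <- completeness_table(rec, s, cfg)
  expect_setequal(unique(tab$domain), nar_domains())
  # maternal history has no applicable slots in the baseline periods
  mh <- tab[tab$domain == "maternal history" & tab$phase == "pre_AF", ]
  expect_true(all(mh$n == 0))
  expect_true(all(is.na(mh$point)))
  filled <- tab[tab$n > 0, ]
  expect_true(all(filled$ci_low <= filled$point &
                    filled$point <= filled$ci_high))
  # patient-mean variant stays in [0, 1] and runs on the same input
  tab2 <- completeness_table(rec, s, cfg, method = "patient_mean")
  expect_true(all(tab2$point[tab2$n > 0] >= 0 & tab2$point[tab2$n > 0] <= 1))
})
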