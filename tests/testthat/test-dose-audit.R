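test_that("guideline dose follows the weight bands", {
  expect_equal(expected_dose(1.5, 3), 4.5)    # 3 mg/kg below 2 kg
  expect_equal(expected_dose(2.0, 3), 10.0)   # boundary belongs to >= 2 kg
  expect_equal(expected_dose(2.5, 3), 12.5)   # 5 mg/kg at or above 2 kg
  expect_equal(expected_dose(c(0.8, 1.99, 2.01), 0),
               c(2.4, 5.97, 10.05))
})

test_that("outside the age window or without a weight the dose is unassessable", {
  expect_true(is.na(expected_dose(2.5, 10)))
  expect_true(is.na(expected_dose(2.5, -1)))
  expect_true(is.na(expected_dose(NA, 3)))
  expect_true(is.na(expected_dose(0, 3)))
  cls <- classify_dose(10, 2.5, 10)
  expect_identical(as.character(cls$class), "unassessable")
  expect_identical(cls$reason, "age outside rule window")
  cls2 <- classify_dose(10, NA, 3)
  expect_identical(cls2$reason, "missing or non-positive weight")
  # a widened window makes the same prescription assessable
  wide <- dose_rule(age_window_days = c(0, 28))
  expect_equal(expected_dose(2.5, 10, wide), 12.5)
})

test_that("classification against the 20% margin", {
  # exact guideline dose
  a <- classify_dose(4.5, 1.5, 3)
  expect_identical(as.character(a$class), "correct")
  expect_equal(a$ratio, 1)
  # 6.0 / 4.5 = 1.333 > 1.2
  b <- classify_dose(6.0, 1.5, 3)
  expect_identical(as.character(b$class), "overdose")
  expect_equal(b$ratio, 6 / 4.5)
  # 7.9 / 10.0 = 0.79 < 0.8
  c3 <- classify_dose(7.9, 2.0, 3)
  expect_identical(as.character(c3$class), "underdose")
  expect_equal(c3$ratio, 0.79)
  # margin boundaries are inclusive: exactly +/-20% is correct
  expect_identical(as.character(classify_dose(4.5 * 1.2, 1.5, 3)$class),
                   "correct")
  expect_identical(as.character(classify_dose(4.5 * 0.8, 1.5, 3)$class),
                   "correct")
})

test_that("classifier equals the absolute-interval oracle on random draws", {
  withr::local_seed(23)
  n <- 20000
  weight <- round(runif(n, 0.3, 6), 3)
  age <- sample(0:14, n, replace = TRUE)
  dose <- round(runif(n, 0.5, 40), 2)
  got <- classify_dose(dose, weight, age)
  oracle <- character(n)
  for (i in seq_len(n)) {
    if (weight[i] <= 0 || age[i] > 7) {
      oracle[i] <- "unassessable"
    } else {
      exp_mg <- if (weight[i] < 2) 3 * weight[i] else 5 * weight[i]
      lo <- 0.8 * exp_mg
      hi <- 1.2 * exp_mg
      oracle[i] <- if (dose[i] < lo) "underdose"
      else if (dose[i] > hi) "overdose" else "correct"
    }
  }
  expect_identical(as.character(got$class), oracle)
})

test_that("classes partition prescriptions and respect scale and margin", {
  withr::local_seed(29)
  n <- 2000
  weight <- runif(n, 0.5, 5.5)
  age <- sample(0:10, n, replace = TRUE)
  dose <- runif(n, 1, 30)
  got <- classify_dose(dose, weight, age)
  expect_identical(sum(table(got$class)), as.integer(n))
  # scale equivariance: doubling dose and expected (via dose_per_kg) together
  rule2 <- dose_rule(bands = tibble::tibble(weight_min = c(0, 2),
                                            weight_max = c(2, Inf),
                                            dose_per_kg = c(6, 10)))
  got2 <- classify_dose(2 * dose, weight, age, rule2)
  expect_identical(as.character(got$class), as.character(got2$class))
  # widening the margin never shrinks the correct set
  wider <- dose_rule(margin = 0.3)
  got3 <- classify_dose(dose, weight, age, wider)
  was_correct <- got$class == "correct"
  expect_true(all(got3$class[was_correct] == "correct"))
})

test_that("dose rule construction validates its geometry", {
  expect_error(dose_rule(margin = 0), "margin")
  expect_error(dose_rule(margin = 1.2), "margin")
  expect_error(dose_rule(bands = tibble::tibble(weight_min = c(0, 3),
                                                weight_max = c(2, Inf),
                                                dose_per_kg = c(3, 5))),
               "tile")
})

test_that("accuracy series: all-guideline cohort scores 100%, empty periods n=0", {
  cfg <- period_config()
  k <- 40
  dates <- seq(as.Date("2013-02-01"), by = "90 days", length.out = k)
  dates <- dates[dates <= cfg$study_end]
  k <- length(dates)
  weight <- rep(c(1.5, 2.5), length.out = k)
  pres <- tibble::tibble(
    prescription_id = sprintf("P%02d", 1:k),
    record_id = sprintf("R%02d", 1:k),
    date = dates, dose_mg = expected_dose(weight, 3),
    weight_kg = weight, age_days = 3
  )
  ser <- dose_accuracy_series(audit_prescriptions(pres), cfg)
  expect_true(all(ser$point[ser$n > 0] == 1))
  expect_true(all(ser$ci_high[ser$n > 0] == 1))
  # a band-period with no assessable prescriptions reports n = 0, no estimate
  one <- pres[1, ]   # 2013-P1, under 2 kg only
  ser1 <- dose_accuracy_series(audit_prescriptions(one), cfg)
  empty <- ser1[ser1$band == "at_least_2kg" | ser1$period != "2013-P1", ]
  expect_true(all(empty$n == 0))
  expect_true(all(is.na(empty$point)))
  # unassessable prescriptions are excluded from the denominator
  late <- pres[1:2, ]
  late$age_days <- c(3, 12)
  late$date <- as.Date(c("2013-02-01", "2013-02-02"))
  ser2 <- dose_accuracy_series(audit_prescriptions(late), cfg)
  expect_identical(sum(ser2$n), 1L)
})
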