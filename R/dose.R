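# Weight-banded gentamicin dosing-correctness audit.

#' Weight-banded dosing rule
#'
#' A once-daily, weight-banded dose rule with a relative correctness margin.
#' The default is the national gentamicin guideline for newborns: 3 mg/kg
#' for babies under 2 kg and 5 mg/kg for those at or above 2 kg (the band
#' boundary belongs to the upper band), once daily, in the first 7 days of
#' life, with a correct dose defined as within +/-20% of the guideline dose.
#'
#' @param drug Drug name.
#' @param bands Tibble with `weight_min` (inclusive), `weight_max`
#'   (exclusive) and `dose_per_kg` (mg/kg); bands must tile the positive
#'   weights without gap or overlap.
#' @param frequency Dosing frequency label (audited as a separate boolean
#'   check, not folded into dose correctness).
#' @param age_window_days Two-element inclusive window of postnatal ages (in
#'   days) the rule covers; prescriptions outside it are unassessable, not
#'   judged. Extend the upper bound to audit beyond the first week.
#' @param margin Relative correctness margin m, 0 < m < 1; default 0.20.
#' @return A list of class `dose_rule`.
#' @export
dose_rule <- function(drug = "gentamicin",
                      bands = tibble::tibble(
                        weight_min = c(0, 2),
                        weight_max = c(2, Inf),
                        dose_per_kg = c(3, 5)
                      ),
                      frequency = "once daily",
                      age_window_days = c(0, 7),
                      margin = 0.20) {
  bands <- dplyr::arrange(tibble::as_tibble(bands), .data$weight_min)
  if (any(bands$dose_per_kg <= 0)) rlang::abort("dose_per_kg must be > 0")
  if (margin <= 0 || margin >= 1) rlang::abort("margin must be in (0, 1)")
  if (bands$weight_min[1] != 0 || !is.infinite(bands$weight_max[nrow(bands)]) ||
      (nrow(bands) > 1 &&
       any(bands$weight_min[-1] != bands$weight_max[-nrow(bands)]))) {
    rlang::abort("bands must tile (0, Inf) without gap or overlap")
  }
  structure(
    list(drug = drug, bands = bands, frequency = frequency,
         age_window_days = age_window_days, margin = margin),
    class = "dose_rule"
  )
}

#' Guideline dose for a given weight and age
#'
#' Looks up the weight band and returns the expected total dose in mg
#' (dose_per_kg x weight). Weight at or above a band boundary falls in the
#' upper band, so 2.0 kg gets 5 mg/kg under the default gentamicin rule.
#' Prescriptions outside the rule's age window, or with missing/non-positive
#' weight, return `NA` (unassessable) rather than erroring — real audit data
#' contain such rows and they are counted, not dropped silently.
#'
#' @param weight_kg Numeric vector of weights (kg).
#' @param age_days Numeric vector of postnatal ages (days); recycled.
#' @param rule A [dose_rule()].
#' @return Numeric vector of expected doses in mg, `NA` where unassessable.
#' @export
expected_dose <- function(weight_kg, age_days, rule = dose_rule()) {
  stopifnot(inherits(rule, "dose_rule"))
  k <- max(length(weight_kg), length(age_days))
  weight_kg <- rep_len(as.numeric(weight_kg), k)
  age_days <- rep_len(as.numeric(age_days), k)
  band <- findInterval(weight_kg, rule$bands$weight_min)
  ok <- !is.na(weight_kg) & weight_kg > 0 &
    !is.na(age_days) & age_days >= rule$age_window_days[1] &
    age_days <= rule$age_window_days[2]
  out <- rep(NA_real_, k)
  out[ok] <- rule$bands$dose_per_kg[band[ok]] * weight_kg[ok]
  out
}

# relative tolerance shields exact-margin ratios from floating-point noise
dose_boundary_tol <- 1e-9

#' Classify prescribed doses against the guideline
#'
#' Computes ratio = prescribed / expected and classifies each prescription:
#' `correct` when (1 - m) <= ratio <= (1 + m) (boundaries inclusive, with a
#' 1e-9 relative tolerance), `overdose` above, `underdose` below, and
#' `unassessable` when no expected dose exists (missing or non-positive
#' weight, or age outside the rule window) — with the reason recorded.
#'
#' @param prescribed_mg Numeric vector of prescribed doses (mg).
#' @param weight_kg,age_days As in [expected_dose()]; recycled.
#' @param rule A [dose_rule()].
#' @return Tibble with `prescribed_mg`, `weight_kg`, `age_days`,
#'   `expected_mg`, `ratio`, `class` (factor correct/overdose/underdose/
#'   unassessable) and `reason` (`NA` unless unassessable).
#' @export
classify_dose <- function(prescribed_mg, weight_kg, age_days,
                          rule = dose_rule()) {
  stopifnot(inherits(rule, "dose_rule"))
  k <- max(length(prescribed_mg), length(weight_kg), length(age_days))
  prescribed_mg <- rep_len(as.numeric(prescribed_mg), k)
  weight_kg <- rep_len(as.numeric(weight_kg), k)
  age_days <- rep_len(as.numeric(age_days), k)

  expected <- expected_dose(weight_kg, age_days, rule)
  bad_dose <- is.na(prescribed_mg) | prescribed_mg <= 0
  ratio <- ifelse(is.na(expected) | bad_dose, NA_real_,
                  prescribed_mg / expected)

  m <- rule$margin
  hi <- (1 + m) * (1 + dose_boundary_tol)
  lo <- (1 - m) * (1 - dose_boundary_tol)
  cls <- rep("unassessable", k)
  cls[!is.na(ratio) & ratio > hi] <- "overdose"
  cls[!is.na(ratio) & ratio < lo] <- "underdose"
  cls[!is.na(ratio) & ratio >= lo & ratio <= hi] <- "correct"

  reason <- rep(NA_character_, k)
  reason[is.na(weight_kg) | weight_kg <= 0] <- "missing or non-positive weight"
  age_out <- !is.na(weight_kg) & weight_kg > 0 &
    (is.na(age_days) | age_days < rule$age_window_days[1] |
       age_days > rule$age_window_days[2])
  reason[age_out] <- "age outside rule window"
  reason[cls != "unassessable"] <- NA_character_
  reason[cls == "unassessable" & is.na(reason)] <- "missing or non-positive dose"

  tibble::tibble(
    prescribed_mg = prescribed_mg, weight_kg = weight_kg,
    age_days = age_days, expected_mg = expected, ratio = ratio,
    class = factor(cls, levels = c("correct", "overdose", "underdose",
                                   "unassessable")),
    reason = reason
  )
}

#' Audit a prescription table
#'
#' Classifies every prescription row and carries through the identifiers
#' needed for trend reporting.
#'
#' @param prescriptions Tibble with at least `prescription_id`, `record_id`,
#'   `date`, `dose_mg`, `weight_kg`, `age_days`.
#' @param rule A [dose_rule()].
#' @return The input identifiers joined to the [classify_dose()] columns,
#'   plus `band` (`"under_2kg"` / `"at_least_2kg"`, `NA` when weight is
#'   missing).
#' @export
audit_prescriptions <- function(prescriptions, rule = dose_rule()) {
  cls <- classify_dose(prescriptions$dose_mg, prescriptions$weight_kg,
                       prescriptions$age_days, rule)
  boundary <- rule$bands$weight_min[2]
  dplyr::bind_cols(
    prescriptions[, c("prescription_id", "record_id", "date")],
    cls,
    tibble::tibble(band = ifelse(
      is.na(prescriptions$weight_kg), NA_character_,
      ifelse(prescriptions$weight_kg < boundary, "under_2kg", "at_least_2kg")
    ))
  )
}

#' Dosing accuracy trend by period and weight band
#'
#' Per-period proportion of correct doses among assessable prescriptions
#' (unassessable rows are excluded from both counts), with confidence
#' intervals, split by weight band. Periods with no assessable prescriptions
#' are reported with `n = 0` and no estimate.
#'
#' @param assessments Output of [audit_prescriptions()].
#' @param config A [period_config()].
#' @param by_band Split by weight band (default) or pool all weights.
#' @return Tibble: `band` (if `by_band`), `period`, `x` (correct), `n`
#'   (assessable), `point`, `ci_low`, `ci_high`.
#' @export
dose_accuracy_series <- function(assessments, config = period_config(),
                                 by_band = TRUE) {
  per <- assign_period(assessments$date, config)
  assessments$period <- per$period
  bands <- if (by_band) c("under_2kg", "at_least_2kg") else "all"
  out <- list()
  for (b in bands) {
    for (p in levels(per$period)) {
      sub <- if (by_band) {
        assessments[!is.na(assessments$band) & assessments$band == b &
                      assessments$period == p, ]
      } else {
        assessments[assessments$period == p, ]
      }
      assessable <- sub$class %in% c("correct", "overdose", "underdose")
      n <- sum(assessable)
      if (n == 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          band = b, period = p, x = 0L, n = 0L, point = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_
        )
      } else {
        x <- sum(sub$class == "correct")
        est <- proportion_estimate(x, n, config)
        out[[length(out) + 1]] <- tibble::tibble(
          band = b, period = p, x = x, n = n, point = est$point,
          ci_low = est$ci_low, ci_high = est$ci_high
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$period <- factor(res$period, levels = config$bins$label)
  if (!by_band) res$band <- NULL
  dplyr::arrange(res, .data$period)
}
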