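# Seeded synthetic cohort generator: admissions and gentamicin prescriptions
# with the statistical structure the audit pipeline assumes, standing in for
# hospital data that are not publicly deposited.

#' Default per-variable documentation probabilities
#'
#' A linear ramp per variable from study start (`p_start`) to study end
#' (`p_end`). Defaults emulate the documented behaviour of a busy newborn
#' unit under audit and feedback: birth weight near-universally documented
#' throughout; gestational age improving steeply (0.10 to 0.80); admission
#' temperature and a handful of physical-examination signs (visible wasting,
#' skin pinch, skin temperature gradient, femoral pulses, eye discharge)
#' stubbornly poor; everything else on a generic 0.40 to 0.80 improvement.
#'
#' @return Tibble with `variable`, `p_start`, `p_end` for all dictionary
#'   variables.
#' @export
default_doc_prob <- function() {
  dict <- nar_dictionary()
  out <- tibble::tibble(variable = dict$name, p_start = 0.40, p_end = 0.80)
  set_p <- function(out, vars, p0, p1) {
    i <- out$variable %in% vars
    out$p_start[i] <- p0
    out$p_end[i] <- p1
    out
  }
  out <- set_p(out, c("birth_weight", "date_of_birth", "admission_date",
                      "gender"), 0.95, 0.99)
  out <- set_p(out, "gestational_age", 0.10, 0.80)
  out <- set_p(out, c("temperature", "skin_rashes"), 0.25, 0.45)
  out <- set_p(out, c("severe_wasting", "skin_pinch",
                      "skin_temperature_gradient", "femoral_pulses",
                      "eye_infection"), 0.05, 0.20)
  out
}

#' Synthetic cohort parameters
#'
#' The stated world of the generator. Defaults are anchored to the audited
#' unit's published marginals: about 55 abstracted admissions per month
#' before the record-form revision and about 230 after; neonatal sepsis
#' prevalence 16.7%; in-hospital mortality 9%; 46% female; birth weight
#' centred on 2.88 kg (truncated normal, sd 0.6 kg, bounds 0.5-5.5 kg); a
#' random 60% of admissions flagged for full-data abstraction; 39.5% of
#' non-sepsis admissions nevertheless receiving antibiotics; and gentamicin
#' over/under-dose rates of 4.4% and 2.4%.
#'
#' @param start_date,end_date Study window (defaults Jan 2013 - Nov 2016).
#' @param admissions_per_month Named vector `c(pre = ..., post = ...)` of
#'   expected monthly abstracted admissions by phase, or a single number for
#'   both phases.
#' @param doc_prob Tibble `variable`, `p_start`, `p_end`; rows override
#'   [default_doc_prob()] by variable name.
#' @param sepsis_prevalence,mortality,female_fraction,full_dataset_fraction,
#'   nonsepsis_antibiotic_fraction Probabilities in \[0, 1\].
#' @param weight_mean_kg,weight_sd_kg,weight_bounds Truncated-normal birth
#'   weight distribution (kg).
#' @param dose_error List with `overdose_rate`, `underdose_rate` (the two
#'   must sum to < 1) and `magnitude_sdlog` (spread of the log-normal error
#'   magnitude beyond the margin).
#' @param revision_date Records admitted before this date carry the
#'   `baseline` form version; from this date, `revised2014`.
#' @param seed Optional integer seed; identical seed and parameters give an
#'   identical cohort.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(start_date = "2013-01-01",
                          end_date = "2016-11-30",
                          admissions_per_month = c(pre = 55, post = 230),
                          doc_prob = NULL,
                          sepsis_prevalence = 0.167,
                          mortality = 0.09,
                          female_fraction = 0.46,
                          weight_mean_kg = 2.88,
                          weight_sd_kg = 0.6,
                          weight_bounds = c(0.5, 5.5),
                          full_dataset_fraction = 0.6,
                          nonsepsis_antibiotic_fraction = 0.395,
                          dose_error = list(overdose_rate = 0.044,
                                            underdose_rate = 0.024,
                                            magnitude_sdlog = 0.25),
                          revision_date = "2014-04-01",
                          seed = NULL) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date <= start_date) {
    rlang::abort("empty or unordered date span")
  }
  if (length(admissions_per_month) == 1) {
    admissions_per_month <- c(pre = unname(admissions_per_month),
                              post = unname(admissions_per_month))
  }
  probs <- c(sepsis_prevalence, mortality, female_fraction,
             full_dataset_fraction, nonsepsis_antibiotic_fraction,
             dose_error$overdose_rate, dose_error$underdose_rate)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("probabilities must be in [0, 1]")
  }
  if (dose_error$overdose_rate + dose_error$underdose_rate >= 1) {
    rlang::abort("overdose_rate + underdose_rate must be < 1")
  }
  if (any(weight_bounds <= 0) || weight_bounds[1] >= weight_bounds[2]) {
    rlang::abort("weight bounds must be positive and ordered")
  }
  dp <- default_doc_prob()
  if (!is.null(doc_prob)) {
    doc_prob <- tibble::as_tibble(doc_prob)
    unknown <- setdiff(doc_prob$variable, dp$variable)
    if (length(unknown) > 0) {
      rlang::abort(paste0("doc_prob for unknown variables: ",
                          paste(unknown, collapse = ", ")))
    }
    keep <- !(dp$variable %in% doc_prob$variable)
    dp <- dplyr::bind_rows(dp[keep, ], doc_prob)
  }
  if (any(dp$p_start < 0 | dp$p_start > 1 | dp$p_end < 0 | dp$p_end > 1)) {
    rlang::abort("documentation probabilities must be in [0, 1]")
  }
  structure(
    list(start_date = start_date, end_date = end_date,
         admissions_per_month = admissions_per_month, doc_prob = dp,
         sepsis_prevalence = sepsis_prevalence, mortality = mortality,
         female_fraction = female_fraction, weight_mean_kg = weight_mean_kg,
         weight_sd_kg = weight_sd_kg, weight_bounds = weight_bounds,
         full_dataset_fraction = full_dataset_fraction,
         nonsepsis_antibiotic_fraction = nonsepsis_antibiotic_fraction,
         dose_error = dose_error, revision_date = as.Date(revision_date),
         seed = seed),
    class = "cohort_params"
  )
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  # inverse-CDF sampling of the truncated normal
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

sample_admission_age <- function(n) {
  # 78% admitted on the date of birth, ~90% within 48 h, tail to day 14
  tail_p <- 0.095 * 0.6^(0:12)
  probs <- c(0.783, 0.122, tail_p / sum(tail_p) * 0.095)
  sample(0:14, n, replace = TRUE, prob = probs)
}

dx_pool <- c("prematurity", "birth asphyxia", "respiratory distress",
             "neonatal jaundice", "low birth weight")

gen_value <- function(v, rec) {
  # plausible documented value for variable spec v given record truths
  n <- nrow(rec)
  switch(
    v$name,
    date_of_birth = format(rec$dob, "%Y-%m-%d"),
    admission_date = format(rec$adm_date, "%Y-%m-%d"),
    discharge_date = format(rec$disch_date, "%Y-%m-%d"),
    gender = rec$sex,
    birth_weight = sprintf("%.2f", rec$weight_kg),
    age_in_days = as.character(as.integer(rec$adm_date - rec$dob)),
    gestational_age = as.character(rec$gest_weeks),
    outcome = rec$vital_status,
    admission_diagnosis = rec$diagnoses,
    discharge_diagnosis = rec$diagnoses,
    gestational_size = ifelse(rec$gest_weeks < 34, "sga",
                              ifelse(rec$gest_weeks > 41, "lga", "aga")),
    temperature = sprintf("%.1f", pmin(pmax(stats::rnorm(n, 36.8, 0.8),
                                            33), 40)),
    respiratory_rate = as.character(round(pmin(pmax(
      stats::rnorm(n, 48, 12), 20), 100))),
    heart_rate = as.character(round(pmin(pmax(
      stats::rnorm(n, 140, 20), 80), 220))),
    oxygen_saturation = as.character(round(pmin(pmax(
      stats::rnorm(n, 94, 4), 60), 100))),
    {
      if (v$value_kind == "numeric") {
        lo <- v$range_min + 0.2 * (v$range_max - v$range_min)
        hi <- v$range_min + 0.8 * (v$range_max - v$range_min)
        as.character(round(stats::runif(n, lo, hi), 1))
      } else if (v$value_kind == "categorical") {
        cats <- v$categories[[1]]
        if (identical(cats, yn())) {
          sample(yn(), n, replace = TRUE, prob = c(0.15, 0.85))
        } else {
          sample(cats, n, replace = TRUE)
        }
      } else if (v$value_kind == "date") {
        format(rec$adm_date, "%Y-%m-%d")
      } else {
        "noted"
      }
    }
  )
}

#' Simulate a synthetic admission cohort with gentamicin prescriptions
#'
#' Draws monthly admission counts (Poisson around the phase's expected rate),
#' admission dates uniform within month, register truths (sex, birth weight,
#' gestational age, admission age, diagnoses, vital status), then a
#' documentation layer: each dictionary variable applicable to the record's
#' form version is documented independently with that variable's
#' ramp probability evaluated at the admission date, and a plausible value is
#' generated when documented. Sepsis-diagnosed babies — and a configurable
#' fraction of the others, emulating antibiotic treatment without a clear
#' sepsis diagnosis — receive one gentamicin prescription whose dose is the
#' guideline dose perturbed multiplicatively: correct doses land strictly
#' inside the margin, over/under-doses strictly outside it, at the configured
#' rates.
#'
#' @param params A [cohort_params()].
#' @param schema A `nar_schema` (the revised form; baseline applicability is
#'   derived from `introduced_in`).
#' @param seed Overrides `params$seed` when given.
#' @return List of class `nar_cohort` with `records` and `prescriptions`
#'   tibbles and the `params` used.
#' @export
simulate_cohort <- function(params = cohort_params(),
                            schema = load_schema("revised2014"),
                            seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"), inherits(schema, "nar_schema"))
  run <- function() simulate_cohort_impl(params, schema)
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

simulate_cohort_impl <- function(params, schema) {
  months <- seq(as.Date(format(params$start_date, "%Y-%m-01")),
                params$end_date, by = "month")
  rate <- ifelse(months < params$revision_date,
                 params$admissions_per_month[["pre"]],
                 params$admissions_per_month[["post"]])
  n_month <- stats::rpois(length(months), rate)
  n <- sum(n_month)

  next_start <- seq(months[1], by = "month", length.out = length(months) + 1)[-1]
  days_in_month <- as.integer(next_start - months)
  month_start <- rep(months, n_month)
  month_len <- rep(days_in_month, n_month)
  # uniform day within month, clipped to the study window
  adm_date <- pmax(month_start +
                     floor(stats::runif(n) * month_len), params$start_date)
  adm_date <- pmin(adm_date, params$end_date)
  adm_date <- sort(adm_date)

  age_days <- sample_admission_age(n)
  dob <- adm_date - age_days
  sex <- ifelse(stats::runif(n) < params$female_fraction, "female", "male")
  weight <- round(rtruncnorm1(n, params$weight_mean_kg, params$weight_sd_kg,
                              params$weight_bounds[1],
                              params$weight_bounds[2]), 3)
  gest <- pmin(pmax(round(stats::rnorm(n, 38, 2.5)), 24), 43)
  sepsis <- stats::runif(n) < params$sepsis_prevalence
  other_dx <- sample(dx_pool, n, replace = TRUE)
  diagnoses <- ifelse(sepsis, paste("neonatal sepsis", other_dx, sep = ";"),
                      other_dx)
  dead <- stats::runif(n) < params$mortality
  los <- 1 + stats::rpois(n, 3)
  disch <- adm_date + los
  version <- ifelse(adm_date < params$revision_date, "baseline",
                    "revised2014")
  full <- stats::runif(n) < params$full_dataset_fraction

  records <- tibble::tibble(
    record_id = sprintf("R%05d", seq_len(n)),
    adm_date = adm_date, dob = dob, disch_date = disch,
    vital_status = ifelse(dead, "dead", "alive"),
    sex = sex, weight_kg = weight, gest_weeks = gest,
    diagnoses = diagnoses, schema_version = version, full_dataset = full
  )

  # documentation layer
  span <- as.numeric(params$end_date - params$start_date)
  t_frac <- as.numeric(adm_date - params$start_date) / span
  dict <- schema$dictionary
  for (i in seq_len(nrow(dict))) {
    v <- dict[i, ]
    dp <- params$doc_prob[params$doc_prob$variable == v$name, ]
    p <- dp$p_start + (dp$p_end - dp$p_start) * t_frac
    documented <- stats::runif(n) < p
    if (v$introduced_in == "revised2014") {
      documented[version == "baseline"] <- FALSE
    }
    col <- rep(NA_character_, n)
    if (any(documented)) {
      vals <- gen_value(v, records)
      col[documented] <- vals[documented]
    }
    records[[v$name]] <- col
  }

  # gentamicin prescriptions
  treated <- sepsis |
    (!sepsis & stats::runif(n) < params$nonsepsis_antibiotic_fraction)
  idx <- which(treated)
  k <- length(idx)
  rule <- dose_rule()
  guideline <- rule$bands$dose_per_kg[findInterval(weight[idx],
                                                   rule$bands$weight_min)] *
    weight[idx]
  u <- stats::runif(k)
  de <- params$dose_error
  kind <- ifelse(u < de$overdose_rate, "over",
                 ifelse(u < de$overdose_rate + de$underdose_rate,
                        "under", "correct"))
  excess <- exp(0.02 + abs(stats::rnorm(k, 0, de$magnitude_sdlog)))
  ratio <- ifelse(kind == "over", (1 + rule$margin) * excess,
                  ifelse(kind == "under", (1 - rule$margin) / excess,
                         stats::runif(k, 0.9, 1.1)))
  prescriptions <- tibble::tibble(
    prescription_id = sprintf("P%05d", seq_len(k)),
    record_id = records$record_id[idx],
    drug = "gentamicin",
    date = adm_date[idx],
    dose_mg = round(guideline * ratio, 2),
    frequency = "once daily",
    weight_kg = weight[idx],
    age_days = age_days[idx]
  )

  structure(list(records = records, prescriptions = prescriptions,
                 params = params),
            class = "nar_cohort")
}

#' @export
print.nar_cohort <- function(x, ...) {
  cat("<nar_cohort>", nrow(x$records), "admissions,",
      nrow(x$prescriptions), "prescriptions,",
      format(x$params$start_date), "to", format(x$params$end_date), "\n")
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `records.csv` and `prescriptions.csv` under `dir`, with absent
#' documentation encoded as empty cells. [read_cohort()] inverts losslessly.
#'
#' @param cohort A `nar_cohort` (or a list with `records` and
#'   `prescriptions`).
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rp <- file.path(dir, "records.csv")
  pp <- file.path(dir, "prescriptions.csv")
  readr::write_csv(cohort$records, rp, na = "")
  readr::write_csv(cohort$prescriptions, pp, na = "")
  invisible(c(records = rp, prescriptions = pp))
}

#' Read a cohort from CSV files
#'
#' @param dir Directory containing `records.csv` and `prescriptions.csv`.
#' @param schema A `nar_schema`; documentation columns are read as character
#'   and the table is structurally checked.
#' @return List with `records` and `prescriptions` tibbles.
#' @export
read_cohort <- function(dir, schema = load_schema("revised2014")) {
  dict_cols <- stats::setNames(
    rep(list(readr::col_character()), nrow(schema$dictionary)),
    schema$dictionary$name
  )
  rec_types <- do.call(readr::cols, c(list(
    record_id = readr::col_character(),
    adm_date = readr::col_date(),
    dob = readr::col_date(),
    disch_date = readr::col_date(),
    vital_status = readr::col_character(),
    sex = readr::col_character(),
    weight_kg = readr::col_double(),
    gest_weeks = readr::col_double(),
    diagnoses = readr::col_character(),
    schema_version = readr::col_character(),
    full_dataset = readr::col_logical()
  ), dict_cols))
  records <- readr::read_csv(file.path(dir, "records.csv"),
                             col_types = rec_types, na = "")
  check_records(records, schema)
  prescriptions <- readr::read_csv(
    file.path(dir, "prescriptions.csv"),
    col_types = readr::cols(
      prescription_id = readr::col_character(),
      record_id = readr::col_character(),
      drug = readr::col_character(),
      date = readr::col_date(),
      dose_mg = readr::col_double(),
      frequency = readr::col_character(),
      weight_kg = readr::col_double(),
      age_days = readr::col_integer()
    ), na = ""
  )
  list(records = records, prescriptions = prescriptions)
}
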