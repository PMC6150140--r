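# Documentation-completeness scoring: binary availability per variable,
# pooled by domain and period, and variable-level stratification.

applicable_matrix <- function(records, schema) {
  # records x variables logical matrix: is the variable on this record's form?
  vars <- schema$dictionary
  base_ok <- matrix(TRUE, nrow(records), nrow(vars))
  revised_only <- vars$introduced_in == "revised2014"
  if (any(revised_only)) {
    base_ok[records$schema_version == "baseline", revised_only] <- FALSE
  }
  colnames(base_ok) <- vars$name
  base_ok
}

#' Binary documentation indicator for one variable
#'
#' The atom of the completeness statistic: for each record, 1 if the variable
#' has a non-empty documented value (after trimming whitespace), 0 if the
#' cell is empty, and `NA` if the variable was not on that record's form
#' version (e.g. a 2014-revision variable queried on a baseline record) — a
#' not-applicable slot, excluded from numerator and denominator alike.
#'
#' @param records Admission tibble.
#' @param variable Variable name (must exist in the dictionary).
#' @param schema A `nar_schema`.
#' @return Integer vector (1/0/`NA`), one element per record.
#' @export
doc_indicator <- function(records, variable, schema) {
  stopifnot(inherits(schema, "nar_schema"))
  row <- schema$dictionary[schema$dictionary$name == variable, ]
  if (nrow(row) == 0) {
    rlang::abort(paste0("unknown variable name: ", variable))
  }
  ind <- as.integer(documented_chr(records[[variable]]))
  if (row$introduced_in == "revised2014") {
    ind[records$schema_version == "baseline"] <- NA_integer_
  }
  ind
}

#' Per-patient documentation completeness
#'
#' For each admission, the fraction of form variables with a documented
#' value among those applicable to the record's form version.
#'
#' @param records Admission tibble.
#' @param schema A `nar_schema`.
#' @return Tibble with `record_id`, `documented`, `applicable`, `fraction`.
#'   A record with no applicable variables is an error.
#' @export
patient_completeness <- function(records, schema) {
  stopifnot(inherits(schema, "nar_schema"))
  app <- applicable_matrix(records, schema)
  doc <- vapply(schema$dictionary$name,
                function(v) documented_chr(records[[v]]),
                logical(nrow(records)))
  doc <- matrix(doc, nrow = nrow(records))
  doc[!app] <- FALSE
  applicable <- rowSums(app)
  if (any(applicable == 0)) {
    rlang::abort("record(s) with no applicable variables")
  }
  tibble::tibble(
    record_id = records$record_id,
    documented = as.integer(rowSums(doc)),
    applicable = as.integer(applicable),
    fraction = rowSums(doc) / applicable
  )
}

#' Pooled documentation completeness for one domain
#'
#' The pooled statistic: x = number of documented variable slots summed over
#' the given records and the domain's applicable variables; n = number of
#' applicable slots. Not-applicable slots (variables missing from a record's
#' form version) are excluded from both counts, so pre-revision records are
#' not penalised for variables their form never carried. Callers bin records
#' into periods first; this function scores whatever it is given.
#'
#' @param records Admission tibble (already restricted to one period if a
#'   per-period figure is wanted).
#' @param domain One of [nar_domains()].
#' @param schema A `nar_schema`.
#' @param config A [period_config()] supplying the CI settings.
#' @return One-row tibble: `domain`, `x`, `n`, `point`, `ci_low`, `ci_high`.
#'   An empty denominator (no applicable slots) is an error, never 0/0.
#' @export
domain_completeness <- function(records, domain, schema,
                                config = period_config()) {
  stopifnot(inherits(schema, "nar_schema"))
  if (!domain %in% nar_domains()) {
    rlang::abort(paste0("unknown domain label: ", domain))
  }
  vars <- schema$dictionary$name[schema$dictionary$domain == domain]
  ind <- lapply(vars, function(v) doc_indicator(records, v, schema))
  ind <- do.call(cbind, ind)
  n <- sum(!is.na(ind))
  if (n == 0) {
    rlang::abort(paste0("no applicable slots for domain '", domain,
                        "' in these records"))
  }
  x <- sum(ind, na.rm = TRUE)
  est <- proportion_estimate(x, n, config)
  tibble::tibble(domain = domain, x = x, n = n, point = est$point,
                 ci_low = est$ci_low, ci_high = est$ci_high)
}

#' Completeness table by domain and period
#'
#' The audit's headline table: pooled documentation completeness for every
#' domain in every study period, with confidence intervals. Records are
#' binned by register admission date. Domain-period cells with no applicable
#' slots (e.g. maternal history before the form revision) are reported with
#' `n = 0` and no estimate rather than erroring, so mixed-version cohorts
#' tabulate cleanly.
#'
#' @param records Admission tibble.
#' @param schema A `nar_schema`.
#' @param config A [period_config()].
#' @param method `"pooled"` (default; slot counts pooled over the patient
#'   population, the audit's primary definition) or `"patient_mean"` (mean of
#'   per-patient fractions, with a normal-approximation CI).
#' @return Tibble: `domain`, `period`, `phase` (modal phase of the bin's
#'   records), `x`, `n`, `point`, `ci_low`, `ci_high`.
#' @export
completeness_table <- function(records, schema, config = period_config(),
                               method = c("pooled", "patient_mean")) {
  method <- match.arg(method)
  bins <- assign_period(records$adm_date, config)
  records <- dplyr::mutate(records, period = bins$period, phase = bins$phase)
  out <- list()
  for (per in levels(bins$period)) {
    rec_p <- records[records$period == per, ]
    if (nrow(rec_p) == 0) next
    phase_p <- names(which.max(table(rec_p$phase)))
    for (dom in nar_domains()) {
      vars <- schema$dictionary$name[schema$dictionary$domain == dom]
      ind <- do.call(cbind, lapply(vars, function(v) {
        doc_indicator(rec_p, v, schema)
      }))
      n <- sum(!is.na(ind))
      if (n == 0) {
        row <- tibble::tibble(domain = dom, period = per, phase = phase_p,
                              x = 0L, n = 0L, point = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_)
      } else if (method == "pooled") {
        x <- sum(ind, na.rm = TRUE)
        est <- proportion_estimate(x, n, config)
        row <- tibble::tibble(domain = dom, period = per, phase = phase_p,
                              x = x, n = n, point = est$point,
                              ci_low = est$ci_low, ci_high = est$ci_high)
      } else {
        frac <- rowMeans(ind, na.rm = TRUE)
        frac <- frac[!is.nan(frac)]
        m <- mean(frac)
        se <- stats::sd(frac) / sqrt(length(frac))
        z <- stats::qnorm(1 - (1 - config$conf_level) / 2)
        row <- tibble::tibble(domain = dom, period = per, phase = phase_p,
                              x = sum(ind, na.rm = TRUE), n = n, point = m,
                              ci_low = max(0, m - z * se),
                              ci_high = min(1, m + z * se))
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- dplyr::bind_rows(out)
  res$period <- factor(res$period, levels = config$bins$label)
  dplyr::arrange(res, .data$period, match(.data$domain, nar_domains()))
}

stratum_of <- function(fraction) {
  # very_poor < 0.25 <= poor <= 0.50 < adequate; strata partition [0, 1]
  ifelse(fraction < 0.25, "very_poor",
         ifelse(fraction <= 0.50, "poor", "adequate"))
}

#' Stratify one variable by documentation level
#'
#' Classifies a variable by its documented fraction among applicable
#' records: `very_poor` below 25%, `poor` from 25% to 50% (both boundaries
#' inclusive), `adequate` above 50%. Used on the final study period to find
#' what remains hard to document despite feedback.
#'
#' @param records Admission tibble (restrict to the period of interest
#'   first).
#' @param variable Variable name.
#' @param schema A `nar_schema`.
#' @return One-row tibble: `variable`, `domain`, `documented_fraction`,
#'   `stratum`. Zero applicable records is an error.
#' @export
stratify_variable <- function(records, variable, schema) {
  ind <- doc_indicator(records, variable, schema)
  if (all(is.na(ind))) {
    rlang::abort(paste0("no applicable records for variable: ", variable))
  }
  frac <- mean(ind, na.rm = TRUE)
  tibble::tibble(
    variable = variable,
    domain = schema$dictionary$domain[schema$dictionary$name == variable],
    documented_fraction = frac,
    stratum = factor(as.character(stratum_of(frac)),
                     levels = c("very_poor", "poor", "adequate"))
  )
}

#' Stratify all schema variables
#'
#' @param records Admission tibble.
#' @param schema A `nar_schema`.
#' @param variables Variables to stratify; default all in the schema version.
#'   Variables with no applicable records are dropped with a warning rather
#'   than erroring, so whole-dictionary sweeps work on any cohort.
#' @return Tibble, one row per variable (see [stratify_variable()]).
#' @export
stratify_variables <- function(records, schema, variables = NULL) {
  if (is.null(variables)) variables <- schema$variables$name
  rows <- list()
  dropped <- character()
  for (v in variables) {
    ind <- doc_indicator(records, v, schema)
    if (all(is.na(ind))) {
      dropped <- c(dropped, v)
      next
    }
    rows[[length(rows) + 1]] <- stratify_variable(records, v, schema)
  }
  if (length(dropped) > 0) {
    rlang::warn(paste0("no applicable records; dropped: ",
                       paste(dropped, collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}
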