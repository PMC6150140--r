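# End-to-end audit pipeline: validate -> bin -> score -> stratify ->
# dose-audit -> summarise, and report serialisation.

#' Run the full audit pipeline
#'
#' Executes the audit-and-feedback analysis end to end on an admission table
#' and a prescription table: structural check and validity findings, period
#' binning, pooled completeness by domain and period, variable stratification
#' on a chosen period (by default the last), the gentamicin dosing-accuracy
#' series by weight band, and a headline summary (admissions, sepsis
#' fraction, mortality, full-data fraction — all over the same denominator,
#' every loaded record, with confidence intervals).
#'
#' @param records Admission tibble (or a `nar_cohort`, whose prescriptions
#'   are then used too).
#' @param prescriptions Prescription tibble; may be `NULL` for a cohort with
#'   no prescriptions (the dosing section is then all `n = 0`).
#' @param schema A `nar_schema`.
#' @param config A [period_config()].
#' @param rule A [dose_rule()].
#' @param strata_period Period label for the variable stratification;
#'   default the last bin with any records.
#' @return A list of class `audit_report`: `metadata`, `findings`,
#'   `completeness`, `strata`, `dosing`, `summary`.
#' @export
run_audit <- function(records, prescriptions = NULL,
                      schema = load_schema("revised2014"),
                      config = period_config(),
                      rule = dose_rule(),
                      strata_period = NULL) {
  if (inherits(records, "nar_cohort")) {
    if (is.null(prescriptions)) prescriptions <- records$prescriptions
    records <- records$records
  }
  check_records(records, schema)
  if (nrow(records) == 0) rlang::abort("empty cohort")
  findings <- validate_record(records, schema)

  bins <- assign_period(records$adm_date, config)
  completeness <- completeness_table(records, schema, config)

  if (is.null(strata_period)) {
    strata_period <- levels(bins$period)[max(as.integer(bins$period))]
  }
  in_period <- as.character(bins$period) == strata_period
  strata <- suppressWarnings(
    stratify_variables(records[in_period, ], schema)
  )
  strata$period <- strata_period

  if (is.null(prescriptions) || nrow(prescriptions) == 0) {
    assessments <- audit_prescriptions(tibble::tibble(
      prescription_id = character(), record_id = character(),
      date = as.Date(character()), dose_mg = numeric(),
      weight_kg = numeric(), age_days = integer()
    ), rule)
    dosing <- tibble::tibble(
      band = rep(c("under_2kg", "at_least_2kg"), each = nrow(config$bins)),
      period = factor(rep(config$bins$label, 2), levels = config$bins$label),
      x = 0L, n = 0L, point = NA_real_, ci_low = NA_real_, ci_high = NA_real_
    )
  } else {
    assessments <- audit_prescriptions(prescriptions, rule)
    dosing <- dose_accuracy_series(assessments, config, by_band = TRUE)
  }

  n <- nrow(records)
  sepsis <- grepl("neonatal sepsis", records$diagnoses, fixed = TRUE)
  headline <- function(label, x) {
    est <- proportion_estimate(x, n, config)
    tibble::tibble(measure = label, x = x, n = n, point = est$point,
                   ci_low = est$ci_low, ci_high = est$ci_high)
  }
  summary <- dplyr::bind_rows(
    headline("sepsis", sum(sepsis)),
    headline("mortality", sum(records$vital_status == "dead")),
    headline("full_dataset", sum(records$full_dataset))
  )

  metadata <- list(
    n_records = n,
    n_prescriptions = if (is.null(prescriptions)) 0L else nrow(prescriptions),
    n_findings = nrow(findings),
    schema_version_counts = as.list(table(records$schema_version)),
    strata_period = strata_period,
    ci_method = config$ci_method,
    conf_level = config$conf_level,
    study_window = c(format(config$study_start), format(config$study_end)),
    revision_date = format(config$revision_date),
    dose_rule = list(drug = rule$drug, margin = rule$margin,
                     age_window_days = rule$age_window_days),
    note = paste("headline denominators use all loaded records; published",
                 "audits sometimes mix combined and subset denominators")
  )

  structure(
    list(metadata = metadata, findings = findings,
         completeness = completeness, strata = strata, dosing = dosing,
         summary = summary),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>", x$metadata$n_records, "records,",
      x$metadata$n_prescriptions, "prescriptions,",
      x$metadata$n_findings, "validity findings\n")
  cat("  completeness:", nrow(x$completeness), "domain-period cells;",
      "strata period:", x$metadata$strata_period, "\n")
  invisible(x)
}

round_pct <- function(p) round(100 * p, 1)

#' Write an audit report to disk
#'
#' Writes four CSV tables (`completeness.csv`, `strata.csv`, `dosing.csv`,
#' `summary.csv`; percentages to one decimal alongside the unrounded counts)
#' and, with `"json"` among `formats`, a `summary.json` carrying the metadata
#' and summary. Nothing time-stamped is written, so regeneration from the
#' same inputs is byte-identical. With `plots = TRUE` (requires ggplot2)
#' trend figures with CI ribbons are written as PDFs: completeness by
#' domain, gestational-age documentation, and dose accuracy by weight band.
#'
#' @param report An `audit_report`.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @param plots Also write trend plots (default `FALSE`).
#' @param records Needed only when `plots = TRUE` (for the gestational-age
#'   trend), the admission tibble the report was built from.
#' @param schema,config As in [run_audit()]; used only for plots.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir, formats = c("csv", "json"),
                         plots = FALSE, records = NULL,
                         schema = load_schema("revised2014"),
                         config = period_config()) {
  stopifnot(inherits(report, "audit_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()

  if ("csv" %in% formats) {
    comp <- dplyr::mutate(report$completeness,
                          pct = round_pct(.data$point),
                          ci_low_pct = round_pct(.data$ci_low),
                          ci_high_pct = round_pct(.data$ci_high))
    strata <- dplyr::mutate(report$strata,
                            pct = round_pct(.data$documented_fraction))
    dosing <- dplyr::mutate(report$dosing,
                            pct = round_pct(.data$point),
                            ci_low_pct = round_pct(.data$ci_low),
                            ci_high_pct = round_pct(.data$ci_high))
    summary <- dplyr::mutate(report$summary,
                             pct = round_pct(.data$point),
                             ci_low_pct = round_pct(.data$ci_low),
                             ci_high_pct = round_pct(.data$ci_high))
    tabs <- list(completeness = comp, strata = strata, dosing = dosing,
                 summary = summary)
    for (nm in names(tabs)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(tabs[[nm]], p, na = "")
      paths <- c(paths, p)
    }
  }

  if ("json" %in% formats) {
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(metadata = report$metadata, summary = report$summary),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    paths <- c(paths, p)
  }

  if (plots) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      rlang::abort("plots = TRUE requires the ggplot2 package")
    }
    paths <- c(paths, write_report_plots(report, out_dir, records, schema,
                                         config))
  }
  invisible(paths)
}

write_report_plots <- function(report, out_dir, records, schema, config) {
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  paths <- character()

  comp <- report$completeness[!is.na(report$completeness$point), ]
  p1 <- gg(comp, aes(x = .data$period, y = 100 * .data$point, group = 1)) +
    ggplot2::geom_ribbon(aes(ymin = 100 * .data$ci_low,
                             ymax = 100 * .data$ci_high),
                         fill = "grey40", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~domain) +
    ggplot2::labs(x = "six-month period", y = "documented slots (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  f1 <- file.path(out_dir, "completeness_trends.pdf")
  ggplot2::ggsave(f1, p1, width = 9, height = 6)
  paths <- c(paths, f1)

  dos <- report$dosing[!is.na(report$dosing$point), ]
  if (nrow(dos) > 0) {
    p2 <- gg(dos, aes(x = .data$period, y = 100 * .data$point, group = 1)) +
      ggplot2::geom_ribbon(aes(ymin = 100 * .data$ci_low,
                               ymax = 100 * .data$ci_high),
                           fill = "grey60", alpha = 0.5) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~band, ncol = 1) +
      ggplot2::labs(x = "six-month period", y = "correct gentamicin dose (%)") +
      ggplot2::theme_minimal()
    f2 <- file.path(out_dir, "dose_accuracy.pdf")
    ggplot2::ggsave(f2, p2, width = 7, height = 6)
    paths <- c(paths, f2)
  }

  if (!is.null(records)) {
    bins <- assign_period(records$adm_date, config)
    ga <- dplyr::bind_rows(lapply(levels(bins$period), function(per) {
      sub <- records[as.character(bins$period) == per, ]
      if (nrow(sub) == 0) return(NULL)
      ind <- doc_indicator(sub, "gestational_age", schema)
      n <- sum(!is.na(ind))
      if (n == 0) return(NULL)
      est <- proportion_estimate(sum(ind, na.rm = TRUE), n, config)
      tibble::tibble(period = per, point = est$point, ci_low = est$ci_low,
                     ci_high = est$ci_high)
    }))
    ga$period <- factor(ga$period, levels = config$bins$label)
    p3 <- gg(ga, aes(x = .data$period, y = 100 * .data$point, group = 1)) +
      ggplot2::geom_ribbon(aes(ymin = 100 * .data$ci_low,
                               ymax = 100 * .data$ci_high),
                           fill = "grey60", alpha = 0.5) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "six-month period",
                    y = "gestational age documented (%)") +
      ggplot2::theme_minimal()
    f3 <- file.path(out_dir, "gestational_age_documentation.pdf")
    ggplot2::ggsave(f3, p3, width = 7, height = 4)
    paths <- c(paths, f3)
  }
  paths
}
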