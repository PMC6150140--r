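# Admission record tables: structure checks and range/validity findings.

#' Register (metadata) columns of an admission table
#'
#' Every admission table carries these always-known register fields alongside
#' the dictionary-named documentation columns. Register names are distinct
#' from dictionary names on purpose: `admission_date`, `date_of_birth`,
#' `discharge_date` and `outcome` also exist as *documentation* variables,
#' whose cells may be empty even when the register knows the fact (the form
#' was simply not filled in).
#'
#' @return Character vector of register column names.
#' @export
register_columns <- function() {
  c("record_id", "adm_date", "dob", "disch_date", "vital_status", "sex",
    "weight_kg", "gest_weeks", "diagnoses", "schema_version", "full_dataset")
}

#' Structural check of an admission table
#'
#' Errors (it does not return findings) when the table is malformed: missing
#' register or dictionary columns, unknown schema version tags, or
#' documentation columns not present in the dictionary. Run before
#' [validate_record()].
#'
#' @param records Admission tibble.
#' @param schema A `nar_schema` (its full dictionary defines the expected
#'   documentation columns).
#' @return `records`, invisibly.
#' @export
check_records <- function(records, schema) {
  stopifnot(inherits(schema, "nar_schema"))
  miss_reg <- setdiff(register_columns(), names(records))
  if (length(miss_reg) > 0) {
    rlang::abort(paste0("records table is missing register columns: ",
                        paste(miss_reg, collapse = ", ")))
  }
  dict_names <- schema$dictionary$name
  miss_doc <- setdiff(dict_names, names(records))
  if (length(miss_doc) > 0) {
    rlang::abort(paste0("records table is missing dictionary columns: ",
                        paste(miss_doc, collapse = ", ")))
  }
  extra <- setdiff(names(records), c(register_columns(), dict_names))
  if (length(extra) > 0) {
    rlang::abort(paste0("records table has columns not in the dictionary: ",
                        paste(extra, collapse = ", ")))
  }
  bad_ver <- setdiff(unique(records$schema_version), nar_versions())
  if (length(bad_ver) > 0) {
    rlang::abort(paste0("unknown schema version tags in records: ",
                        paste(bad_ver, collapse = ", ")))
  }
  invisible(records)
}

documented_chr <- function(x) {
  !is.na(x) & trimws(as.character(x)) != ""
}

#' Range and validity findings for admission records
#'
#' Applies the point-of-entry checks of the data platform: documented numeric
#' values must parse and fall in the dictionary range, documented categorical
#' values must belong to the category set, documented dates must parse as
#' ISO dates, and register dates must be ordered (admission on or after
#' birth; discharge on or after admission). Missingness is never a finding —
#' absent values are scored by the completeness statistics, not flagged as
#' invalid. The input table is not modified.
#'
#' @param records Admission tibble (see [check_records()]).
#' @param schema A `nar_schema`.
#' @return Tibble of findings with columns `record_id`, `variable`, `rule`
#'   (`"range"`, `"category"`, `"date_parse"` or `"date_order"`), `value`,
#'   `message`. Zero rows means clean.
#' @export
validate_record <- function(records, schema) {
  check_records(records, schema)
  finding <- function(id, variable, rule, value, message) {
    tibble::tibble(record_id = id, variable = variable, rule = rule,
                   value = as.character(value), message = message)
  }
  out <- list()

  for (i in seq_len(nrow(schema$dictionary))) {
    v <- schema$dictionary[i, ]
    x <- as.character(records[[v$name]])
    doc <- documented_chr(x)
    if (!any(doc)) next
    if (v$value_kind == "numeric") {
      num <- suppressWarnings(as.numeric(x))
      bad <- doc & (is.na(num) | num < v$range_min | num > v$range_max)
      if (any(bad)) {
        out[[length(out) + 1]] <- finding(
          records$record_id[bad], v$name, "range", x[bad],
          sprintf("value outside [%g, %g]", v$range_min, v$range_max)
        )
      }
    } else if (v$value_kind == "categorical") {
      cats <- v$categories[[1]]
      bad <- doc & !(x %in% cats)
      if (any(bad)) {
        out[[length(out) + 1]] <- finding(
          records$record_id[bad], v$name, "category", x[bad],
          paste0("value not in {", paste(cats, collapse = ", "), "}")
        )
      }
    } else if (v$value_kind == "date") {
      parsed <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
      bad <- doc & is.na(parsed)
      if (any(bad)) {
        out[[length(out) + 1]] <- finding(
          records$record_id[bad], v$name, "date_parse", x[bad],
          "value does not parse as an ISO date"
        )
      }
    }
  }

  adm <- as.Date(records$adm_date)
  dob <- as.Date(records$dob)
  dis <- as.Date(records$disch_date)
  inv1 <- !is.na(adm) & !is.na(dob) & adm < dob
  if (any(inv1)) {
    out[[length(out) + 1]] <- finding(
      records$record_id[inv1], "adm_date", "date_order",
      as.character(adm[inv1]), "admission date before date of birth"
    )
  }
  inv2 <- !is.na(adm) & !is.na(dis) & dis < adm
  if (any(inv2)) {
    out[[length(out) + 1]] <- finding(
      records$record_id[inv2], "disch_date", "date_order",
      as.character(dis[inv2]), "discharge date before admission date"
    )
  }

  if (length(out) == 0) {
    return(tibble::tibble(record_id = character(), variable = character(),
                          rule = character(), value = character(),
                          message = character()))
  }
  dplyr::bind_rows(out)
}
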