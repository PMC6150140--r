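# Versioned data dictionary for the newborn admission record (NAR).

#' Domain labels of the newborn admission record
#'
#' The six analysis domains of the NAR, in form order. Every variable in the
#' dictionary belongs to exactly one of these.
#'
#' @return Character vector of length six.
#' @export
nar_domains <- function() {
  c(
    "maternal history",
    "demographics and diagnosis",
    "presenting complaints",
    "cardinal signs on examination",
    "other physical examination",
    "vital signs"
  )
}

#' Known schema version tags
#' @return Character vector: `"baseline"`, `"revised2014"`.
#' @export
nar_versions <- function() c("baseline", "revised2014")

yn <- function() c("yes", "no")

#' Default NAR data dictionary
#'
#' The full dictionary of the revised (2014) newborn admission record: 50
#' variables across six domains. Variables added in the 2014 revision carry
#' `introduced_in = "revised2014"`; the pre-revision form is the subset with
#' `introduced_in = "baseline"`. All six maternal-history variables date from
#' the 2014 revision, as do seven physical-examination signs and oxygen
#' saturation.
#'
#' Validity ranges for numeric variables and category sets for categorical
#' ones back the point-of-entry range/validity checks; the bounds are
#' deliberately wide clinical-plausibility limits and are configurable via a
#' user dictionary (see [read_dictionary()]).
#'
#' @return A tibble with columns `name`, `domain`, `value_kind` (one of
#'   `"numeric"`, `"categorical"`, `"date"`, `"text"`), `range_min`,
#'   `range_max`, `categories` (list column), `introduced_in`.
#' @export
nar_dictionary <- function() {
  row <- function(name, domain, kind, rmin = NA_real_, rmax = NA_real_,
                  cats = NULL, intro = "baseline") {
    tibble::tibble(
      name = name, domain = domain, value_kind = kind,
      range_min = rmin, range_max = rmax,
      categories = list(cats), introduced_in = intro
    )
  }
  d <- nar_domains()
  sign_rows <- function(names, domain, intro = rep("baseline", length(names))) {
    purrr::map2(names, intro, function(nm, iv) {
      row(nm, domain, "categorical", cats = yn(), intro = iv)
    })
  }

  dplyr::bind_rows(
    # maternal history -- all added in the 2014 revision
    row("mothers_age", d[1], "numeric", 12, 55, intro = "revised2014"),
    row("parity", d[1], "numeric", 0, 15, intro = "revised2014"),
    row("gravidity", d[1], "numeric", 1, 15, intro = "revised2014"),
    row("mothers_blood_group", d[1], "categorical",
        cats = c("A+", "A-", "B+", "B-", "AB+", "AB-", "O+", "O-"),
        intro = "revised2014"),
    row("hiv_status", d[1], "categorical",
        cats = c("positive", "negative", "unknown"), intro = "revised2014"),
    row("vdrl_status", d[1], "categorical",
        cats = c("reactive", "non_reactive", "unknown"), intro = "revised2014"),

    # demographics and diagnosis
    row("date_of_birth", d[2], "date"),
    row("admission_date", d[2], "date"),
    row("gender", d[2], "categorical", cats = c("male", "female")),
    row("birth_weight", d[2], "numeric", 0.4, 6.0),
    row("age_in_days", d[2], "numeric", 0, 28),
    row("gestational_age", d[2], "numeric", 22, 44),
    row("mode_of_delivery", d[2], "categorical",
        cats = c("svd", "caesarean_section", "breech", "assisted")),
    row("apgar_5min", d[2], "numeric", 0, 10),
    row("admission_diagnosis", d[2], "text"),
    row("discharge_date", d[2], "date"),
    row("outcome", d[2], "categorical", cats = c("alive", "dead")),
    row("discharge_diagnosis", d[2], "text"),

    # presenting complaints
    sign_rows(c("fever", "convulsions", "difficulty_breathing", "vomiting",
                "difficulty_feeding", "apnoea"), d[3]),

    # cardinal signs on examination
    sign_rows(c("grunting", "central_cyanosis", "bulging_fontanelle",
                "floppy"), d[4]),

    # other physical examination (7 signs added in 2014)
    row("stridor", d[5], "categorical", cats = yn(), intro = "revised2014"),
    row("bilateral_air_entry", d[5], "categorical", cats = yn(),
        intro = "revised2014"),
    sign_rows(c("crackles", "chest_indrawing", "skin_pinch"), d[5]),
    row("femoral_pulses", d[5], "categorical", cats = yn(),
        intro = "revised2014"),
    row("capillary_refill_time", d[5], "numeric", 0, 10),
    row("heart_murmur", d[5], "categorical", cats = yn(),
        intro = "revised2014"),
    sign_rows("pallor", d[5]),
    row("skin_temperature_gradient", d[5], "categorical", cats = yn(),
        intro = "revised2014"),
    sign_rows(c("eye_infection", "umbilical_infection", "skin_rashes",
                "stiff_neck", "irritability", "jaundice"), d[5]),
    row("gestational_size", d[5], "categorical", cats = c("sga", "aga", "lga"),
        intro = "revised2014"),
    row("severe_wasting", d[5], "categorical", cats = yn(),
        intro = "revised2014"),

    # vital signs
    row("temperature", d[6], "numeric", 30, 42),
    row("respiratory_rate", d[6], "numeric", 10, 120),
    row("heart_rate", d[6], "numeric", 40, 250),
    row("oxygen_saturation", d[6], "numeric", 0, 100, intro = "revised2014")
  )
}

check_dictionary <- function(dict) {
  req <- c("name", "domain", "value_kind", "range_min", "range_max",
           "categories", "introduced_in")
  missing <- setdiff(req, names(dict))
  if (length(missing) > 0) {
    rlang::abort(paste0("dictionary is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(dict$name) > 0) {
    dup <- unique(dict$name[duplicated(dict$name)])
    rlang::abort(paste0("duplicate variable names in dictionary: ",
                        paste(dup, collapse = ", ")))
  }
  bad_dom <- setdiff(unique(dict$domain), nar_domains())
  if (length(bad_dom) > 0) {
    rlang::abort(paste0("unknown domain labels: ",
                        paste(bad_dom, collapse = ", ")))
  }
  bad_ver <- setdiff(unique(dict$introduced_in), nar_versions())
  if (length(bad_ver) > 0) {
    rlang::abort(paste0("unknown schema version tags: ",
                        paste(bad_ver, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(dict$value_kind),
                      c("numeric", "categorical", "date", "text"))
  if (length(bad_kind) > 0) {
    rlang::abort(paste0("unknown value kinds: ",
                        paste(bad_kind, collapse = ", ")))
  }
  # a validity constraint exists iff the kind supports one
  has_range <- !is.na(dict$range_min) | !is.na(dict$range_max)
  has_cats <- !purrr::map_lgl(dict$categories, is.null)
  bad <- (dict$value_kind == "numeric" & !has_range) |
    (dict$value_kind == "categorical" & !has_cats) |
    (dict$value_kind %in% c("date", "text") & (has_range | has_cats)) |
    (dict$value_kind == "numeric" & has_cats) |
    (dict$value_kind == "categorical" & has_range)
  if (any(bad)) {
    rlang::abort(paste0(
      "validity constraints inconsistent with value kind for: ",
      paste(dict$name[bad], collapse = ", ")
    ))
  }
  invisible(dict)
}

#' Load a versioned NAR schema
#'
#' Builds the schema for one version of the newborn admission record. With no
#' `dictionary` argument the default dictionary ([nar_dictionary()]) is used:
#' the `"revised2014"` schema has six domains of sizes 6, 12, 6, 4, 18 and 4
#' (50 variables); the `"baseline"` schema is the subset of variables already
#' on the pre-revision form (36 variables).
#'
#' @param version `"revised2014"` or `"baseline"`.
#' @param dictionary Optional dictionary: a tibble in the [nar_dictionary()]
#'   layout or a path to a YAML dictionary file (see [read_dictionary()]).
#' @return An object of class `nar_schema`: a list with `version`,
#'   `variables` (the dictionary rows applicable to this version) and
#'   `dictionary` (the full dictionary, kept so applicability of later
#'   variables can still be decided).
#' @export
load_schema <- function(version = c("revised2014", "baseline"),
                        dictionary = NULL) {
  if (!is.character(version) || length(version) < 1 ||
      !(version[1] %in% nar_versions())) {
    rlang::abort(paste0("unknown schema version tag: ",
                        paste(utils::head(version, 1), collapse = "")))
  }
  version <- version[1]
  dict <- if (is.null(dictionary)) {
    nar_dictionary()
  } else if (is.character(dictionary)) {
    read_dictionary(dictionary)
  } else {
    tibble::as_tibble(dictionary)
  }
  check_dictionary(dict)
  vars <- if (version == "baseline") {
    dict[dict$introduced_in == "baseline", ]
  } else {
    dict
  }
  structure(
    list(version = version, variables = vars, dictionary = dict),
    class = "nar_schema"
  )
}

#' @export
print.nar_schema <- function(x, ...) {
  cat("<nar_schema> version:", x$version, "\n")
  sizes <- domain_sizes(x)
  for (d in names(sizes)) cat(sprintf("  %-32s %d\n", d, sizes[[d]]))
  cat("  total:", nrow(x$variables), "variables\n")
  invisible(x)
}

#' Number of variables per domain
#'
#' @param schema A `nar_schema`.
#' @return Named integer vector over the six domains (a domain absent from
#'   this version, such as maternal history on the baseline form, counts 0).
#' @export
domain_sizes <- function(schema) {
  stopifnot(inherits(schema, "nar_schema"))
  counts <- table(factor(schema$variables$domain, levels = nar_domains()))
  out <- as.integer(counts)
  names(out) <- nar_domains()
  out
}

#' Write a dictionary to a YAML file
#'
#' Serialises a dictionary (or a schema's full dictionary) as a YAML list of
#' per-variable entries `{name, domain, kind, range, categories,
#' introduced_in}`. [read_dictionary()] inverts it field-for-field.
#'
#' @param dictionary A dictionary tibble or a `nar_schema`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  if (inherits(dictionary, "nar_schema")) dictionary <- dictionary$dictionary
  check_dictionary(dictionary)
  entries <- purrr::pmap(dictionary, function(name, domain, value_kind,
                                              range_min, range_max,
                                              categories, introduced_in) {
    e <- list(name = name, domain = domain, kind = value_kind,
              introduced_in = introduced_in)
    if (!is.na(range_min) || !is.na(range_max)) {
      e$range <- list(min = range_min, max = range_max)
    }
    if (!is.null(categories)) e$categories <- as.list(categories)
    e
  })
  yaml::write_yaml(list(variables = entries), path)
  invisible(path)
}

#' Read a dictionary from a YAML file
#'
#' @param path Path to a YAML file written by [write_dictionary()] or
#'   hand-authored in the same layout.
#' @return A dictionary tibble (see [nar_dictionary()] for the layout).
#' @export
read_dictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$variables)) {
    rlang::abort("dictionary file has no 'variables' key")
  }
  dict <- purrr::map_dfr(raw$variables, function(e) {
    tibble::tibble(
      name = e$name,
      domain = e$domain,
      value_kind = e$kind,
      range_min = if (is.null(e$range$min)) NA_real_ else as.numeric(e$range$min),
      range_max = if (is.null(e$range$max)) NA_real_ else as.numeric(e$range$max),
      categories = list(if (is.null(e$categories)) NULL
                        else as.character(unlist(e$categories))),
      introduced_in = e$introduced_in
    )
  })
  check_dictionary(dict)
  dict
}
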