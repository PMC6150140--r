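# Period binning and binomial interval estimation.

#' Study period configuration
#'
#' Defines the calendar bins and the audit-phase boundary used by all trend
#' reporting. The default scheme is six-month calendar half-years (Jan-Jun =
#' "P1", Jul-Dec = "P2") from the study start to its end, with the first and
#' last bins clipped to the study window, and the pre/post phase boundary at
#' the record-form revision date: dates before it are `pre_AF`, dates on or
#' after it `post_AF`. Note a bin can straddle the boundary (the 2014
#' revision fell inside the first half of 2014); phase attaches to the date,
#' not the bin.
#'
#' @param study_start,study_end Inclusive study window (coerced with
#'   [as.Date()]). Defaults span January 2013 to November 2016.
#' @param revision_date Phase boundary, default `"2014-04-01"`.
#' @param bin_edges Optional explicit bin starts (Date vector, sorted); each
#'   bin runs to the day before the next edge, the last to `study_end`. Use
#'   when calendar half-years are not wanted.
#' @param conf_level Confidence level for interval estimates, default 0.95.
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return A list of class `period_config` with a `bins` tibble
#'   (`label`, `start`, `end`) and the settings.
#' @export
period_config <- function(study_start = "2013-01-01",
                          study_end = "2016-11-30",
                          revision_date = "2014-04-01",
                          bin_edges = NULL,
                          conf_level = 0.95,
                          ci_method = c("wilson", "clopper-pearson")) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  revision_date <- as.Date(revision_date)
  ci_method <- match.arg(ci_method)
  if (is.na(study_start) || is.na(study_end) || study_end < study_start) {
    rlang::abort("study window is empty or unordered")
  }

  if (is.null(bin_edges)) {
    years <- seq(as.integer(format(study_start, "%Y")),
                 as.integer(format(study_end, "%Y")))
    starts <- as.Date(c(outer(c("-01-01", "-07-01"), years,
                              function(s, y) paste0(y, s))))
    starts <- sort(starts)
    labels <- paste0(format(starts, "%Y"),
                     ifelse(format(starts, "%m") == "01", "-P1", "-P2"))
  } else {
    starts <- sort(as.Date(bin_edges))
    labels <- paste0("B", seq_along(starts))
  }
  ends <- c(starts[-1] - 1, as.Date("9999-12-31"))
  keep <- ends >= study_start & starts <= study_end
  bins <- tibble::tibble(label = labels[keep],
                         start = pmax(starts[keep], study_start),
                         end = pmin(ends[keep], study_end))

  structure(
    list(bins = bins, study_start = study_start, study_end = study_end,
         revision_date = revision_date, conf_level = conf_level,
         ci_method = ci_method),
    class = "period_config"
  )
}

#' Assign dates to study periods
#'
#' @param dates Date vector (or coercible).
#' @param config A [period_config()].
#' @return Tibble with one row per date: `date`, `period` (bin label, a
#'   factor ordered by calendar time) and `phase` (`"pre_AF"`/`"post_AF"`).
#'   Dates outside the study window are an error.
#' @export
assign_period <- function(dates, config = period_config()) {
  stopifnot(inherits(config, "period_config"))
  dates <- as.Date(dates)
  out_of_window <- is.na(dates) | dates < config$study_start |
    dates > config$study_end
  if (any(out_of_window)) {
    rlang::abort(sprintf(
      "%d date(s) outside the study window [%s, %s]",
      sum(out_of_window), config$study_start, config$study_end
    ))
  }
  idx <- findInterval(as.numeric(dates), as.numeric(config$bins$start))
  tibble::tibble(
    date = dates,
    period = factor(config$bins$label[idx], levels = config$bins$label),
    phase = factor(ifelse(dates < config$revision_date, "pre_AF", "post_AF"),
                   levels = c("pre_AF", "post_AF"))
  )
}

#' Binomial proportion with a Wilson score interval
#'
#' Point estimate x/n with the Wilson score confidence interval (the interval
#' obtained by inverting the normal score test; well behaved at the 0 and 1
#' boundaries and the method that reproduces the printed intervals of routine
#' audit reports, e.g. 712/7985 -> 8.3% to 9.6% at 95%). A Clopper-Pearson
#' (exact) alternative is available. The reported `point` is always x/n, not
#' the Wilson midpoint. Vectorised over `x` and `n`.
#'
#' @param x Successes (0 <= x <= n).
#' @param n Trials (n >= 1).
#' @param conf_level Confidence level, default 0.95.
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return Tibble with columns `x`, `n`, `point`, `ci_low`, `ci_high`,
#'   `conf_level`, `method`.
#' @export
wilson_interval <- function(x, n, conf_level = 0.95,
                            method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (length(n) == 1) n <- rep(n, length(x))
  if (length(x) == 1) x <- rep(x, length(n))
  stopifnot(length(x) == length(n))
  if (any(n < 1)) rlang::abort("n must be >= 1")
  if (any(x < 0 | x > n)) rlang::abort("x must satisfy 0 <= x <= n")
  p <- x / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- pmax(0, centre - half)
    hi <- pmin(1, centre + half)
    # analytically exact at the boundaries; avoid floating residue
    lo[x == 0] <- 0
    hi[x == n] <- 1
  } else {
    alpha <- 1 - conf_level
    lo <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
    hi <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  }
  tibble::tibble(x = x, n = n, point = p, ci_low = lo, ci_high = hi,
                 conf_level = conf_level, method = method)
}

#' Proportion estimate using a period configuration's settings
#'
#' Convenience wrapper used by the reporting layer: applies the CI method and
#' confidence level stored in a [period_config()].
#'
#' @inheritParams wilson_interval
#' @param config A [period_config()].
#' @return See [wilson_interval()].
#' @export
proportion_estimate <- function(x, n, config = period_config()) {
  wilson_interval(x, n, conf_level = config$conf_level,
                  method = config$ci_method)
}
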