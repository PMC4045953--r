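#' Registry coverage interval
#'
#' The interval of complete data capture for a dispensing registry. All
#' records must fall inside it, and user-classification observability is
#' judged against it: a calendar year is reportable for a given outcome only
#' when the full washout (and, for insulins-only outcomes, the lookforward)
#' window fits inside coverage for every possible anchor date in that year.
#'
#' @param start_date,end_date coverage bounds (`Date` or ISO-8601 strings);
#'   `start_date` must precede `end_date`.
#' @return an object of class `registry_coverage` with elements `start_date`
#'   and `end_date`.
#' @examples
#' registry_coverage("2004-01-01", "2011-12-31")
#' @export
registry_coverage <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date))
    stop("coverage bounds must be valid dates", call. = FALSE)
  if (!start_date < end_date)
    stop("coverage start_date must precede end_date", call. = FALSE)
  structure(list(start_date = start_date, end_date = end_date),
            class = "registry_coverage")
}

#' @export
print.registry_coverage <- function(x, ...) {
  cat("<registry_coverage> ", format(x$start_date), " to ",
      format(x$end_date), "\n", sep = "")
  invisible(x)
}

coverage_years <- function(coverage) {
  seq.int(year_of(coverage$start_date), year_of(coverage$end_date))
}

#' Washout / lookforward window configuration
#'
#' Windows of the new-user design: `washout_months` is the length of the
#' drug-free lookback required before a first fill counts as incident
#' (default 24 months), and `lookforward_months` is the OAD-free follow-up
#' required after a first insulin fill for the insulins-only classification
#' (default 12 months).
#'
#' @param washout_months positive integer, months of required drug-free
#'   history.
#' @param lookforward_months positive integer, months of required OAD-free
#'   follow-up for insulins-only status.
#' @return an object of class `window_config`.
#' @examples
#' window_config()            # 24-month washout, 12-month lookforward
#' window_config(72, 12)      # six-year washout sensitivity analysis
#' @export
window_config <- function(washout_months = 24L, lookforward_months = 12L) {
  washout_months <- as.integer(washout_months)
  lookforward_months <- as.integer(lookforward_months)
  if (is.na(washout_months) || washout_months < 1L)
    stop("washout_months must be a positive integer", call. = FALSE)
  if (is.na(lookforward_months) || lookforward_months < 1L)
    stop("lookforward_months must be a positive integer", call. = FALSE)
  structure(list(washout_months = washout_months,
                 lookforward_months = lookforward_months),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat("<window_config> washout ", x$washout_months, " months, lookforward ",
      x$lookforward_months, " months\n", sep = "")
  invisible(x)
}

#' Year-level observability of outcomes under coverage and windows
#'
#' Determines for each calendar year whether prevalence, incidence, and
#' insulins-only outcomes are fully observable: the washout of the earliest
#' possible anchor (Jan 1) must start at or after coverage start, and for
#' insulins-only outcomes the lookforward of the latest possible anchor
#' (Dec 31) must end at or before coverage end. With the default 24/12-month
#' windows and coverage 2004-2011 this yields prevalence 2004-2011,
#' incidence 2006-2011, and insulins-only outcomes 2006-2010.
#'
#' @param years integer vector of calendar years.
#' @param windows a [window_config()].
#' @param coverage a [registry_coverage()].
#' @return a `data.table` with columns `year`, `observable_prevalence`,
#'   `observable_incidence`, `observable_insulin_only`.
#' @export
observable_years <- function(years, windows, coverage) {
  stopifnot(inherits(windows, "window_config"),
            inherits(coverage, "registry_coverage"))
  years <- as.integer(years)
  in_cov <- jan1(years) >= coverage$start_date & dec31(years) <= coverage$end_date
  washout_ok <- shift_months(jan1(years), -windows$washout_months) >=
    coverage$start_date
  lookfwd_ok <- shift_months(dec31(years), windows$lookforward_months) <=
    coverage$end_date
  data.table(
    year = years,
    observable_prevalence = in_cov,
    observable_incidence = in_cov & washout_ok,
    observable_insulin_only = in_cov & washout_ok & lookfwd_ok
  )
}
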