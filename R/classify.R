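#' First fill of a drug class within a calendar year
#'
#' @param history dispensing records for one person, sorted by date.
#' @param year calendar year.
#' @param drug_class `"ANY_A10"` (any blood glucose-lowering drug),
#'   `"INSULIN"` (A10A) or `"OAD"` (A10B).
#' @return the earliest matching `dispense_date` in the year, or `NA` when
#'   there is none.
#' @export
first_fill_in_year <- function(history, year,
                               drug_class = c("ANY_A10", "INSULIN", "OAD")) {
  drug_class <- match.arg(drug_class)
  check_sorted_history(history)
  if (nrow(history) == 0L) return(as.Date(NA))
  cls <- classify_atc(history$atc_code)
  keep <- if (drug_class == "ANY_A10") cls != "OTHER" else cls == drug_class
  d <- as.Date(history$dispense_date)[keep & year_of(as.Date(history$dispense_date)) == year]
  if (length(d)) min(d) else as.Date(NA)
}

check_sorted_history <- function(history) {
  if (nrow(history) && is.unsorted(as.Date(history$dispense_date)))
    stop("history must be sorted by dispense_date", call. = FALSE)
  invisible(TRUE)
}

## last event date strictly before each query date (NA when none);
## events must be keyed on (person_id, date) and carry date2 = date
roll_last_before <- function(events, ids, dates) {
  out <- rep(as.Date(NA), length(ids))
  ok <- !is.na(dates)
  if (!any(ok) || nrow(events) == 0L) return(out)
  q <- data.table(person_id = ids[ok], date = dates[ok] - 1L)
  out[ok] <- events[q, on = c("person_id", "date"), roll = Inf, x.date2]
  out
}

## first event date at or after each query date (NA when none)
roll_first_at_or_after <- function(events, ids, dates) {
  out <- rep(as.Date(NA), length(ids))
  ok <- !is.na(dates)
  if (!any(ok) || nrow(events) == 0L) return(out)
  q <- data.table(person_id = ids[ok], date = dates[ok])
  out[ok] <- events[q, on = c("person_id", "date"), roll = -Inf, x.date2]
  out
}

empty_status <- function() {
  data.table(
    person_id = character(), year = integer(), sex = character(),
    birth_year = integer(), age = integer(),
    age_band = factor(character(), levels = levels(age_band(integer()))),
    prevalent_any = logical(), prevalent_oad = logical(),
    prevalent_insulin_only = logical(),
    incident_any = logical(), incident_oad = logical(),
    incident_insulin_only = logical(),
    anchor_any = as.Date(character()), anchor_oad = as.Date(character()),
    anchor_insulin = as.Date(character()),
    observable_prevalence = logical(), observable_incidence = logical(),
    observable_insulin_only = logical()
  )
}

#' Classify prevalent and incident drug users for every person and year
#'
#' Applies the new-user design to a dispensing registry. For each person and
#' calendar year:
#'
#' * `prevalent_any` / `prevalent_oad`: at least one fill of any blood
#'   glucose-lowering drug (ATC A10) / of an OAD (A10B) in the year.
#' * `prevalent_insulin_only`: at least one insulin (A10A) fill in the year
#'   and no OAD fill in the closed window from `washout_months` before to
#'   `lookforward_months` after the first insulin fill of the year (the
#'   anchor). An OAD fill on the anchor date itself counts as combination
#'   therapy and disqualifies.
#' * `incident_any`: the first A10 fill of the year is preceded by no A10
#'   fill in the half-open washout `[anchor - washout, anchor)`.
#' * `incident_oad`: as above, anchored at the first OAD fill of the year;
#'   any A10 fill (insulin included) inside the washout disqualifies.
#' * `incident_insulin_only`: the first insulin fill of the year has a clean
#'   A10 washout and no OAD fill in `[anchor, anchor + lookforward]`.
#'
#' A person may be incident in more than one year when a gap of at least the
#' washout length recurs between treatment episodes. Flags whose windows
#' extend beyond registry coverage are returned as `NA` together with
#' year-level observability indicators (see [observable_years()]).
#'
#' @param records dispensing records (as from [read_dispensings()]); input
#'   ordering is irrelevant. Non-A10 records are ignored.
#' @param years calendar years to evaluate; defaults to all coverage years.
#' @param windows a [window_config()].
#' @param coverage a [registry_coverage()].
#' @return a `data.table` with one row per person and evaluated year:
#'   identifiers (`person_id`, `sex`, `birth_year`, attained `age`,
#'   `age_band`), six classification flags, three anchor dates, and three
#'   observability indicators.
#' @examples
#' cov <- registry_coverage("2004-01-01", "2011-12-31")
#' rec <- data.frame(person_id = "P1", dispense_date = "2008-03-10",
#'                   atc_code = "A10BA02", sex = "female", birth_year = 1950)
#' classify_registry(rec, windows = window_config(), coverage = cov)
#' @export
classify_registry <- function(records, years = NULL,
                              windows = window_config(), coverage) {
  stopifnot(inherits(windows, "window_config"),
            inherits(coverage, "registry_coverage"))
  if (is.null(years)) years <- coverage_years(coverage)
  years <- sort(unique(as.integer(years)))

  rec <- as.data.table(records)
  if (nrow(rec) == 0L) return(empty_status())
  rec <- rec[, DISPENSING_COLS, with = FALSE]
  rec[, dispense_date := as.Date(dispense_date)]
  rec[, drug_class := classify_atc(atc_code)]

  persons <- rec[order(person_id, dispense_date),
                 .(sex = sex[1L], birth_year = birth_year[1L]),
                 by = person_id]
  st <- persons[, .(year = years), by = .(person_id, sex, birth_year)]

  a10 <- rec[drug_class != "OTHER"]
  a10[, year := year_of(dispense_date)]

  anch <- function(sub) {
    sub <- sub[year %in% years]
    if (nrow(sub) == 0L)
      return(data.table(person_id = character(), year = integer(),
                        anchor = as.Date(character())))
    sub[, .(anchor = min(dispense_date)), by = .(person_id, year)]
  }
  st <- merge(st, setnames(anch(a10), "anchor", "anchor_any"),
              by = c("person_id", "year"), all.x = TRUE)
  st <- merge(st, setnames(anch(a10[drug_class == "OAD"]), "anchor", "anchor_oad"),
              by = c("person_id", "year"), all.x = TRUE)
  st <- merge(st, setnames(anch(a10[drug_class == "INSULIN"]), "anchor", "anchor_insulin"),
              by = c("person_id", "year"), all.x = TRUE)

  ev <- function(sub) {
    e <- sub[, .(person_id, date = dispense_date)]
    e[, date2 := date]
    setkey(e, person_id, date)
    e
  }
  ev_a10 <- ev(a10)
  ev_oad <- ev(a10[drug_class == "OAD"])

  w <- windows$washout_months
  l <- windows$lookforward_months

  st[, prevalent_any := !is.na(anchor_any)]
  st[, prevalent_oad := !is.na(anchor_oad)]

  last_any <- roll_last_before(ev_a10, st$person_id, st$anchor_any)
  st[, incident_any := prevalent_any &
       (is.na(last_any) | last_any < shift_months(anchor_any, -w))]

  last_before_oad <- roll_last_before(ev_a10, st$person_id, st$anchor_oad)
  st[, incident_oad := prevalent_oad &
       (is.na(last_before_oad) | last_before_oad < shift_months(anchor_oad, -w))]

  ins_wstart <- shift_months(st$anchor_insulin, -w)
  ins_wend <- shift_months(st$anchor_insulin, l)
  first_oad_win <- roll_first_at_or_after(ev_oad, st$person_id, ins_wstart)
  st[, prevalent_insulin_only := !is.na(anchor_insulin) &
       (is.na(first_oad_win) | first_oad_win > ins_wend)]

  last_before_ins <- roll_last_before(ev_a10, st$person_id, st$anchor_insulin)
  first_oad_fwd <- roll_first_at_or_after(ev_oad, st$person_id, st$anchor_insulin)
  st[, incident_insulin_only := !is.na(anchor_insulin) &
       (is.na(last_before_ins) | last_before_ins < ins_wstart) &
       (is.na(first_oad_fwd) | first_oad_fwd > ins_wend)]

  obs <- observable_years(years, windows, coverage)
  st <- merge(st, obs, by = "year")

  st[observable_prevalence == FALSE,
     `:=`(prevalent_any = NA, prevalent_oad = NA)]
  st[observable_insulin_only == FALSE, prevalent_insulin_only := NA]
  st[observable_incidence == FALSE, `:=`(incident_any = NA, incident_oad = NA)]
  st[observable_incidence == FALSE | observable_insulin_only == FALSE,
     incident_insulin_only := NA]

  st[, age := year - birth_year]
  st[, age_band := age_band(pmax(age, 0L))]
  setcolorder(st, names(empty_status()))
  setorder(st, person_id, year)
  st[]
}

#' Classify prevalence flags for one person-year
#'
#' Single-history convenience wrapper around [classify_registry()]; the
#' history must be sorted by `dispense_date` (contract error otherwise).
#'
#' @inheritParams first_fill_in_year
#' @param windows a [window_config()].
#' @param coverage a [registry_coverage()].
#' @return a one-row list with prevalence flags, anchor dates and
#'   observability indicators.
#' @export
classify_prevalent <- function(history, year, windows = window_config(),
                               coverage) {
  check_sorted_history(history)
  st <- classify_registry(history, years = year, windows = windows,
                          coverage = coverage)
  cols <- c("person_id", "year", "prevalent_any", "prevalent_oad",
            "prevalent_insulin_only", "anchor_any", "anchor_oad",
            "anchor_insulin", "observable_prevalence",
            "observable_insulin_only")
  as.list(st[, cols, with = FALSE])
}

#' Classify incidence flags for one person-year
#'
#' @inheritParams classify_prevalent
#' @return a one-row list with incidence flags, anchor dates and
#'   observability indicators.
#' @export
classify_incident <- function(history, year, windows = window_config(),
                              coverage) {
  check_sorted_history(history)
  st <- classify_registry(history, years = year, windows = windows,
                          coverage = coverage)
  cols <- c("person_id", "year", "incident_any", "incident_oad",
            "incident_insulin_only", "anchor_any", "anchor_oad",
            "anchor_insulin", "observable_incidence",
            "observable_insulin_only")
  as.list(st[, cols, with = FALSE])
}
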