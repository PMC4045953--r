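#' Washout sensitivity sweep
#'
#' Re-runs the user classification for one target year under a list of
#' window configurations and tabulates the prevalent insulins-only count and
#' the incident counts per window. Extending the washout can only remove
#' users, so counts are non-increasing in `washout_months`; in registries
#' with OAD-to-insulin switchers whose OAD history ends more than the
#' default washout before the insulin start, longer washouts give strictly
#' smaller insulins-only counts.
#'
#' Windows whose spans exceed registry coverage for the target year are
#' flagged `observable_* = FALSE` and their counts reported as `NA`, never
#' silently dropped.
#'
#' @param records dispensing records.
#' @param year target calendar year.
#' @param windows_list list of [window_config()] objects.
#' @param coverage a [registry_coverage()].
#' @return a `data.table` with one row per window: the window parameters,
#'   observability flags, and counts `prevalent_insulin_only`,
#'   `incident_any`, `incident_oad`, `incident_insulin_only`.
#' @export
sensitivity_sweep <- function(records, year, windows_list, coverage) {
  stopifnot(length(year) == 1L)
  if (inherits(windows_list, "window_config")) windows_list <- list(windows_list)
  rows <- lapply(windows_list, function(wc) {
    stopifnot(inherits(wc, "window_config"))
    obs <- observable_years(year, wc, coverage)
    st <- classify_registry(records, years = year, windows = wc,
                            coverage = coverage)
    cnt <- function(col, ok) {
      if (!ok) return(NA_integer_)
      if (nrow(st) == 0L) return(0L)
      sum(st[[col]], na.rm = TRUE)
    }
    ok_io <- obs$observable_insulin_only
    ok_inc <- obs$observable_incidence
    data.table(
      washout_months = wc$washout_months,
      lookforward_months = wc$lookforward_months,
      observable_incidence = ok_inc,
      observable_insulin_only = ok_io,
      prevalent_insulin_only = cnt("prevalent_insulin_only", ok_io),
      incident_any = cnt("incident_any", ok_inc),
      incident_oad = cnt("incident_oad", ok_inc),
      incident_insulin_only = cnt("incident_insulin_only", ok_inc && ok_io)
    )
  })
  rbindlist(rows)
}

class_filter <- function(cls, group) {
  switch(group,
         any = cls != "OTHER",
         oad = cls == "OAD",
         insulin_only = cls == "INSULIN",
         stop("unknown group: ", group, call. = FALSE))
}

anchor_col <- function(group) {
  switch(group, any = "anchor_any", oad = "anchor_oad",
         insulin_only = "anchor_insulin")
}

#' Treatment persistence among incident users
#'
#' Fraction of incident users who redeemed more than one prescription of the
#' defining drug class within `months` months of their first fill (the
#' anchor fill counts as the first prescription). Only users whose full
#' follow-up window lies inside registry coverage are evaluated; groups with
#' no eligible incident users yield `NA`.
#'
#' @param statuses classification table from [classify_registry()]; filter
#'   it beforehand to restrict to a year or stratum.
#' @param records the dispensing records the statuses were derived from.
#' @param months follow-up length in months (default 12).
#' @param coverage a [registry_coverage()].
#' @param groups which incident groups to evaluate.
#' @return a `data.table` with columns `group`, `n_incident`,
#'   `n_persistent`, `fraction`.
#' @export
persistence_fraction <- function(statuses, records, months = 12L, coverage,
                                 groups = c("any", "oad", "insulin_only")) {
  rec <- as.data.table(records)
  rec[, dispense_date := as.Date(dispense_date)]
  cls <- classify_atc(rec$atc_code)
  st <- as.data.table(statuses)
  rows <- lapply(groups, function(g) {
    flag <- paste0("incident_", g)
    users <- data.table(person_id = st$person_id, year = st$year,
                        anchor = as.Date(st[[anchor_col(g)]]))
    users <- users[st[[flag]] %in% TRUE]
    users[, wend := shift_months(anchor, months)]
    users <- users[wend <= coverage$end_date]
    if (nrow(users) == 0L)
      return(data.table(group = g, n_incident = 0L, n_persistent = NA_integer_,
                        fraction = NA_real_))
    fills <- rec[class_filter(cls, g), .(person_id, date = dispense_date)]
    cnt <- fills[users, on = "person_id", allow.cartesian = TRUE][
      date >= anchor & date <= wend, .N, by = .(person_id, year)]
    n_persistent <- sum(cnt$N >= 2L)
    data.table(group = g, n_incident = nrow(users),
               n_persistent = n_persistent,
               fraction = n_persistent / nrow(users))
  })
  rbindlist(rows)
}

#' Insulin discontinuation among incident insulins-only users
#'
#' Fraction of incident insulins-only users who had stopped insulin
#' treatment within `horizon_months` of their first insulin fill, where
#' "stopped" means no insulin fill during the final `tail_months` of the
#' horizon, i.e. in the half-open window
#' `(anchor + horizon - tail, anchor + horizon]`. Among women of
#' reproductive age this fraction is dominated by gestational diabetes.
#'
#' Only users whose full horizon lies inside coverage are evaluated; an
#' empty stratum yields `NA`.
#'
#' @inheritParams persistence_fraction
#' @param horizon_months total follow-up horizon in months (default 24).
#' @param tail_months length of the fill-free tail defining "stopped"
#'   (default 12).
#' @param year,sex,age_range optional stratum filters applied to `statuses`
#'   (e.g. `year = 2008, sex = "female", age_range = c(30, 39)`).
#' @return a one-row `data.table` with `n_incident`, `n_stopped`,
#'   `fraction`.
#' @export
discontinuation_fraction <- function(statuses, records, horizon_months = 24L,
                                     tail_months = 12L, coverage,
                                     year = NULL, sex = NULL,
                                     age_range = NULL) {
  stopifnot(tail_months <= horizon_months)
  st <- as.data.table(statuses)
  keep <- rep(TRUE, nrow(st))
  if (!is.null(year)) keep <- keep & st[["year"]] %in% year
  if (!is.null(sex)) keep <- keep & st[["sex"]] %in% sex
  if (!is.null(age_range)) keep <- keep & st[["age"]] >= age_range[1L] &
      st[["age"]] <= age_range[2L]
  st <- st[keep]
  users <- st[incident_insulin_only %in% TRUE,
              .(person_id, year, anchor = anchor_insulin)]
  users[, wend := shift_months(anchor, horizon_months)]
  users[, wstart := shift_months(anchor, horizon_months - tail_months)]
  users <- users[wend <= coverage$end_date]
  if (nrow(users) == 0L)
    return(data.table(n_incident = 0L, n_stopped = NA_integer_,
                      fraction = NA_real_))
  rec <- as.data.table(records)
  rec[, dispense_date := as.Date(dispense_date)]
  ins <- rec[classify_atc(rec$atc_code) == "INSULIN",
             .(person_id, date = dispense_date)]
  cnt <- ins[users, on = "person_id", allow.cartesian = TRUE][
    !is.na(date) & date > wstart & date <= wend, .N, by = .(person_id, year)]
  active <- unique(cnt[, .(person_id, year)])
  n_stopped <- nrow(users) - nrow(merge(users, active, by = c("person_id", "year")))
  data.table(n_incident = nrow(users), n_stopped = n_stopped,
             fraction = n_stopped / nrow(users))
}
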