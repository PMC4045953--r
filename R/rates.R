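#' Person-years at risk from annual population counts
#'
#' Person-years for a calendar year and stratum are estimated as the
#' arithmetic mean of the Jan 1 population counts of that year and the next,
#' summed over the stratum.
#'
#' @param pop population counts (columns `year`, `sex`, `age`, `count`;
#'   `year` refers to Jan 1).
#' @param year calendar year.
#' @param sex optional `"female"`/`"male"` filter; `NULL` for both.
#' @param age_min,age_max optional attained-age bounds (inclusive).
#' @return a positive scalar.
#' @examples
#' pop <- data.frame(year = c(2010, 2011), sex = "female", age = 40,
#'                   count = c(100, 102))
#' person_years(pop, 2010)  # 101
#' @export
person_years <- function(pop, year, sex = NULL, age_min = 0, age_max = Inf) {
  p <- as.data.table(pop)
  stratum <- paste0(if (is.null(sex)) "both sexes" else sex,
                    ", ages ", age_min, "-", age_max)
  one <- function(y) {
    sub <- p[p$year == y]
    if (nrow(sub) == 0L)
      stop("population counts missing for Jan 1 ", y, " (stratum ", stratum,
           ")", call. = FALSE)
    keep <- sub[["age"]] >= age_min & sub[["age"]] <= age_max
    if (!is.null(sex)) keep <- keep & sub[["sex"]] %in% sex
    sum(sub$count[keep])
  }
  (one(year) + one(year + 1L)) / 2
}

#' Incidence rate per 100,000 person-years with 95% confidence interval
#'
#' Rate = count / person-years x 100,000. The default confidence interval is
#' a normal (Wald) approximation on the rate scale,
#' `rate * (1 +/- z / sqrt(count))`, truncated at zero below; `"log"` gives
#' the Wald interval on the log-rate scale, `rate * exp(+/- z / sqrt(count))`.
#' A zero count yields `ci_low = 0` and `ci_high` from the rule of three,
#' `3 / person_years * 1e5`.
#'
#' @param count non-negative event counts.
#' @param person_years positive person-year denominators.
#' @param alpha two-sided significance level (default 0.05).
#' @param ci_method `"wald"` (rate scale, default) or `"log"`.
#' @return a `data.table` with columns `count`, `person_years`, `rate`,
#'   `ci_low`, `ci_high` (all per 100,000 person-years, full precision).
#' @examples
#' incidence_rate(15515, 4953217)  # 313 (308, 318) after integer rounding
#' @export
incidence_rate <- function(count, person_years, alpha = 0.05,
                           ci_method = c("wald", "log")) {
  ci_method <- match.arg(ci_method)
  if (any(person_years <= 0)) stop("person_years must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  n <- pmax(length(count), length(person_years))
  count <- rep_len(count, n)
  person_years <- rep_len(person_years, n)
  z <- qnorm(1 - alpha / 2)
  rate <- count / person_years * 1e5
  if (ci_method == "wald") {
    half <- z / sqrt(count)
    lo <- pmax(rate * (1 - half), 0)
    hi <- rate * (1 + half)
  } else {
    lo <- rate * exp(-z / sqrt(count))
    hi <- rate * exp(z / sqrt(count))
  }
  zero <- count == 0
  lo[zero] <- 0
  hi[zero] <- 3 / person_years[zero] * 1e5
  data.table(count = count, person_years = person_years, rate = rate,
             ci_low = lo, ci_high = hi)
}

#' Prevalence proportion
#'
#' @param count non-negative user counts.
#' @param population positive population denominators (mean annual
#'   population of the stratum).
#' @return a `data.table` with columns `count`, `population`, `percent`
#'   (full precision).
#' @examples
#' prevalence(31515, 4888946)  # 0.64% after rounding to 2 decimals
#' @export
prevalence <- function(count, population) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  data.table(count = count, population = population,
             percent = count / population * 100)
}

band_range <- function(label) {
  if (grepl("\\+$", label)) c(as.numeric(sub("\\+$", "", label)), Inf)
  else as.numeric(strsplit(label, "-", fixed = TRUE)[[1L]])
}

outcome_flag <- function(measure, outcome) {
  paste0(if (measure == "incidence") "incident_" else "prevalent_", outcome)
}

outcome_observable <- function(measure, outcome, obs_row) {
  if (outcome == "insulin_only") {
    if (measure == "incidence")
      obs_row$observable_incidence && obs_row$observable_insulin_only
    else obs_row$observable_insulin_only
  } else {
    if (measure == "incidence") obs_row$observable_incidence
    else obs_row$observable_prevalence
  }
}

#' Tabulate incidence rates or prevalence by year, stratum and outcome
#'
#' Builds the report table of the new-user analysis: one cell per calendar
#' year, stratum and outcome (`any` A10 drug, `oad`, `insulin_only`), with
#' counts, person-year (or mean population) denominators and either
#' incidence rates with confidence intervals or prevalence percentages.
#' Year/outcome combinations whose windows are not fully observable under
#' registry coverage are emitted with `observable = FALSE` and `NA`
#' measures, mirroring the explicit footnote marker of published tables.
#'
#' @param statuses classification table from [classify_registry()].
#' @param pop population counts (columns `year`, `sex`, `age`, `count`);
#'   must include Jan 1 of the year after the last reported year.
#' @param years years to report; defaults to all years present in
#'   `statuses`.
#' @param outcomes subset of `c("any", "oad", "insulin_only")`.
#' @param measure `"incidence"` or `"prevalence"`.
#' @param strata `"sex"` (rows for women, men and total) or `"sex_age"`
#'   (rows for every sex by 10-year age band combination).
#' @param alpha,ci_method passed to [incidence_rate()].
#' @return a `data.table` with columns `year`, `sex`, `age_band`,
#'   `outcome`, `count`, `person_years`, `rate`/`percent`, `ci_low`,
#'   `ci_high` (incidence only) and `observable`.
#' @export
make_table <- function(statuses, pop, years = NULL,
                       outcomes = c("any", "oad", "insulin_only"),
                       measure = c("incidence", "prevalence"),
                       strata = c("sex", "sex_age"),
                       alpha = 0.05, ci_method = "wald") {
  measure <- match.arg(measure)
  strata <- match.arg(strata)
  st <- as.data.table(statuses)
  if (is.null(years)) years <- sort(unique(st$year))
  years <- as.integer(years)

  obs_tab <- unique(st[, .(year, observable_prevalence, observable_incidence,
                           observable_insulin_only)])
  bands <- levels(age_band(integer()))
  sexes <- if (strata == "sex") list(list(sex = "female", band = NA),
                                     list(sex = "male", band = NA),
                                     list(sex = NULL, band = NA))
  else unlist(lapply(SEX_LEVELS, function(s)
    lapply(bands, function(b) list(sex = s, band = b))), recursive = FALSE)

  rows <- list()
  for (y in years) {
    obs_row <- obs_tab[year == y]
    if (nrow(obs_row) == 0L)   # no status rows for this year: assume observable
      obs_row <- data.table(year = y, observable_prevalence = TRUE,
                            observable_incidence = TRUE,
                            observable_insulin_only = TRUE)
    for (sx in sexes) {
      ar <- if (is.na(sx$band[1L])) c(0, Inf) else band_range(sx$band)
      py <- person_years(pop, y, sex = sx$sex, age_min = ar[1L],
                         age_max = ar[2L])
      sel <- st$year == y
      if (!is.null(sx$sex)) sel <- sel & st$sex == sx$sex
      if (!is.na(sx$band[1L])) sel <- sel & as.character(st$age_band) == sx$band
      sub <- st[sel]
      for (oc in outcomes) {
        ok <- outcome_observable(measure, oc, obs_row)
        cnt <- if (ok) sum(sub[[outcome_flag(measure, oc)]], na.rm = TRUE)
        else NA_integer_
        base <- data.table(year = y,
                           sex = if (is.null(sx$sex)) "total" else sx$sex,
                           age_band = as.character(sx$band),
                           outcome = oc, count = cnt, person_years = py,
                           observable = ok)
        if (measure == "incidence") {
          if (ok) {
            r <- incidence_rate(cnt, py, alpha = alpha, ci_method = ci_method)
            base[, `:=`(rate = r$rate, ci_low = r$ci_low, ci_high = r$ci_high)]
          } else base[, `:=`(rate = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_)]
        } else {
          base[, percent := if (ok) cnt / py * 100 else NA_real_]
        }
        rows[[length(rows) + 1L]] <- base
      }
    }
  }
  out <- rbindlist(rows)
  setcolorder(out, c("year", "sex", "age_band", "outcome", "count",
                     "person_years"))
  out[]
}
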