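#' Shift dates by whole calendar months
#'
#' Moves each date by `months` calendar months, keeping the day of month and
#' clamping to the last day of the target month when the source day does not
#' exist there (e.g. 2010-01-31 shifted by +1 month gives 2010-02-28).
#'
#' Washout and lookforward windows are denominated in months, so window
#' arithmetic uses calendar-month shifts rather than a fixed day count; the
#' clamping rule makes the shift well defined for every date and exactly
#' reproducible.
#'
#' @param dates a `Date` vector (NAs pass through).
#' @param months integer number of months to shift; negative shifts backwards.
#' @return a `Date` vector of the same length.
#' @examples
#' shift_months(as.Date("2010-05-01"), -24)  # 2008-05-01
#' shift_months(as.Date("2008-03-31"), -1)   # 2008-02-29 (leap year clamp)
#' @export
shift_months <- function(dates, months) {
  stopifnot(inherits(dates, "Date"), length(months) == 1L,
            is.finite(months), months == as.integer(months))
  out <- rep(as.Date(NA), length(dates))
  ok <- !is.na(dates)
  if (!any(ok)) return(out)
  lt <- as.POSIXlt(dates[ok])
  m0 <- lt$year * 12L + lt$mon + as.integer(months)
  yy <- m0 %/% 12L + 1900L
  mm <- m0 %% 12L + 1L
  dd <- pmin(lt$mday, days_in_month(yy, mm))
  out[ok] <- as.Date(sprintf("%04d-%02d-%02d", yy, mm, dd))
  out
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | (year %% 400L == 0L)
  d[month == 2L & leap] <- 29L
  d
}

year_of <- function(dates) as.POSIXlt(dates)$year + 1900L

jan1 <- function(year) as.Date(sprintf("%04d-01-01", year))
dec31 <- function(year) as.Date(sprintf("%04d-12-31", year))

#' Assign ages to age bands
#'
#' Default banding is the 10-year grouping 0-9, 10-19, ..., 70-79, 80+
#' used for stratified incidence reporting.
#'
#' @param age integer vector of attained ages (years).
#' @param width band width in years.
#' @param top lower bound of the open-ended top band.
#' @return a factor with one level per band, in age order.
#' @export
age_band <- function(age, width = 10L, top = 80L) {
  stopifnot(all(is.na(age) | (age >= 0 & age <= 120)))
  lo <- seq(0L, top, by = width)
  labs <- c(paste0(head(lo, -1L), "-", head(lo, -1L) + width - 1L),
            paste0(top, "+"))
  cut(age, breaks = c(lo, Inf), labels = labs, right = FALSE)
}

## round half away from zero (display convention for rates and percentages)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
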