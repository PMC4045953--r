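## ---- small display-rounding helpers (independent of the package) -----------

round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
round_half_away_int <- function(x) as.integer(round_half_away(x))

## ---- fixture builders ------------------------------------------------------

COV <- registry_coverage("2004-01-01", "2011-12-31")

rec_tab <- function(person_id, dispense_date, atc_code,
                    sex = "female", birth_year = 1960L) {
  if (length(dispense_date) == 0L)
    return(data.frame(person_id = character(), dispense_date = as.Date(character()),
                      atc_code = character(), sex = character(),
                      birth_year = integer(), stringsAsFactors = FALSE))
  data.frame(person_id = person_id,
             dispense_date = as.Date(dispense_date),
             atc_code = atc_code, sex = sex, birth_year = birth_year,
             stringsAsFactors = FALSE)
}

## random registry with arbitrary fill patterns (edge cases included:
## same-day fills, non-A10 co-medication, multi-year gaps)
random_registry <- function(n_persons, coverage = COV) {
  codes <- c("A10AB01", "A10AC01", "A10BA02", "A10BB01", "C10AA05", "N02BE01")
  span <- as.integer(coverage$end_date - coverage$start_date)
  rows <- lapply(seq_len(n_persons), function(i) {
    k <- stats::rpois(1, 4) + 1L
    d <- coverage$start_date + sample.int(span + 1L, k, replace = TRUE) - 1L
    rec_tab(sprintf("R%03d", i), sort(d),
            sample(codes, k, replace = TRUE,
                   prob = c(.2, .1, .3, .15, .15, .1)),
            sex = sample(c("female", "male"), 1L),
            birth_year = sample(1920:2005, 1L))
  })
  do.call(rbind, rows)
}

## ---- independent month-shift (stepwise, clamped) ---------------------------

naive_shift_months <- function(date, k) {
  if (is.na(date)) return(as.Date(NA))
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L; m <- lt$mon + 1L; d <- lt$mday
  step <- if (k >= 0) 1L else -1L
  for (i in seq_len(abs(k))) {
    m <- m + step
    if (m == 13L) { m <- 1L; y <- y + 1L }
    if (m == 0L) { m <- 12L; y <- y - 1L }
  }
  mlen <- c(31, if ((y %% 4 == 0 && y %% 100 != 0) || y %% 400 == 0) 29 else 28,
            31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
  as.Date(sprintf("%04d-%02d-%02d", y, m, min(d, mlen)))
}

## ---- naive full-scan classification oracle ---------------------------------

## literal window definitions scanned over the entire history, one
## person-year at a time; deliberately slow and simple
oracle_classify <- function(records, years, windows, coverage) {
  w <- windows$washout_months; l <- windows$lookforward_months
  cls <- classify_atc(records$atc_code)
  records <- records[cls != "OTHER", , drop = FALSE]
  cls <- cls[cls != "OTHER"]
  yr_start <- as.Date(sprintf("%04d-01-01", years))
  yr_end <- as.Date(sprintf("%04d-12-31", years))

  obs_prev <- yr_start >= coverage$start_date & yr_end <= coverage$end_date
  obs_inc <- obs_prev &
    mapply(function(y) naive_shift_months(y, -w) >= coverage$start_date,
           yr_start)
  obs_io <- obs_inc &
    mapply(function(y) naive_shift_months(y, l) <= coverage$end_date, yr_end)

  persons <- unique(records$person_id)
  rows <- list()
  for (p in sort(persons)) {
    pi <- records$person_id == p
    d <- as.Date(records$dispense_date[pi])
    pc <- cls[pi]
    d_oad <- d[pc == "OAD"]; d_ins <- d[pc == "INSULIN"]
    for (j in seq_along(years)) {
      in_year <- d >= yr_start[j] & d <= yr_end[j]
      a_any <- if (any(in_year)) min(d[in_year]) else as.Date(NA)
      a_oad <- if (any(in_year & pc == "OAD"))
        min(d[in_year & pc == "OAD"]) else as.Date(NA)
      a_ins <- if (any(in_year & pc == "INSULIN"))
        min(d[in_year & pc == "INSULIN"]) else as.Date(NA)

      washout_clean <- function(anchor)
        !any(d >= naive_shift_months(anchor, -w) & d < anchor)
      p_any <- !is.na(a_any)
      p_oad <- !is.na(a_oad)
      p_io <- !is.na(a_ins) &&
        !any(d_oad >= naive_shift_months(a_ins, -w) &
               d_oad <= naive_shift_months(a_ins, l))
      i_any <- p_any && washout_clean(a_any)
      i_oad <- p_oad && washout_clean(a_oad)
      i_io <- !is.na(a_ins) && washout_clean(a_ins) &&
        !any(d_oad >= a_ins & d_oad <= naive_shift_months(a_ins, l))

      rows[[length(rows) + 1L]] <- data.frame(
        person_id = p, year = years[j],
        prevalent_any = if (obs_prev[j]) p_any else NA,
        prevalent_oad = if (obs_prev[j]) p_oad else NA,
        prevalent_insulin_only = if (obs_io[j]) p_io else NA,
        incident_any = if (obs_inc[j]) i_any else NA,
        incident_oad = if (obs_inc[j]) i_oad else NA,
        incident_insulin_only = if (obs_inc[j] && obs_io[j]) i_io else NA,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

FLAG_COLS <- c("prevalent_any", "prevalent_oad", "prevalent_insulin_only",
               "incident_any", "incident_oad", "incident_insulin_only")

expect_matches_oracle <- function(records, years, windows, coverage = COV) {
  got <- as.data.frame(classify_registry(records, years = years,
                                         windows = windows,
                                         coverage = coverage))
  want <- oracle_classify(records, years, windows, coverage)
  got <- got[got$person_id %in% want$person_id,
             c("person_id", "year", FLAG_COLS)]
  got <- got[order(got$person_id, got$year), ]
  want <- want[order(want$person_id, want$year), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}

## ---- independent Newton-Raphson maximiser for the Poisson likelihood -------

newton_poisson <- function(X, y, offset = rep(0, length(y)),
                           tol = 1e-12, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    grad <- drop(t(X) %*% (y - mu))
    hess <- -t(X * mu) %*% X
    delta <- solve(hess, -grad)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  beta
}

## small Poisson cell table at report scale (bands x sexes x years)
sim_cell_table <- function(n_years = 6L, bands = 4L, base_rate = 3e-3,
                           irr = 1.0, py = 2e5, interaction = rep(0, bands)) {
  g <- expand.grid(year = seq_len(n_years), band = seq_len(bands),
                   sex = c("female", "male"))
  g$year_c <- g$year - mean(range(g$year))
  band_mult <- seq(0.5, 2.5, length.out = bands)
  mu <- py * base_rate * band_mult[g$band] *
    (irr * exp(interaction[g$band]))^g$year_c *
    ifelse(g$sex == "male", 1.15, 1)
  g$count <- stats::rpois(nrow(g), mu)
  g$person_years <- py
  g$age_band <- factor(g$band)
  g
}
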