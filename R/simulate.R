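OAD_CODES <- c(A10BA02 = 0.60, A10BB01 = 0.15, A10BG03 = 0.10, A10BH01 = 0.15)
INSULIN_CODES <- c(A10AB01 = 0.30, A10AC01 = 0.30, A10AD01 = 0.20,
                   A10AE04 = 0.20)

default_pyramid <- function() {
  ## stationary decade weights, roughly a western-European age structure
  dec_w <- c(12.5, 13, 13, 14, 14, 12, 10, 7, 4.5)
  data.table(age = 0:89, weight = rep(dec_w / 10, each = 10L))
}

default_onset_rate <- function() {
  ## drug-treated diabetes onset per 100,000 person-years: dominated by
  ## Type 2 (OAD) onsets rising with age, small insulin-only (Type 1)
  ## component in the young; overall crude rate ~ 300 per 100,000
  bands <- levels(age_band(integer()))
  data.table(
    age_band = rep(bands, 2L),
    sex = rep(c("female", "male"), each = length(bands)),
    rate = c(20, 30, 90, 170, 280, 470, 610, 620, 470,     # female
             22, 32, 55, 130, 340, 620, 820, 830, 620)     # male
  )
}

#' Configuration for the synthetic dispensing registry
#'
#' Full parameterisation of the simulator. Defaults target roughly 1/100 of
#' a national registry (50,000 persons over 2004-2011) with onset rates,
#' modality mix and artefacts shaped like drug-treated diabetes: ageing
#' onset hazard with an optional multiplicative calendar trend, a
#' baseline pool of prevalent users, OAD-to-insulin switching with a
#' treatment-free gap, transient insulin use in women of reproductive age
#' (gestational diabetes) and off-label metformin in young women (PCOS).
#' Set `n_persons = 4.9e6` for a full national scale run.
#'
#' @param seed integer RNG seed; all simulator randomness derives from it.
#' @param years calendar years of registry coverage.
#' @param n_persons roster size.
#' @param growth_rate annual multiplicative population growth (0 keeps the
#'   Jan 1 counts identical across years).
#' @param pyramid data frame `age`/`weight` giving the stationary age
#'   structure; default built-in.
#' @param sex_share_female probability a person is female.
#' @param onset_rate data frame `age_band`/`sex`/`rate` of onset hazards
#'   per 100,000 person-years; default built-in.
#' @param annual_irr true multiplicative calendar trend in onset (IRR per
#'   year); 1 means no trend.
#' @param modality_mix named probabilities for `oad_only`, `insulin_only`
#'   and `oad_then_insulin`; must sum to 1.
#' @param refill_mean_days,refill_shape mean and gamma shape of the
#'   inter-fill interval (days); shape 9 gives CV 1/3.
#' @param gestational_fraction share of female insulin-only starters aged
#'   within `gestational_age_range` whose insulin use is transient.
#' @param gestational_age_range onset-age range for gestational cases.
#' @param gestational_duration_months range of transient insulin duration.
#' @param pcos_rate metformin-without-diabetes start hazard per 100,000
#'   person-years among women in `pcos_age_range`.
#' @param pcos_age_range age range for PCOS metformin use.
#' @param pcos_duration_years range of PCOS treatment duration.
#' @param attrition_rate annual probability of leaving observation
#'   (emigration/death); exponential exit times.
#' @param prevalent_years mean years since onset used to seed the
#'   prevalent-at-baseline pool (prevalence ~ incidence x duration).
#' @param switch_oad_years range of OAD treatment duration before a switch.
#' @param switch_gap_years range of the treatment-free gap between OAD stop
#'   and insulin start for switchers; the default exceeds the 24-month
#'   washout so switchers reappear as incident insulins-only users.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              years = 2004:2011,
                              n_persons = 50000L,
                              growth_rate = 0,
                              pyramid = NULL,
                              sex_share_female = 0.5,
                              onset_rate = NULL,
                              annual_irr = 1.0,
                              modality_mix = c(oad_only = 0.85,
                                               insulin_only = 0.10,
                                               oad_then_insulin = 0.05),
                              refill_mean_days = 90,
                              refill_shape = 9,
                              gestational_fraction = 0.59,
                              gestational_age_range = c(20, 44),
                              gestational_duration_months = c(4, 9),
                              pcos_rate = 30,
                              pcos_age_range = c(18, 45),
                              pcos_duration_years = c(1, 3),
                              attrition_rate = 0.01,
                              prevalent_years = 10,
                              switch_oad_years = c(1, 3),
                              switch_gap_years = c(2.5, 4)) {
  if (is.null(pyramid)) pyramid <- default_pyramid()
  if (is.null(onset_rate)) onset_rate <- default_onset_rate()
  mm <- modality_mix[c("oad_only", "insulin_only", "oad_then_insulin")]
  if (anyNA(mm) || any(mm < 0) || abs(sum(mm) - 1) > 1e-8)
    stop("modality_mix must be probabilities over oad_only/insulin_only/",
         "oad_then_insulin summing to 1", call. = FALSE)
  stopifnot(n_persons >= 1, all(onset_rate$rate >= 0), pcos_rate >= 0,
            gestational_fraction >= 0, gestational_fraction <= 1,
            attrition_rate >= 0, attrition_rate < 1,
            refill_mean_days > 0, refill_shape > 0, prevalent_years >= 0)
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 n_persons = as.integer(n_persons),
                 growth_rate = growth_rate, pyramid = as.data.table(pyramid),
                 sex_share_female = sex_share_female,
                 onset_rate = as.data.table(onset_rate),
                 annual_irr = annual_irr, modality_mix = mm,
                 refill_mean_days = refill_mean_days,
                 refill_shape = refill_shape,
                 gestational_fraction = gestational_fraction,
                 gestational_age_range = gestational_age_range,
                 gestational_duration_months = gestational_duration_months,
                 pcos_rate = pcos_rate, pcos_age_range = pcos_age_range,
                 pcos_duration_years = pcos_duration_years,
                 attrition_rate = attrition_rate,
                 prevalent_years = prevalent_years,
                 switch_oad_years = switch_oad_years,
                 switch_gap_years = switch_gap_years),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> seed ", x$seed, ", ", x$n_persons, " persons, ",
      min(x$years), "-", max(x$years), ", true IRR/year ", x$annual_irr,
      "\n", sep = "")
  invisible(x)
}

## deterministic person roster shared by the population and dispensing
## simulators: the first RNG draws after set.seed(config$seed)
make_roster <- function(config) {
  set.seed(config$seed)
  pyr <- config$pyramid
  n <- config$n_persons
  age0 <- sample(pyr$age, n, replace = TRUE, prob = pyr$weight)
  sex <- ifelse(runif(n) < config$sex_share_female, "female", "male")
  data.table(person_id = sprintf("P%07d", seq_len(n)), sex = sex,
             birth_year = config$years[1L] - age0)
}

#' Simulate Jan 1 population counts
#'
#' Tabulates the simulated person roster into Jan 1 counts per year, sex
#' and single-year attained age, for every coverage year plus one extra
#' year (so person-year denominators of the final year are computable).
#' The same roster underlies [simulate_dispensings()], so denominators are
#' exactly consistent with the population generating the dispensing events;
#' the roster ages over calendar time, total counts stay constant (scaled
#' multiplicatively by `growth_rate` when non-zero). Deterministic given
#' the configuration.
#'
#' @param config a [simulation_config()].
#' @return a population `data.table` (`year`, `sex`, `age`, `count`).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  roster <- make_roster(config)
  yrs <- c(config$years, max(config$years) + 1L)
  rows <- lapply(yrs, function(y) {
    g <- (1 + config$growth_rate)^(y - config$years[1L])
    tab <- roster[, .(count = .N * g), by = .(sex, age = y - birth_year)]
    tab[, year := y]
    tab
  })
  out <- rbindlist(rows)[age >= 0]
  setcolorder(out, c("year", "sex", "age", "count"))
  setorder(out, year, sex, age)
  out[]
}

lookup_rate <- function(onset_rate, bands, sexes) {
  key <- paste(as.character(bands), sexes)
  tab <- setNames(onset_rate$rate,
                  paste(as.character(onset_rate$age_band), onset_rate$sex))
  r <- tab[key]
  r[is.na(r)] <- 0
  unname(r)
}

runif_range <- function(n, range) runif(n, range[1L], range[2L])

## fill dates from `start` (first fill exactly at start) to `end`,
## gamma-distributed inter-fill gaps
gen_fills <- function(start, end, mean_days, shape) {
  if (is.na(end) || end < start) return(as.Date(character()))
  dur <- as.numeric(end - start)
  t <- 0
  last <- 0
  repeat {
    gaps <- rgamma(max(8L, ceiling((dur - last) / mean_days * 1.6)),
                   shape = shape, scale = mean_days / shape)
    t <- c(t, last + cumsum(gaps))
    last <- t[length(t)]
    if (last > dur) break
  }
  start + floor(t[t <= dur])
}

#' Simulate a dispensing registry with known ground truth
#'
#' Generates per-person streams of insulin (A10A) and OAD (A10B) fills over
#' the coverage years. Onset of drug-treated diabetes follows a piecewise-
#' constant exponential hazard by age band and sex, multiplied by
#' `annual_irr^(year - first_year)`; a prevalent pool is seeded with onsets
#' before coverage start so the registry shows realistic left truncation.
#' Treatment modality is drawn from `modality_mix`; switchers stop OAD and
#' restart on insulin after a treatment-free gap; gestational cases take
#' insulin transiently then stop; PCOS cases emit metformin fills with no
#' diabetes truth record. Records are truncated to coverage at both ends.
#'
#' @param config a [simulation_config()].
#' @return a list with `dispensings` (standard dispensing record table) and
#'   `truth` (one row per true diabetes onset: `person_id`, `sex`,
#'   `birth_year`, `true_onset_date`, `true_modality`,
#'   `true_discontinuation_date`).
#' @export
simulate_dispensings <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  roster <- make_roster(config)   # seeds the RNG; later draws continue it
  yrs <- config$years
  y0 <- yrs[1L]
  n <- config$n_persons
  cov_start <- jan1(y0)
  cov_end <- dec31(max(yrs))

  sex <- roster$sex
  birth_year <- roster$birth_year
  ids <- roster$person_id

  ## exit from observation (emigration/death), exponential in years
  exit_date <- rep(as.Date("9999-12-31"), n)
  if (config$attrition_rate > 0) {
    lam <- -log(1 - config$attrition_rate)
    exit_date <- cov_start + floor(rexp(n, lam) * 365.25)
  }

  ## baseline hazard per person-year (per 100k -> probability scale)
  rate_at <- function(yr) {
    ages <- pmax(yr - birth_year, 0L)
    lookup_rate(config$onset_rate, age_band(ages), sex) / 1e5
  }

  ## prevalent-at-baseline pool: prevalence ~ hazard x mean duration
  h0 <- rate_at(y0)
  prevalent <- runif(n) < (1 - exp(-h0 * config$prevalent_years))
  onset <- rep(as.Date(NA), n)
  onset[prevalent] <- cov_start -
    ceiling(runif(sum(prevalent), 0, config$prevalent_years * 365.25))

  ## incident onsets: first year whose uniform draw falls under the hazard
  at_risk <- !prevalent
  for (yr in yrs) {
    h <- rate_at(yr) * config$annual_irr^(yr - y0)
    hit <- at_risk & (runif(n) < (1 - exp(-h)))
    onset[hit] <- jan1(yr) + floor(runif(sum(hit), 0, 365))
    at_risk <- at_risk & !hit
  }

  has_onset <- !is.na(onset)
  idx <- which(has_onset)
  onset_age <- year_of(onset[idx]) - birth_year[idx]

  modality <- sample(names(config$modality_mix), length(idx), replace = TRUE,
                     prob = config$modality_mix)
  gest <- modality == "insulin_only" & sex[idx] == "female" &
    onset_age >= config$gestational_age_range[1L] &
    onset_age <= config$gestational_age_range[2L] &
    runif(length(idx)) < config$gestational_fraction
  modality[gest] <- "gestational"

  ## PCOS: metformin without diabetes among women of reproductive age
  pcos_start <- rep(as.Date(NA), n)
  if (config$pcos_rate > 0) {
    eligible <- !has_onset & sex == "female"
    at_risk_p <- eligible
    for (yr in yrs) {
      ages <- yr - birth_year
      in_age <- ages >= config$pcos_age_range[1L] &
        ages <= config$pcos_age_range[2L]
      h <- ifelse(in_age, config$pcos_rate / 1e5, 0)
      hit <- at_risk_p & (runif(n) < (1 - exp(-h)))
      pcos_start[hit] <- jan1(yr) + floor(runif(sum(hit), 0, 365))
      at_risk_p <- at_risk_p & !hit
    }
  }

  mean_d <- config$refill_mean_days
  shp <- config$refill_shape
  pick_code <- function(pool, k) sample(names(pool), k, replace = TRUE,
                                        prob = pool)
  far_future <- as.Date("9999-12-31")

  recs <- vector("list", length(idx) + sum(!is.na(pcos_start)))
  truth <- vector("list", length(idx))
  ri <- 0L

  for (j in seq_along(idx)) {
    i <- idx[j]
    o <- onset[idx[j]]
    mod <- modality[j]
    stop_obs <- min(exit_date[i], cov_end)
    disc <- as.Date(NA)
    episodes <- switch(
      mod,
      oad_only = list(list(drug = "oad", from = o, to = far_future)),
      insulin_only = list(list(drug = "ins", from = o, to = far_future)),
      gestational = {
        dur <- round(runif_range(1L, config$gestational_duration_months) * 30.44)
        disc <- o + dur
        list(list(drug = "ins", from = o, to = disc))
      },
      oad_then_insulin = {
        oad_end <- o + round(runif_range(1L, config$switch_oad_years) * 365.25)
        ins_start <- oad_end +
          round(runif_range(1L, config$switch_gap_years) * 365.25)
        list(list(drug = "oad", from = o, to = oad_end),
             list(drug = "ins", from = ins_start, to = far_future))
      })
    dates <- list()
    codes <- list()
    for (ep in episodes) {
      d <- gen_fills(ep$from, min(ep$to, stop_obs), mean_d, shp)
      d <- d[d >= cov_start & d <= cov_end]
      if (length(d)) {
        dates[[length(dates) + 1L]] <- d
        codes[[length(codes) + 1L]] <-
          if (ep$drug == "oad") pick_code(OAD_CODES, length(d))
          else pick_code(INSULIN_CODES, length(d))
      }
    }
    if (length(dates)) {
      ri <- ri + 1L
      recs[[ri]] <- data.table(person_id = ids[i],
                               dispense_date = do.call(c, dates),
                               atc_code = unlist(codes), sex = sex[i],
                               birth_year = birth_year[i])
    }
    truth[[j]] <- data.table(person_id = ids[i], sex = sex[i],
                             birth_year = birth_year[i],
                             true_onset_date = o, true_modality = mod,
                             true_discontinuation_date = disc)
  }

  for (i in which(!is.na(pcos_start))) {
    dur <- round(runif_range(1L, config$pcos_duration_years) * 365.25)
    d <- gen_fills(pcos_start[i],
                   min(pcos_start[i] + dur, exit_date[i], cov_end),
                   mean_d, shp)
    d <- d[d >= cov_start & d <= cov_end]
    if (length(d)) {
      ri <- ri + 1L
      recs[[ri]] <- data.table(person_id = ids[i], dispense_date = d,
                               atc_code = "A10BA02", sex = sex[i],
                               birth_year = birth_year[i])
    }
  }

  dispensings <- if (ri > 0L) rbindlist(recs[seq_len(ri)]) else
    data.table(person_id = character(), dispense_date = as.Date(character()),
               atc_code = character(), sex = character(),
               birth_year = integer())
  setorder(dispensings, person_id, dispense_date, atc_code)
  truth <- if (length(truth)) rbindlist(truth) else
    data.table(person_id = character(), sex = character(),
               birth_year = integer(), true_onset_date = as.Date(character()),
               true_modality = character(),
               true_discontinuation_date = as.Date(character()))
  setorder(truth, person_id)
  list(dispensings = dispensings, truth = truth)
}

#' Tabulate true incident onsets by year and stratum
#'
#' Gold-standard counts of simulated diabetes onsets for comparison with
#' classifier output. Classifier counts may legitimately differ through the
#' planned artefacts (PCOS metformin use, re-incidence of switchers after a
#' treatment-free gap).
#'
#' @param truth truth table from [simulate_dispensings()].
#' @param years years to tabulate.
#' @return a `data.table` of counts by `year`, `sex` and `age_band`.
#' @export
truth_summary <- function(truth, years) {
  tr <- as.data.table(truth)
  if (nrow(tr) == 0L)
    return(data.table(year = integer(), sex = character(),
                      age_band = character(), n = integer()))
  tr <- tr[!is.na(true_onset_date)]
  tr[, year := year_of(true_onset_date)]
  tr <- tr[year %in% years]
  tr[, age_band := age_band(pmax(year - birth_year, 0L))]
  out <- tr[, .(n = .N), by = .(year, sex, age_band)]
  setorder(out, year, sex, age_band)
  out[]
}
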