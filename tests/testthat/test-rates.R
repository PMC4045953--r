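test_that("person-years are the mean of adjacent Jan 1 counts over the stratum", {
  pop <- data.frame(year = rep(c(2010, 2011), each = 4),
                    sex = rep(c("female", "female", "male", "male"), 2),
                    age = rep(c(40, 41, 40, 41), 2),
                    count = c(100, 50, 90, 60, 102, 50, 94, 58))
  expect_equal(person_years(pop, 2010), (300 + 304) / 2)
  expect_equal(person_years(pop, 2010, sex = "female"), (150 + 152) / 2)
  expect_equal(person_years(pop, 2010, sex = "male", age_min = 40,
                            age_max = 40), 92)
  ## identical counts both years: idempotent
  pop2 <- transform(pop, count = 100)
  expect_equal(person_years(pop2, 2010), 400)
  expect_error(person_years(pop, 2011), "missing for Jan 1 2012")
})

test_that("published incidence cells reproduce from printed counts and person-years", {
  tab <- norpd_incident_table()
  tab <- tab[!is.na(tab$count), ]
  got <- incidence_rate(tab$count, tab$person_years)
  r <- round_half_away_int(got$rate)
  lo <- round_half_away_int(got$ci_low)
  hi <- round_half_away_int(got$ci_high)
  ## every printed cell is within one integer (the published table mixes
  ## rounding and truncation); most cells reproduce exactly
  expect_true(all(abs(r - tab$rate) <= 1))
  expect_true(all(abs(lo - tab$ci_low) <= 1))
  expect_true(all(abs(hi - tab$ci_high) <= 1))
  exact <- r == tab$rate & lo == tab$ci_low & hi == tab$ci_high
  expect_gte(sum(exact), 37)

  ## spot checks: national total 2011 and women's insulins-only 2006
  tot <- incidence_rate(15515, 4953217)
  expect_equal(round_half_away_int(tot$rate), 313)
  expect_equal(round_half_away_int(c(tot$ci_low, tot$ci_high)), c(308, 318))
  wi <- incidence_rate(670, 2347036)
  expect_equal(round_half_away_int(wi$rate), 29)
  expect_equal(round_half_away_int(c(wi$ci_low, wi$ci_high)), c(26, 31))
})

test_that("rate CIs behave at the edges", {
  z <- incidence_rate(0, 1e5)
  expect_equal(z$rate, 0)
  expect_equal(z$ci_low, 0)
  expect_equal(z$ci_high, 3)            # rule of three: 3 / 1e5 * 1e5
  expect_error(incidence_rate(10, 0), "positive")
  expect_error(incidence_rate(-1, 10), "non-negative")

  ## scale invariance: doubling count and PY preserves rate and CI ratio
  a <- incidence_rate(200, 5e5)
  b <- incidence_rate(400, 1e6)
  expect_equal(a$rate, b$rate)
  expect_lt(b$ci_high - b$ci_low, a$ci_high - a$ci_low)

  ## log-scale variant brackets the rate multiplicatively
  lw <- incidence_rate(100, 1e6, ci_method = "log")
  expect_equal(lw$ci_low * lw$ci_high, lw$rate^2, tolerance = 1e-12)
})

test_that("prevalence percentages reproduce the published headline figures", {
  hc <- norpd_headline_counts()
  got <- prevalence(hc$count, hc$mean_population)
  expect_equal(round_half_away(got$percent[1], 1), 3.2)
  expect_equal(round_half_away(got$percent[2], 2), 0.64)
  expect_equal(round_half_away(got$percent[3], 2), 0.57)
  expect_equal(prevalence(0, 100)$percent, 0)
  expect_error(prevalence(5, 0), "positive")
})

test_that("rate CI covers the true rate at nominal level for Poisson counts", {
  set.seed(7)
  true_rate <- 300; py <- 1e5
  y <- rpois(500, true_rate / 1e5 * py)
  ci <- incidence_rate(y, py)
  cover <- mean(ci$ci_low <= true_rate & true_rate <= ci$ci_high)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("report tables count classified users by stratum and flag unobservable cells", {
  pop <- data.frame(year = rep(2004:2012, each = 2),
                    sex = rep(c("female", "male"), 9),
                    age = 50, count = 1000)
  ## empty statuses: all-zero counts with valid person-years
  empty <- classify_registry(rec_tab(character(0), character(0), character(0)),
                             windows = window_config(), coverage = COV)
  tab <- make_table(empty, pop, years = 2006, measure = "incidence")
  expect_true(all(tab$count == 0))
  expect_true(all(tab$person_years == c(1000, 1000, 2000)[match(tab$sex,
                c("female", "male", "total"))]))

  recs <- rbind(
    rec_tab("P1", "2008-03-10", "A10BA02", sex = "female", birth_year = 1958L),
    rec_tab("P2", "2008-07-01", "A10AB01", sex = "male", birth_year = 1958L),
    rec_tab("P3", c("2008-05-01", "2008-09-01"), c("A10BA02", "A10BA02"),
            sex = "male", birth_year = 1958L))
  st <- classify_registry(recs, windows = window_config(), coverage = COV)
  tab <- make_table(st, pop, years = c(2008, 2011), measure = "incidence")
  pick <- function(y, s, o) tab[tab$year == y & tab$sex == s &
                                  tab$outcome == o, ]
  expect_equal(pick(2008, "total", "any")$count, 3L)
  expect_equal(pick(2008, "total", "oad")$count, 2L)
  expect_equal(pick(2008, "total", "insulin_only")$count, 1L)
  expect_equal(pick(2008, "female", "oad")$count, 1L)
  expect_equal(pick(2008, "total", "any")$rate, 3 / 2000 * 1e5)
  ## female + male = total in every cell
  for (o in c("any", "oad", "insulin_only"))
    expect_equal(pick(2008, "female", o)$count + pick(2008, "male", o)$count,
                 pick(2008, "total", o)$count)
  ## final coverage year: insulins-only unobservable, marked not dropped
  expect_false(pick(2011, "total", "insulin_only")$observable)
  expect_true(is.na(pick(2011, "total", "insulin_only")$count))
  expect_true(pick(2011, "total", "oad")$observable)

  prev <- make_table(st, pop, years = 2008, measure = "prevalence")
  expect_equal(prev[prev$sex == "total" & prev$outcome == "any", ]$percent,
               3 / 2000 * 100)
})
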