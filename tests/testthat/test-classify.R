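W <- window_config()   # 24-month washout, 12-month lookforward

test_that("first fill of a class in a year is the class-filtered minimum", {
  h <- rec_tab("P1", c("2010-02-01", "2010-03-01", "2010-05-01", "2010-07-01"),
               c("A10BA02", "A10BA02", "A10AB01", "A10BA02"))
  expect_equal(first_fill_in_year(h, 2010, "OAD"), as.Date("2010-02-01"))
  expect_equal(first_fill_in_year(h, 2010, "INSULIN"), as.Date("2010-05-01"))
  expect_equal(first_fill_in_year(h, 2010, "ANY_A10"), as.Date("2010-02-01"))
  expect_true(is.na(first_fill_in_year(h, 2009, "OAD")))
  expect_error(first_fill_in_year(h[c(3, 1, 2, 4), ], 2010, "OAD"), "sorted")
})

test_that("prevalent insulins-only requires an OAD-free window around the anchor", {
  ## no OAD anywhere: insulins only
  st <- classify_prevalent(rec_tab("P1", "2010-05-01", "A10AB01"), 2010,
                           W, COV)
  expect_true(st$prevalent_any)
  expect_true(st$prevalent_insulin_only)
  expect_false(st$prevalent_oad)

  ## OAD fill 2009-01-15 lies inside [2008-05-01, 2011-05-01]: disqualified
  h <- rec_tab("P1", c("2009-01-15", "2010-05-01"), c("A10BA02", "A10AB01"))
  st <- classify_prevalent(h, 2010, W, COV)
  expect_true(st$prevalent_any)
  expect_false(st$prevalent_insulin_only)

  ## OAD just outside the washout boundary does not disqualify
  h <- rec_tab("P1", c("2008-04-30", "2010-05-01"), c("A10BA02", "A10AB01"))
  expect_true(classify_prevalent(h, 2010, W, COV)$prevalent_insulin_only)

  ## same-day insulin + OAD is combination therapy, not insulins only
  h <- rec_tab("P1", c("2010-05-01", "2010-05-01"), c("A10AB01", "A10BA02"))
  expect_false(classify_prevalent(h, 2010, W, COV)$prevalent_insulin_only)
})

test_that("insulins-only prevalence is unobservable when the lookforward leaves coverage", {
  st <- classify_prevalent(rec_tab("P1", "2011-06-01", "A10AB01"), 2011,
                           W, COV)
  expect_false(st$observable_insulin_only)
  expect_true(is.na(st$prevalent_insulin_only))
  expect_true(st$prevalent_any)   # plain prevalence still observable in 2011
})

test_that("incident users have a clean washout before the first fill of the year", {
  ## gap above 24 months: incident in both years (re-incidence)
  h <- rec_tab("P1", c("2006-03-01", "2010-06-01"), c("A10BA02", "A10BA02"))
  expect_true(classify_incident(h, 2006, W, COV)$incident_oad)
  expect_true(classify_incident(h, 2010, W, COV)$incident_oad)

  ## insulin then OAD within the year: any-incidence only
  h <- rec_tab("P1", c("2010-05-01", "2010-08-01"), c("A10AB01", "A10BA02"))
  st <- classify_incident(h, 2010, W, COV)
  expect_true(st$incident_any)
  expect_false(st$incident_oad)          # insulin inside the OAD washout
  expect_false(st$incident_insulin_only) # OAD in the lookforward

  ## the anchor fill itself never disqualifies
  h <- rec_tab("P1", "2008-07-15", "A10BA02")
  expect_true(classify_incident(h, 2008, W, COV)$incident_oad)

  ## fill just inside the washout boundary disqualifies
  h <- rec_tab("P1", c("2008-06-02", "2010-06-01"), c("A10BA02", "A10BA02"))
  expect_false(classify_incident(h, 2010, W, COV)$incident_oad)
  h <- rec_tab("P1", c("2008-06-01", "2010-06-01"), c("A10BA02", "A10BA02"))
  expect_false(classify_incident(h, 2010, W, COV)$incident_oad)  # closed start
  h <- rec_tab("P1", c("2008-05-31", "2010-06-01"), c("A10BA02", "A10BA02"))
  expect_true(classify_incident(h, 2010, W, COV)$incident_oad)
})

test_that("incidence is unobservable during the run-in period", {
  st <- classify_incident(rec_tab("P1", "2005-06-01", "A10BA02"), 2005, W, COV)
  expect_false(st$observable_incidence)
  expect_true(is.na(st$incident_any))
  expect_true(is.na(st$incident_oad))
})

test_that("same-day insulin + OAD start counts once in the incident partition", {
  h <- rec_tab("P1", c("2010-05-01", "2010-05-01"), c("A10AB01", "A10BA02"))
  st <- classify_incident(h, 2010, W, COV)
  expect_true(st$incident_any)
  expect_true(st$incident_oad)            # insulin same day is not "previous"
  expect_false(st$incident_insulin_only)  # OAD on the anchor date
  n_sub <- sum(st$incident_oad, st$incident_insulin_only)
  expect_lte(n_sub, sum(st$incident_any))
})

test_that("registry classification emits one row per person and evaluated year", {
  expect_equal(nrow(classify_registry(rec_tab(character(0), character(0),
                                              character(0)),
                                      windows = W, coverage = COV)), 0L)

  st <- classify_registry(rec_tab("P1", "2008-03-10", "A10BA02"),
                          windows = W, coverage = COV)
  expect_equal(nrow(st), 8L)              # 2004..2011
  expect_equal(st$year, 2004:2011)
  expect_equal(sum(st$incident_oad, na.rm = TRUE), 1L)
  expect_equal(st[st$year == 2008, ]$incident_oad, TRUE)
  expect_equal(st[st$year == 2008, ]$anchor_oad, as.Date("2008-03-10"))
  ## attained age: year minus birth year, banded per calendar year
  expect_equal(st[st$year == 2008, ]$age, 48L)      # 2008 - 1960
  expect_equal(st[st$year == 2008, ]$age_band, age_band(48L))
  expect_equal(st[st$year == 2011, ]$age_band, age_band(51L))
})

test_that("a three-person registry matches the full-history oracle", {
  recs <- rbind(
    rec_tab("A", c("2005-02-01", "2007-06-15", "2007-08-01"),
            c("A10BA02", "A10AB01", "A10BA02")),
    rec_tab("B", c("2006-03-01", "2010-06-01"), c("A10AB01", "A10AB01"),
            sex = "male", birth_year = 1990L),
    rec_tab("C", "2009-12-31", "A10BA02", sex = "male", birth_year = 1940L))
  expect_matches_oracle(recs, 2004:2011, W)
})
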