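test_that("washout sweep counts a pure insulin history at every washout", {
  recs <- rec_tab("P1", c("2010-03-01", "2010-06-01", "2010-09-01"),
                  rep("A10AB01", 3))
  sweep <- sensitivity_sweep(recs, 2010,
                             lapply(c(24, 36, 48, 60, 72), window_config), COV)
  expect_equal(sweep$prevalent_insulin_only, rep(1L, 5))
  expect_equal(sweep$incident_insulin_only, rep(1L, 5))
})

test_that("widening the washout over an empty band leaves counts unchanged", {
  ## OAD 2007-06-01 sits 35 months before the insulin anchor: inside a
  ## 36-month washout, outside 24 and 25 month washouts
  recs <- rec_tab("P1", c("2007-06-01", "2010-05-01"),
                  c("A10BA02", "A10AB01"))
  sweep <- sensitivity_sweep(recs, 2010,
                             lapply(c(24, 25, 36), window_config), COV)
  expect_equal(sweep$prevalent_insulin_only, c(1L, 1L, 0L))
})

test_that("unobservable windows are flagged, not silently dropped", {
  recs <- rec_tab("P1", "2010-05-01", "A10AB01")
  sweep <- sensitivity_sweep(recs, 2010,
                             lapply(c(24, 96), window_config), COV)
  expect_equal(sweep$observable_incidence, c(TRUE, FALSE))
  expect_true(is.na(sweep$prevalent_insulin_only[2]))
  expect_true(is.na(sweep$incident_any[2]))
})

test_that("planted OAD-to-insulin switchers shrink counts under longer washouts", {
  ## switchers: OAD history ending 3 years before the insulin anchor
  switchers <- do.call(rbind, lapply(1:5, function(i)
    rec_tab(paste0("S", i),
            c("2006-04-01", "2010-06-01", "2010-09-01"),
            c("A10BA02", "A10AB01", "A10AB01"))))
  clean <- do.call(rbind, lapply(1:3, function(i)
    rec_tab(paste0("C", i), c("2010-02-01", "2010-07-01"),
            c("A10AB01", "A10AB01"))))
  sweep <- sensitivity_sweep(rbind(switchers, clean), 2010,
                             lapply(c(24, 72), window_config), COV)
  expect_equal(sweep$prevalent_insulin_only, c(8L, 3L))
  expect_lt(sweep$prevalent_insulin_only[2], sweep$prevalent_insulin_only[1])
})

test_that("persistence fraction counts refills of the defining class", {
  ## 3 of 4 incident OAD users refill within 12 months
  recs <- rbind(
    rec_tab("P1", c("2008-02-01", "2008-05-01"), c("A10BA02", "A10BA02")),
    rec_tab("P2", c("2008-03-01", "2008-04-01"), c("A10BA02", "A10BA02")),
    rec_tab("P3", c("2008-06-01", "2009-05-20"), c("A10BA02", "A10BA02")),
    rec_tab("P4", "2008-08-01", "A10BA02"))
  st <- classify_registry(recs, windows = window_config(), coverage = COV)
  pf <- persistence_fraction(st, recs, months = 12L, coverage = COV)
  expect_equal(pf[pf$group == "oad", ]$n_incident, 4L)
  expect_equal(pf[pf$group == "oad", ]$fraction, 0.75)
  expect_equal(pf[pf$group == "any", ]$fraction, 0.75)

  ## single fills only: persistence 0
  solo <- rec_tab(c("Q1", "Q2"), c("2008-02-01", "2009-03-01"),
                  c("A10BA02", "A10BA02"), birth_year = c(1950L, 1960L))
  st <- classify_registry(solo, windows = window_config(), coverage = COV)
  pf <- persistence_fraction(st, solo, months = 12L, coverage = COV)
  expect_equal(pf[pf$group == "oad", ]$fraction, 0)

  ## monthly refills: persistence 1; no incident insulin users -> NA
  freq <- rec_tab("R1", format(seq(as.Date("2008-02-01"), by = "month",
                                   length.out = 6)), rep("A10BA02", 6))
  st <- classify_registry(freq, windows = window_config(), coverage = COV)
  pf <- persistence_fraction(st, freq, months = 12L, coverage = COV)
  expect_equal(pf[pf$group == "oad", ]$fraction, 1)
  expect_true(is.na(pf[pf$group == "insulin_only", ]$fraction))
})

test_that("discontinuation fraction finds users with a fill-free final year", {
  ## 6 of 10 incident insulins-only users stop (no fill in months 12-24)
  continuing <- do.call(rbind, lapply(1:4, function(i)
    rec_tab(paste0("K", i),
            format(seq(as.Date("2008-03-01"), by = "2 months",
                       length.out = 12)), rep("A10AB01", 12),
            sex = "female", birth_year = 1975L)))
  stopping <- do.call(rbind, lapply(1:6, function(i)
    rec_tab(paste0("S", i), c("2008-03-01", "2008-06-01"),
            rep("A10AB01", 2), sex = "female", birth_year = 1975L)))
  recs <- rbind(continuing, stopping)
  st <- classify_registry(recs, windows = window_config(), coverage = COV)
  dfr <- discontinuation_fraction(st, recs, horizon_months = 24L,
                                  coverage = COV, year = 2008)
  expect_equal(dfr$n_incident, 10L)
  expect_equal(dfr$fraction, 0.6)

  ## all continue -> 0; all stop after the anchor -> 1
  dfr <- discontinuation_fraction(classify_registry(continuing,
                                                    windows = window_config(),
                                                    coverage = COV),
                                  continuing, coverage = COV, year = 2008)
  expect_equal(dfr$fraction, 0)
  dfr <- discontinuation_fraction(classify_registry(stopping,
                                                    windows = window_config(),
                                                    coverage = COV),
                                  stopping, coverage = COV, year = 2008)
  expect_equal(dfr$fraction, 1)

  ## empty stratum reported as absent
  dfr <- discontinuation_fraction(st, recs, coverage = COV, year = 2008,
                                  sex = "male")
  expect_true(is.na(dfr$fraction))
})
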