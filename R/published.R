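#' Published NorPD incident-user table, 2006-2011
#'
#' Reference figures from the published nationwide analysis of the
#' Norwegian Prescription Database (NorPD): incident users of any blood
#' glucose-lowering drug, OAD and insulins only per calendar year and sex,
#' with person-years, incidence rates per 100,000 person-years and 95%
#' confidence intervals as printed. Insulins-only cells for 2011 are `NA`
#' because the 12-month lookforward extends past registry coverage (the
#' published table marks them with a footnote). Used to validate the rate
#' and CI arithmetic of [incidence_rate()].
#'
#' @return a `data.table` with columns `sex`, `year`, `person_years`,
#'   `outcome`, `count`, `rate`, `ci_low`, `ci_high`.
#' @export
norpd_incident_table <- function() {
  fread(system.file("extdata", "norpd_incident_users_2006_2011.csv",
                    package = "rxcohort"))
}

#' Published NorPD headline prevalence counts
#'
#' Published prevalent-user counts with their mean-population denominators:
#' users of any blood glucose-lowering drug in 2011, insulins-only users in
#' 2010 under the default 24-month washout, and insulins-only users in 2010
#' under the extended six-year washout of the sensitivity analysis.
#'
#' @return a `data.table` with columns `measure`, `year`, `washout_months`,
#'   `count`, `mean_population`, `printed_percent`.
#' @export
norpd_headline_counts <- function() {
  fread(system.file("extdata", "norpd_headline_counts.csv",
                    package = "rxcohort"))
}
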