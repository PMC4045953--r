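---
title: "The new-user design for dispensing registries: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The new-user design for dispensing registries: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxcohort)
```

rxcohort analyses longitudinal dispensing records — one row per redeemed
prescription — to estimate prevalent and incident use of blood
glucose-lowering drugs (ATC group A10) as a proxy for drug-treated
diabetes. This vignette explains the classification rules and their edge
conventions, the statistical estimators, the numerical choices inside the
Poisson solver, and what the bundled registry simulator does and does not
emulate.

## Classification model

All rules operate on a per-person, per-calendar-year basis with two
windows, configured by `window_config()`:

* **washout** (default 24 months): the drug-free lookback required before a
  first fill counts as *incident*;
* **lookforward** (default 12 months): the OAD-free follow-up required
  after a first insulin fill for the *insulins only* classification, a
  proxy for Type 1 diabetes (insulin users never exposed to oral agents
  around treatment start).

With the *anchor* defined as the first fill of the relevant class in the
year:

| flag | anchor | rule |
|---|---|---|
| `prevalent_any` | — | ≥ 1 A10 fill in the year |
| `prevalent_oad` | — | ≥ 1 A10B fill in the year |
| `prevalent_insulin_only` | first insulin fill | no OAD fill in `[anchor − washout, anchor + lookforward]` (closed) |
| `incident_any` | first A10 fill | no A10 fill in `[anchor − washout, anchor)` |
| `incident_oad` | first OAD fill | no A10 fill (insulin included) in `[anchor − washout, anchor)` |
| `incident_insulin_only` | first insulin fill | clean A10 washout **and** no OAD fill in `[anchor, anchor + lookforward]` |

### Edge conventions

Several conventions are genuinely open given only the verbal definitions;
the package fixes them as follows.

**Month arithmetic.** "24 months prior" is a calendar-month shift of the
anchor date with the day-of-month kept and clamped to the end of shorter
months (`shift_months()`), not a 730-day offset. Month-denominated windows
are then exactly reproducible and independent of leap years.

**Window endpoints.** The incident washout is half-open, `[anchor −
washout, anchor)`: the anchor fill itself never disqualifies, while a fill
on the first day of the washout does. The insulins-only windows are closed
at the anchor date: an OAD fill dispensed on the same day as the first
insulin fill marks combination therapy, so the person is *not* an
insulins-only user. This convention also preserves the partition bound —
for every year, incident-any counts are at least the sum of incident-OAD
and incident-insulins-only counts — which an anchor-exclusive lookforward
would violate for same-day insulin + OAD starts.

**Incident-OAD anchor.** The washout for incident OAD use is anchored at
the first *OAD* fill of the year (not the first A10 fill), and any
glucose-lowering fill inside it — including insulin — disqualifies. This is
the literal reading of "no blood glucose-lowering drugs in the previous 24
months".

**Re-incidence.** A person can be incident in more than one year if a gap
of at least the washout length recurs between treatment episodes. The
definition implies this; no dedup-to-first-ever is applied. It is also the
mechanism by which OAD-to-insulin switchers with a long treatment pause
re-enter the incident insulins-only group, which is what the washout
sensitivity analysis quantifies.

**Age.** Age is the attained age in the calendar year, `year − birth_year`,
banded into 10-year groups (`0-9`, …, `70-79`, `80+`).

**"Stopped insulin treatment".** Discontinuation within a horizon (default
24 months) is operationalised as *no insulin fill during the final 12
months of the horizon*, i.e. in `(anchor + 12m, anchor + 24m]`. A
refill-gap definition would need a dispensing-duration model that
dispensing records do not carry; the fill-free-tail definition only assumes
that ongoing treatment produces at least one fill per year, which holds for
any realistic refill interval.

### Observability

A year is reportable for an outcome only when the windows of *every
possible* anchor date in it fit inside registry coverage: the washout of a
Jan 1 anchor must start at or after coverage start, and (for insulins-only
outcomes) the lookforward of a Dec 31 anchor must end at or before coverage
end. With coverage 2004–2011 and default windows this yields prevalence
2004–2011, incidence 2006–2011 and insulins-only outcomes 2006–2010 — the
first two coverage years act as a run-in period, and the final year cannot
support the lookforward. Flags whose year is unobservable are `NA` with an
explicit indicator; report tables mark such cells rather than dropping
them. Observability is always computed from coverage, never assumed.

## Rates, intervals and rounding

Person-years for year *y* and stratum *s* are the mean of the Jan 1 counts
of *y* and *y+1* summed over *s* — the standard mid-year approximation for
an open population. Incidence is `count / person_years × 100,000` with the
Wald interval on the rate scale,

$$\mathrm{rate} \cdot \left(1 \pm z_{1-\alpha/2}/\sqrt{\mathrm{count}}\right),$$

truncated below at zero; a log-scale Wald variant is available
(`ci_method = "log"`). Both reproduce the published national table after
integer rounding on the cells where the table's own rounding is consistent;
the package stores full precision and rounds only in reports, using
round-half-away-from-zero. Zero counts get `ci_low = 0` and `ci_high` from
the rule of three, `3/PY × 10^5`. Prevalence is `count / mean population ×
100`.

## Poisson trend model

Counts per (year × age band × sex) cell are modelled as Poisson with log
link and log person-year offset; the calendar-year term is linear, so
`exp(β_year)` is the incidence rate ratio per year. The solver
(`fit_poisson()`) is iteratively reweighted least squares on the working
response with:

* calendar year centred at its midpoint before fitting (conditioning; the
  IRR is invariant to centring);
* reference coding with the youngest age band and female sex as baselines
  (the IRR per year is invariant to this choice);
* **step-halving** whenever a proposed step would decrease the
  log-likelihood, so the likelihood is non-decreasing across iterations;
* convergence when the relative log-likelihood change or the score norm
  falls below `tol` (default 1e-10), with `converged = FALSE` returned
  (never an error) at `max_iter`;
* a rank check on the design matrix up front, failing with the names of
  collinear columns;
* covariance from the inverse observed information at the optimum.

Stratum-specific trends (e.g. men aged 70+) are obtained by fitting
within-stratum models with a linear year term (`trend_irr()`), matching
per-panel trend reporting, rather than by reading contrasts out of a single
interaction model; the year-by-age interaction itself is assessed by a
likelihood-ratio test between nested fits (`lr_test()`). Overdispersion is
not modelled — the published analysis uses plain Poisson — but a Pearson
dispersion statistic is attached to every fit as a diagnostic.

## The synthetic registry

No individual-level national dispensing data are distributable, so the
package ships a simulator (`simulation_config()`,
`simulate_dispensings()`) whose output exercises every pipeline feature
with known ground truth:

* **onset** of drug-treated diabetes as a piecewise-constant exponential
  hazard by 10-year age band and sex, multiplied by a calendar trend
  `annual_irr^(year − first_year)` — the simplest process for which the
  Poisson analysis is exact;
* a **prevalent pool** seeded with onsets before coverage start
  (prevalence ≈ hazard × `prevalent_years`, default 10), so the run-in
  truncation behaviour of the classifier is exercised;
* **modality mix**: OAD only (85%), insulins only (10%), OAD-then-insulin
  switchers (5%) who stop OAD and restart on insulin after a 2.5–4-year
  treatment-free gap — deliberately longer than the default washout, so
  switchers reappear as apparent insulins-only users until the washout is
  extended;
* **gestational diabetes**: a configurable fraction (default 0.59) of
  female insulin starters aged 20–44 take insulin for only 4–9 months;
* **PCOS**: metformin fills without any diabetes truth record among women
  18–45 (default 30/100,000 person-years);
* gamma-distributed refill intervals (mean 90 days, shape 9, CV 1/3),
  annual attrition (default 1%), and truncation of all records to coverage
  at both ends.

Population denominators are tabulated from the *same* person roster that
generates events, aged year by year, so counts, truth and denominators are
exactly consistent; the roster is drawn deterministically from the seed
before any event randomness, making `simulate_population()` and
`simulate_dispensings()` mutually consistent and byte-reproducible. Onset
hazards depend on the attained age band, so an age-adjusted Poisson fit of
classifier counts on the simulated denominators is correctly specified.

Default scale is 50,000 persons (~1/100 of a small national population),
which runs the full pipeline in seconds; `n_persons = 4.9e6` gives a
full-scale registry.

**What passing tests do and do not show.** The simulator validates the
*logic* of classification, estimation and trend testing against a process
whose truth is known. It does not attempt real demography (the pyramid is
a stylised stationary age structure), treatment switching within OAD
classes, dose titration, seasonality of dispensing, migration, or
institutional dispensing — so agreement on synthetic data says nothing
about those sources of error in real registries, only that the analysis
machinery is correct given its inputs.

Calibration studies use these problem sizes, chosen to keep Monte Carlo
error small relative to the tolerances they check: trend recovery with 50
replicates of 20,000 persons under a true IRR of 0.95 (clean configuration:
no switchers, PCOS or attrition, whose artefacts would bias a trend
estimate by design); interaction LR-test size over 200 replicates of cell
tables at the published table's count scale; rate-CI coverage over 500
Poisson draws at count ≈ 300; and gestational recovery with a
high-incidence young-female configuration yielding ≈ 100+ incident
insulins-only users.

## Known limitations

* The insulins-only proxy misclassifies insulin-treated Type 2 diabetes
  with distant OAD exposure (quantified, not removed, by the washout
  sweep) and gestational diabetes (quantified by the discontinuation
  fraction).
* Wald intervals on the rate scale can undercover for counts below ~20;
  all published cells validated here have counts ≥ 670.
* Person-year denominators ignore migration and death within the year
  beyond what the Jan 1 means capture.
* The exact CI method behind the published table is not stated; the Wald
  form reproduces every arithmetically consistent printed cell, but other
  methods may as well.
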