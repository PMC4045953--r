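#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: artifact directory, input
#' paths (defaulting to the simulator's outputs inside `out_dir`), registry
#' coverage, classification windows, reporting years, CI settings and the
#' simulation configuration.
#'
#' @param out_dir directory where artifacts are written.
#' @param coverage a [registry_coverage()].
#' @param windows a [window_config()].
#' @param sim a [simulation_config()] for the `simulate` step.
#' @param dispensings_path,population_path input CSVs; default to the
#'   simulator artifacts inside `out_dir`.
#' @param years years to report; defaults to all coverage years.
#' @param alpha CI significance level.
#' @param ci_method CI method for [incidence_rate()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            coverage = registry_coverage("2004-01-01",
                                                         "2011-12-31"),
                            windows = window_config(),
                            sim = simulation_config(),
                            dispensings_path = NULL,
                            population_path = NULL,
                            years = NULL,
                            alpha = 0.05,
                            ci_method = "wald") {
  if (is.null(dispensings_path))
    dispensings_path <- file.path(out_dir, "dispensings.csv")
  if (is.null(population_path))
    population_path <- file.path(out_dir, "population.csv")
  if (is.null(years)) years <- coverage_years(coverage)
  structure(list(out_dir = out_dir, coverage = coverage, windows = windows,
                 sim = sim, dispensings_path = dispensings_path,
                 population_path = population_path,
                 years = as.integer(years), alpha = alpha,
                 ci_method = ci_method),
            class = "pipeline_config")
}

artifact <- function(config, name) file.path(config$out_dir, name)

need_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact '", path, "'; run the '", producer,
         "' step first", call. = FALSE)
  path
}

read_user_status <- function(path) {
  st <- fread(path, colClasses = list(character = "person_id"))
  for (col in c("anchor_any", "anchor_oad", "anchor_insulin"))
    st[[col]] <- as.Date(st[[col]])
  flags <- grep("^(prevalent|incident|observable)_", names(st), value = TRUE)
  for (col in flags) st[[col]] <- as.logical(st[[col]])
  st
}

#' Run the analysis pipeline
#'
#' Orchestrates the end-to-end analysis on disk artifacts, so each stage is
#' independently re-runnable and every reported number is re-derivable from
#' the intermediate person-year status CSV. Subcommands:
#'
#' * `simulate` - generate the synthetic registry (`dispensings.csv`,
#'   `population.csv`, `truth.csv`).
#' * `classify` - user classification to `user_status.csv`.
#' * `rates` - incidence and prevalence tables (`incidence_rates.csv`,
#'   `prevalence.csv`, age-stratified `incidence_cells_by_age.csv`).
#' * `trend` - per-stratum IRR-per-year fits and the year-by-age
#'   interaction likelihood-ratio test (`trend_summary.csv`,
#'   `trend_lr_tests.csv`).
#' * `report` - rounded display tables plus `manifest.json` (config hash,
#'   package version, seed).
#' * `all` - all of the above in order.
#'
#' Runs are deterministic given the configuration: re-running a command
#' reproduces its artifacts byte-identically.
#'
#' @param command one of `"simulate"`, `"classify"`, `"rates"`, `"trend"`,
#'   `"report"`, `"all"`.
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(command = c("all", "simulate", "classify", "rates",
                                     "trend", "report"),
                         config, quiet = FALSE) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[rxcohort] ", ...)
  steps <- if (command == "all")
    c("simulate", "classify", "rates", "trend", "report") else command
  out <- character()

  for (s in steps) out <- c(out, switch(
    s,
    simulate = {
      sim <- simulate_dispensings(config$sim)
      pop <- simulate_population(config$sim)
      write_dispensings(sim$dispensings, artifact(config, "dispensings.csv"))
      write_population(pop, artifact(config, "population.csv"))
      fwrite(sim$truth, artifact(config, "truth.csv"), dateTimeAs = "ISO")
      say("simulate: ", nrow(sim$dispensings), " dispensings, ",
          nrow(sim$truth), " true onsets, seed ", config$sim$seed)
      c(dispensings = artifact(config, "dispensings.csv"),
        population = artifact(config, "population.csv"),
        truth = artifact(config, "truth.csv"))
    },
    classify = {
      rec <- read_dispensings(need_artifact(config$dispensings_path,
                                            "simulate"), config$coverage)
      st <- classify_registry(rec, years = config$years,
                              windows = config$windows,
                              coverage = config$coverage)
      fwrite(st, artifact(config, "user_status.csv"), dateTimeAs = "ISO")
      for (y in sort(unique(st$year)))
        say("classify: ", y, ": prevalent_any=",
            sum(st[year == y]$prevalent_any, na.rm = TRUE), " incident_any=",
            sum(st[year == y]$incident_any, na.rm = TRUE))
      c(user_status = artifact(config, "user_status.csv"))
    },
    rates = {
      st <- read_user_status(need_artifact(artifact(config, "user_status.csv"),
                                           "classify"))
      pop <- read_population(need_artifact(config$population_path, "simulate"))
      inc <- make_table(st, pop, years = config$years, measure = "incidence",
                        strata = "sex", alpha = config$alpha,
                        ci_method = config$ci_method)
      prev <- make_table(st, pop, years = config$years,
                         measure = "prevalence", strata = "sex")
      cells <- make_table(st, pop, years = config$years,
                          measure = "incidence", strata = "sex_age",
                          alpha = config$alpha, ci_method = config$ci_method)
      fwrite(inc, artifact(config, "incidence_rates.csv"))
      fwrite(prev, artifact(config, "prevalence.csv"))
      fwrite(cells, artifact(config, "incidence_cells_by_age.csv"))
      say("rates: ", nrow(inc), " incidence cells, ", nrow(prev),
          " prevalence cells")
      c(incidence = artifact(config, "incidence_rates.csv"),
        prevalence = artifact(config, "prevalence.csv"),
        cells = artifact(config, "incidence_cells_by_age.csv"))
    },
    trend = {
      cells <- fread(need_artifact(artifact(config,
                                            "incidence_cells_by_age.csv"),
                                   "rates"))
      fits <- list()
      lrs <- list()
      for (oc in unique(cells$outcome)) {
        ok <- cells[outcome == oc & observable %in% TRUE & !is.na(count)]
        if (nrow(ok) == 0L || length(unique(ok$year)) < 2L) next
        for (sx in c("female", "male", NULL)) {
          fits[[length(fits) + 1L]] <-
            tryCatch(trend_irr(cells, outcome = oc, sex = sx,
                               alpha = config$alpha),
                     error = function(e) NULL)
        }
        fits[[length(fits) + 1L]] <-
          tryCatch(trend_irr(cells, outcome = oc, alpha = config$alpha),
                   error = function(e) NULL)
        lrs[[length(lrs) + 1L]] <-
          tryCatch(cbind(outcome = oc, interaction_lr_test(ok)),
                   error = function(e) NULL)
      }
      fits <- rbindlist(Filter(Negate(is.null), fits))
      lrs <- rbindlist(Filter(Negate(is.null), lrs))
      fwrite(fits, artifact(config, "trend_summary.csv"))
      fwrite(lrs, artifact(config, "trend_lr_tests.csv"))
      say("trend: ", nrow(fits), " stratum fits, ", nrow(lrs), " LR tests")
      c(trend = artifact(config, "trend_summary.csv"),
        lr = artifact(config, "trend_lr_tests.csv"))
    },
    report = {
      inc <- fread(need_artifact(artifact(config, "incidence_rates.csv"),
                                 "rates"))
      prev <- fread(need_artifact(artifact(config, "prevalence.csv"),
                                  "rates"))
      inc[, `:=`(rate = round_half_away(rate),
                 ci_low = round_half_away(ci_low),
                 ci_high = round_half_away(ci_high),
                 marker = ifelse(observable %in% TRUE, "", "unobservable"))]
      prev[, `:=`(percent = round_half_away(percent, 2L),
                  marker = ifelse(observable %in% TRUE, "", "unobservable"))]
      fwrite(inc, artifact(config, "report_incidence.csv"))
      fwrite(prev, artifact(config, "report_prevalence.csv"))
      cfg_path <- artifact(config, "config.yaml")
      write_pipeline_config(config, cfg_path)
      manifest <- list(
        package = "rxcohort",
        version = as.character(packageVersion("rxcohort")),
        seed = config$sim$seed,
        config_md5 = unname(tools::md5sum(cfg_path)),
        artifacts = sort(setdiff(list.files(config$out_dir),
                                 "manifest.json")))
      jsonlite::write_json(manifest, artifact(config, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      n_unobs <- sum(inc$marker != "") + sum(prev$marker != "")
      if (n_unobs > 0)
        say("report: ", n_unobs,
            " unobservable cells marked in the report tables")
      say("report: written to ", config$out_dir)
      c(report_incidence = artifact(config, "report_incidence.csv"),
        report_prevalence = artifact(config, "report_prevalence.csv"),
        manifest = artifact(config, "manifest.json"))
    }))
  invisible(out)
}

## year-by-age interaction LR test on observable cells of one outcome
interaction_lr_test <- function(cells) {
  d <- as.data.table(cells)
  d[, year_c := year - mean(range(year))]
  multi_sex <- length(unique(d$sex)) > 1L
  f0 <- count ~ year_c + factor(age_band)
  f1 <- count ~ year_c * factor(age_band)
  if (multi_sex) {
    f0 <- update(f0, . ~ . + factor(sex))
    f1 <- update(f1, . ~ . + factor(sex))
  }
  null_fit <- fit_poisson(f0, d, offset = "person_years")
  alt_fit <- fit_poisson(f1, d, offset = "person_years")
  lr_test(null_fit, alt_fit)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  sim <- config$sim
  lst <- list(
    out_dir = config$out_dir,
    dispensings_path = config$dispensings_path,
    population_path = config$population_path,
    coverage = list(start_date = format(config$coverage$start_date),
                    end_date = format(config$coverage$end_date)),
    windows = list(washout_months = config$windows$washout_months,
                   lookforward_months = config$windows$lookforward_months),
    years = config$years, alpha = config$alpha, ci_method = config$ci_method,
    sim = c(sim[setdiff(names(sim), c("pyramid", "onset_rate",
                                      "modality_mix"))],
            list(modality_mix = as.list(sim$modality_mix),
                 pyramid = as.list(sim$pyramid),
                 onset_rate = as.list(sim$onset_rate)))
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_pipeline_config()] (or hand
#'   authored with the same structure).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  simargs <- lst$sim
  simargs$modality_mix <- unlist(simargs$modality_mix)
  simargs$pyramid <- as.data.table(simargs$pyramid)
  simargs$onset_rate <- as.data.table(simargs$onset_rate)
  sim <- do.call(simulation_config, simargs)
  pipeline_config(
    out_dir = lst$out_dir,
    coverage = registry_coverage(lst$coverage$start_date,
                                 lst$coverage$end_date),
    windows = window_config(lst$windows$washout_months,
                            lst$windows$lookforward_months),
    sim = sim,
    dispensings_path = lst$dispensings_path,
    population_path = lst$population_path,
    years = unlist(lst$years),
    alpha = lst$alpha, ci_method = lst$ci_method)
}
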