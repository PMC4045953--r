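## ATC code shape for full dispensing records: letter, 2 digits, letter,
## letter, 2 digits (7 characters, e.g. "A10BA02").
ATC_FULL_RE <- "^[A-Za-z][0-9]{2}[A-Za-z]{2}[0-9]{2}$"

DISPENSING_COLS <- c("person_id", "dispense_date", "atc_code", "sex",
                     "birth_year")
POPULATION_COLS <- c("year", "sex", "age", "count")
SEX_LEVELS <- c("female", "male")

#' Classify an ATC code into a blood glucose-lowering drug class
#'
#' Prefix-based classification within ATC group A10 (drugs used in
#' diabetes): codes beginning `A10A` are insulins and analogues
#' (`"INSULIN"`), codes beginning `A10B` are oral and other blood
#' glucose-lowering drugs (`"OAD"`), other `A10`-prefixed codes are
#' `"ANY_A10"`, and everything else is `"OTHER"`. Pure function of the first
#' four characters for A10 codes; accepts prefixes for class queries.
#'
#' @param atc_code character vector of ATC codes or prefixes.
#' @return character vector in `c("INSULIN", "OAD", "ANY_A10", "OTHER")`.
#' @examples
#' classify_atc(c("A10AB01", "A10BA02", "C10AA05", "A10"))
#' @export
classify_atc <- function(atc_code) {
  if (!is.character(atc_code) || any(is.na(atc_code)) || any(!nzchar(atc_code)))
    stop("atc_code must be non-empty character strings", call. = FALSE)
  out <- rep("OTHER", length(atc_code))
  a10 <- startsWith(atc_code, "A10")
  out[a10] <- "ANY_A10"
  out[startsWith(atc_code, "A10A")] <- "INSULIN"
  out[startsWith(atc_code, "A10B")] <- "OAD"
  out
}

validate_dispensings <- function(dt, coverage) {
  miss <- setdiff(DISPENSING_COLS, names(dt))
  if (length(miss))
    stop("dispensing data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(dt), DISPENSING_COLS)
  if (length(extra))
    stop("dispensing data has unknown column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  setcolorder(dt, DISPENSING_COLS)

  raw <- as.character(dt$dispense_date)
  dt[, dispense_date := as.Date(raw, format = "%Y-%m-%d")]
  bad <- which(is.na(dt$dispense_date))
  if (length(bad))
    stop("malformed dispense_date in row(s): ",
         paste(head(bad, 5L), collapse = ", "),
         " (expected ISO-8601 YYYY-MM-DD, got e.g. '", raw[bad[1L]], "')",
         call. = FALSE)

  bad <- which(!grepl(ATC_FULL_RE, dt$atc_code))
  if (length(bad))
    stop("invalid ATC code in row(s): ", paste(head(bad, 5L), collapse = ", "),
         " (full 7-character codes required, got e.g. '",
         dt$atc_code[bad[1L]], "')", call. = FALSE)

  bad <- which(!dt$sex %in% SEX_LEVELS)
  if (length(bad))
    stop("sex must be one of ", paste(SEX_LEVELS, collapse = "/"),
         "; bad row(s): ", paste(head(bad, 5L), collapse = ", "), call. = FALSE)

  dt[, birth_year := as.integer(birth_year)]
  if (anyNA(dt$birth_year))
    stop("birth_year must be an integer year", call. = FALSE)

  if (!is.null(coverage)) {
    out_of_cov <- which(dt$dispense_date < coverage$start_date |
                          dt$dispense_date > coverage$end_date)
    if (length(out_of_cov))
      stop("dispense_date outside registry coverage (",
           format(coverage$start_date), " to ", format(coverage$end_date),
           ") in row(s): ", paste(head(out_of_cov, 5L), collapse = ", "),
           call. = FALSE)
  }
  setorder(dt, person_id, dispense_date, atc_code)
  dt[]
}

#' Read dispensing records from a CSV file
#'
#' Expects a comma-delimited UTF-8 file with a mandatory header row naming
#' exactly the columns `person_id`, `dispense_date` (ISO-8601 day
#' resolution), `atc_code` (full 7-character ATC code), `sex`
#' (`female`/`male`), `birth_year`. Records are validated and returned
#' sorted by person and date; any record outside `coverage` is an error.
#'
#' @param path path to the CSV file.
#' @param coverage a [registry_coverage()]; pass `NULL` to skip the coverage
#'   check.
#' @return a `data.table` of validated dispensing records.
#' @seealso [write_dispensings()], [classify_registry()]
#' @export
read_dispensings <- function(path, coverage = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path, colClasses = list(character = "person_id"),
              encoding = "UTF-8")
  if (nrow(dt) == 0L) {
    dt <- data.table(person_id = character(), dispense_date = as.Date(character()),
                     atc_code = character(), sex = character(),
                     birth_year = integer())
    return(dt)
  }
  validate_dispensings(dt, coverage)
}

#' Write dispensing records to CSV
#'
#' Inverse of [read_dispensings()]: writes the five-column dispensing CSV
#' so that a write-then-read round trip is the identity on field values.
#'
#' @param records dispensing records (`data.frame` with the five standard
#'   columns).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dispensings <- function(records, path) {
  dt <- as.data.table(records)[, DISPENSING_COLS, with = FALSE]
  fwrite(dt, path, dateTimeAs = "ISO")
  invisible(path)
}

#' Read annual population denominators from a CSV file
#'
#' Expects columns `year` (count refers to Jan 1 of that year), `sex`
#' (`female`/`male`), `age` (integer years), `count` (non-negative).
#' Duplicate `(year, sex, age)` strata and negative counts are errors.
#'
#' @param path path to the CSV file.
#' @return a `data.table` of population counts.
#' @seealso [person_years()]
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path, encoding = "UTF-8")
  if (nrow(dt) == 0L)
    return(data.table(year = integer(), sex = character(), age = integer(),
                      count = numeric()))
  validate_population(dt)
}

validate_population <- function(dt) {
  miss <- setdiff(POPULATION_COLS, names(dt))
  if (length(miss))
    stop("population data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- as.data.table(dt)[, POPULATION_COLS, with = FALSE]
  dt[, `:=`(year = as.integer(year), age = as.integer(age),
            count = as.numeric(count))]
  if (anyNA(dt$year) || anyNA(dt$age) || anyNA(dt$count))
    stop("population year/age/count must be numeric", call. = FALSE)
  if (any(!dt$sex %in% SEX_LEVELS))
    stop("population sex must be one of ", paste(SEX_LEVELS, collapse = "/"),
         call. = FALSE)
  if (any(dt$count < 0))
    stop("population counts must be non-negative", call. = FALSE)
  dup <- dt[, .N, by = .(year, sex, age)][N > 1L]
  if (nrow(dup))
    stop("duplicate population stratum (year, sex, age): e.g. ",
         dup$year[1L], "/", dup$sex[1L], "/", dup$age[1L], call. = FALSE)
  setorder(dt, year, sex, age)
  dt[]
}

#' Write population denominators to CSV
#'
#' @param pop population counts (`data.frame` with columns `year`, `sex`,
#'   `age`, `count`).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_population <- function(pop, path) {
  dt <- as.data.table(pop)[, POPULATION_COLS, with = FALSE]
  fwrite(dt, path)
  invisible(path)
}
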