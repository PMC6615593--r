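## CSV ingest for the three panel inputs: reported events, reference
## population estimates and country metadata. All readers are strict:
## malformed values, duplicate keys and invariant violations are errors
## naming the offending rows, and empty cells / literal "NA" become missing
## values, never zero.

REPORTED_SCHEMA <- c("country_code", "year", "vaccine",
                     "doses_administered", "target_population")
REFERENCE_SCHEMA <- c("country_code", "year", "live_births",
                      "surviving_infants")
META_SCHEMA <- c("country_code", "region", "membership_start_year",
                 "first_reporting_year", "has_reference_estimates",
                 "bcg_in_schedule", "bcg_target_is_full_birth_cohort",
                 "bcg_target_age_under_one", "dtp3_target_age_under_one",
                 "ever_reported_bcg_target", "ever_reported_dtp3_target")
META_OPTIONAL <- c("bcg_excluded_years", "dtp3_excluded_years")

read_checked_csv <- function(path, col_types, required, optional = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  x <- readr::read_csv(path, col_types = col_types, na = c("", "NA"),
                       progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop("parse error in ", path, " at row ", probs$row[1], ": expected ",
         probs$expected[1], ", got '", probs$actual[1], "'", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x[, c(required, intersect(optional, names(x)))]
}

fail_rows <- function(bad, what) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    stop(what, " at data row(s) ", paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) " ..." else "", call. = FALSE)
  }
}

is_whole <- function(x) is.na(x) | abs(x - round(x)) < 1e-8

#' Read a reported-data panel of country-by-year-by-vaccine events
#'
#' One row per (country, year, vaccine) reporting event carrying the doses
#' administered and the target population the country reported for that
#' vaccine. For BCG the target population proxies reported live births; for
#' DTP3 (and DTP1) it proxies reported surviving infants.
#'
#' @param path Path to a CSV file with columns
#'   `country_code,year,vaccine,doses_administered,target_population`.
#' @param year_range Length-2 integer vector of the first and last admissible
#'   reporting year (default 2000--2016).
#' @return A tibble with one validated [ReportingEvent-like] row per input
#'   row; empty cells and literal `"NA"` become `NA`.
#' @export
read_reported_panel <- function(path, year_range = c(2000L, 2016L)) {
  x <- read_checked_csv(
    path,
    readr::cols(country_code = readr::col_character(),
                year = readr::col_integer(),
                vaccine = readr::col_character(),
                doses_administered = readr::col_double(),
                target_population = readr::col_double()),
    REPORTED_SCHEMA)
  fail_rows(is.na(x$country_code), "missing country_code")
  fail_rows(is.na(x$year) | x$year < year_range[1] | x$year > year_range[2],
            paste0("year outside ", year_range[1], "-", year_range[2]))
  fail_rows(!(x$vaccine %in% vaccine_codes()),
            paste0("vaccine not one of ", paste(vaccine_codes(), collapse = "/")))
  fail_rows(!is.na(x$doses_administered) &
              (x$doses_administered < 0 | !is_whole(x$doses_administered)),
            "negative or non-integer doses_administered")
  fail_rows(!is.na(x$target_population) &
              (x$target_population <= 0 | !is_whole(x$target_population)),
            "nonpositive or non-integer target_population")
  key <- paste(x$country_code, x$year, x$vaccine)
  fail_rows(duplicated(key) | duplicated(key, fromLast = TRUE),
            "duplicate (country_code, year, vaccine) key")
  x
}

#' Read a reference panel of live births and surviving infants
#'
#' Reads projected live births (LB) and surviving infants (SI) per country
#' and year from a reference source (for example United Nations population
#' projections). The panel must be internally consistent (`SI <= LB`, both
#' positive) and complete: a full rectangle over the requested countries and
#' years, because the reference source has no missing data for covered
#' countries.
#'
#' @param path CSV with columns
#'   `country_code,year,live_births,surviving_infants`.
#' @param countries Optional character vector of countries that must be
#'   covered; defaults to the countries present in the file.
#' @param years Optional integer vector of years that must be covered;
#'   defaults to the years present in the file.
#' @return A validated tibble, one row per (country, year).
#' @export
read_reference_panel <- function(path, countries = NULL, years = NULL) {
  x <- read_checked_csv(
    path,
    readr::cols(country_code = readr::col_character(),
                year = readr::col_integer(),
                live_births = readr::col_double(),
                surviving_infants = readr::col_double()),
    REFERENCE_SCHEMA)
  fail_rows(is.na(x$live_births) | x$live_births <= 0,
            "missing or nonpositive live_births")
  fail_rows(is.na(x$surviving_infants) | x$surviving_infants <= 0,
            "missing or nonpositive surviving_infants")
  fail_rows(x$surviving_infants > x$live_births,
            "surviving_infants greater than live_births")
  key <- paste(x$country_code, x$year)
  fail_rows(duplicated(key), "duplicate (country_code, year) key")
  if (is.null(countries)) countries <- unique(x$country_code)
  if (is.null(years)) years <- sort(unique(x$year))
  want <- paste(rep(countries, each = length(years)), years)
  gaps <- setdiff(want, key)
  if (length(gaps) > 0) {
    stop("reference panel incomplete; missing (country year): ",
         paste(utils::head(gaps, 5), collapse = "; "),
         if (length(gaps) > 5) " ..." else "", call. = FALSE)
  }
  x
}

#' Read country metadata driving the eligibility cascade
#'
#' One row per country: WHO region, membership and first-reporting years,
#' whether the reference source covers the country, and the schedule /
#' target-definition booleans consumed by [apply_eligibility()]. Two
#' optional columns, `bcg_excluded_years` and `dtp3_excluded_years`, hold
#' semicolon-separated year lists for country-years whose target definition
#' failed the inclusion criteria only in those years.
#'
#' @param path CSV path; see the package README for the full column list.
#' @return A validated tibble, one row per country.
#' @export
read_country_meta <- function(path) {
  lgl <- readr::col_logical()
  x <- read_checked_csv(
    path,
    readr::cols(country_code = readr::col_character(),
                region = readr::col_character(),
                membership_start_year = readr::col_integer(),
                first_reporting_year = readr::col_integer(),
                has_reference_estimates = lgl,
                bcg_in_schedule = lgl,
                bcg_target_is_full_birth_cohort = lgl,
                bcg_target_age_under_one = lgl,
                dtp3_target_age_under_one = lgl,
                ever_reported_bcg_target = lgl,
                ever_reported_dtp3_target = lgl,
                bcg_excluded_years = readr::col_character(),
                dtp3_excluded_years = readr::col_character()),
    META_SCHEMA, META_OPTIONAL)
  fail_rows(duplicated(x$country_code), "duplicate country_code")
  fail_rows(!(x$region %in% region_codes()), "unknown region code")
  fail_rows(is.na(x$membership_start_year) | is.na(x$first_reporting_year) |
              x$first_reporting_year < x$membership_start_year,
            "first_reporting_year before membership_start_year")
  for (col in META_OPTIONAL) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  x
}

## "2004;2007" -> integer vector; NA/"" -> integer(0)
parse_year_list <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}
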