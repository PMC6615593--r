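## Aggregation of flag records into the reporting surfaces: per-indicator
## tallies (events and countries, at "any year" / ">=5 years" / ">=10
## years"), flag-count sums and distributions per year, direction of the
## reference differences, and regional denominator sums.

#' Sum fired flags per country-year
#'
#' Non-evaluable flags contribute 0. Only country-years with at least one
#' evaluable flag appear (those are the country-years in the analysis set).
#'
#' @param flags Flag tibble from [evaluate_flags()].
#' @return Tibble `country_code, year, n_evaluable, n_flags` with
#'   `n_flags` in 0..9.
#' @export
sum_flags_per_country_year <- function(flags) {
  out <- dplyr::summarise(
    dplyr::group_by(flags, country_code, year),
    n_evaluable = sum(evaluable),
    n_flags = sum(fired),
    .groups = "drop")
  out[out$n_evaluable > 0, ]
}

#' Tabulate per-indicator event and country tallies
#'
#' For each flag (and threshold variant, when flag tibbles evaluated at
#' several thresholds are concatenated): the number of evaluable reporting
#' events, the number flagged with its percentage (rounded to the nearest
#' integer, half away from zero), and country tallies -- countries flagged
#' in any year, in 5 or more years and in 10 or more years, against the
#' base of countries with at least one evaluable event for that indicator.
#'
#' @param flags Flag tibble from [evaluate_flags()]; bind rows of several
#'   runs to tabulate multiple threshold variants.
#' @param decisions Optional decisions tibble; when given, every included
#'   country-year must be covered by `flags` (consistency check).
#' @return Tibble with one row per (flag_id, threshold).
#' @export
tabulate_indicator_summary <- function(flags, decisions = NULL) {
  if (!is.null(decisions)) {
    inc <- unique(paste(decisions$country_code[decisions$included],
                        decisions$year[decisions$included]))
    have <- unique(paste(flags$country_code, flags$year))
    if (length(setdiff(inc, have)) > 0) {
      stop("flags do not cover all included country-years", call. = FALSE)
    }
  }
  per_cy <- dplyr::summarise(
    dplyr::group_by(flags, flag_id, threshold, country_code),
    n_evaluable = sum(evaluable),
    n_years_fired = sum(fired),
    .groups = "drop")
  per_cy <- per_cy[per_cy$n_evaluable > 0, ]
  ev <- dplyr::summarise(
    dplyr::group_by(flags, flag_id, threshold),
    events_evaluable = sum(evaluable),
    events_fired = sum(fired),
    .groups = "drop")
  co <- dplyr::summarise(
    dplyr::group_by(per_cy, flag_id, threshold),
    countries_total = dplyr::n(),
    countries_fired_any_year = sum(n_years_fired >= 1),
    countries_fired_ge5_years = sum(n_years_fired >= 5),
    countries_fired_ge10_years = sum(n_years_fired >= 10),
    .groups = "drop")
  out <- dplyr::left_join(ev, co, by = c("flag_id", "threshold"))
  out$events_fired_pct <- ifelse(
    out$events_evaluable > 0,
    as.integer(round_half_away(100 * out$events_fired / out$events_evaluable)),
    NA_integer_)
  out <- dplyr::rename(out, threshold_variant = "threshold")
  out[, c("flag_id", "threshold_variant", "events_evaluable", "events_fired",
          "events_fired_pct", "countries_total", "countries_fired_any_year",
          "countries_fired_ge5_years", "countries_fired_ge10_years")]
}

#' Distribution of countries by number of flags fired, per year
#'
#' Histogram over the bins 0, 1, 2, 3, 4 and 5+ of the per-country flag
#' sums, for each requested year. Bin counts conserve the number of
#' countries with at least one evaluable flag that year.
#'
#' @param per_country_year Output of [sum_flags_per_country_year()].
#' @param years Years to tabulate; must lie within the data's year range.
#' @return Tibble `year, bin, n_countries` with six bins per year.
#' @export
flag_count_distribution <- function(per_country_year, years) {
  rng <- range(per_country_year$year)
  bad <- years[years < rng[1] | years > rng[2]]
  if (length(bad) > 0) {
    stop("year(s) outside the panel range ", rng[1], "-", rng[2], ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bins <- c("0", "1", "2", "3", "4", "5+")
  out <- lapply(years, function(y) {
    n <- per_country_year$n_flags[per_country_year$year == y]
    lab <- ifelse(n >= 5, "5+", as.character(n))
    tibble::tibble(year = y, bin = bins,
                   n_countries = as.integer(table(factor(lab, levels = bins))))
  })
  dplyr::bind_rows(out)
}

#' Direction of the reference-divergence flags
#'
#' Splits fired reference-divergence events into those whose reported
#' denominator was above the reference projection (positive percent
#' difference) and those below (negative). Higher plus lower always equals
#' the fired total.
#'
#' @param flags Flag tibble; only the LB and SI reference-divergence flags
#'   are used.
#' @return Tibble `flag_id, higher, lower, fired_total`.
#' @export
direction_analysis <- function(flags) {
  f <- flags[flags$flag_id %in% c("F7_LB_REF_DIFF_GT10",
                                  "F8_SI_REF_DIFF_GT10"), ]
  dplyr::summarise(
    dplyr::group_by(f, flag_id),
    higher = sum(fired & statistic_value > 0),
    lower = sum(fired & statistic_value < 0),
    fired_total = sum(fired),
    .groups = "drop")
}

#' Regional sums of reported versus reference denominators
#'
#' Per (region, year): the sum of reported LB (BCG target populations) and
#' SI (DTP3 target populations) over included country-years, next to the
#' sum of the reference projections over the same included set. A country
#' that is in the analysis set but did not report that year contributes 0
#' to the reported sum while its reference projection stays in the
#' reference sum -- non-reporting shows up as a dip of the reported series
#' only.
#'
#' @inheritParams derive_statistics
#' @param meta Country metadata tibble carrying `region`.
#' @return Tibble `region, year, reported_lb_sum, reported_si_sum,
#'   reference_lb_sum, reference_si_sum`.
#' @export
regional_aggregate <- function(reports, reference, decisions, meta) {
  if (any(!meta$region %in% region_codes())) {
    stop("unknown region code in metadata", call. = FALSE)
  }
  w <- panel_wide(reports, reference, decisions)
  w <- dplyr::left_join(w, meta[, c("country_code", "region")],
                        by = "country_code")
  w <- w[w$inc_bcg | w$inc_dtp3, ]
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  dplyr::summarise(
    dplyr::group_by(w, region, year),
    reported_lb_sum = sum(zero_na(lb[inc_bcg])),
    reported_si_sum = sum(zero_na(si[inc_dtp3])),
    reference_lb_sum = sum(ref_lb[inc_bcg]),
    reference_si_sum = sum(ref_si[inc_dtp3]),
    .groups = "drop")
}
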