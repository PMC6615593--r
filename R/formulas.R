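## The four arithmetic primitives of the denominator quality assessment,
## plus the denominator-error -> coverage-error sensitivity. All are
## vectorised, keep full floating precision, and propagate NA (missing in,
## missing out); genuinely invalid inputs (nonpositive denominators) are
## errors, never silently missing.

#' Administrative vaccination coverage
#'
#' `100 * doses / target_population`, unrounded. Values above 100% signal a
#' possibly underestimated target population.
#'
#' @param doses Doses administered in the year (nonnegative).
#' @param target_population Reported target population (positive).
#' @return Coverage in percent; `NA` where either input is missing.
#' @export
coverage <- function(doses, target_population) {
  if (any(!is.na(target_population) & target_population <= 0)) {
    stop("target_population must be positive", call. = FALSE)
  }
  if (any(!is.na(doses) & doses < 0)) {
    stop("doses must be nonnegative", call. = FALSE)
  }
  100 * doses / target_population
}

#' Year-to-year percent difference
#'
#' `100 * (value_year2 / value_year1 - 1)`, the signed percent change from
#' one year to the next. Applies identically to denominator series (LB, SI)
#' and to coverage series.
#'
#' @param value_year1 Value in the earlier year (positive).
#' @param value_year2 Value in the later year.
#' @return Signed percent difference; `NA` where either input is missing.
#' @export
yoy_percent_difference <- function(value_year1, value_year2) {
  if (any(!is.na(value_year1) & value_year1 <= 0)) {
    stop("value_year1 must be positive", call. = FALSE)
  }
  100 * (value_year2 / value_year1 - 1)
}

#' Percent difference of a reported value from a reference estimate
#'
#' `100 * (reported - reference) / reference`. Negative means the country
#' reported fewer than the reference projection; positive means more.
#'
#' @param reported Reported target population.
#' @param reference Reference projection (positive).
#' @return Signed percent difference; `NA` where `reported` is missing.
#' @export
percent_difference_vs_reference <- function(reported, reference) {
  if (any(!is.na(reference) & reference <= 0)) {
    stop("reference must be positive", call. = FALSE)
  }
  100 * (reported - reference) / reference
}

#' Implied infant mortality rate from reported denominators
#'
#' `1000 * (LB - SI) / LB`, using the live births and surviving infants a
#' country reported for the same year. A negative value means more
#' surviving infants than live births were reported, which is infeasible
#' and flags inconsistent denominators.
#'
#' @param live_births Reported live births (positive).
#' @param surviving_infants Reported surviving infants.
#' @return Rate per 1000 live births; `NA` where either input is missing.
#' @export
implied_imr <- function(live_births, surviving_infants) {
  if (any(!is.na(live_births) & live_births <= 0)) {
    stop("live_births must be positive", call. = FALSE)
  }
  1000 * (live_births - surviving_infants) / live_births
}

#' Coverage error induced by a relative denominator error
#'
#' If the true coverage is `c` and the denominator is misstated by a
#' relative error `e` (e.g. `-0.10` for a 10% underestimate), the
#' calculated coverage becomes `c / (1 + e)`; the returned value is the
#' error in percentage points, `c / (1 + e) - c`. It is positive when the
#' denominator is underestimated and grows with the true coverage, so high
#' coverage estimates are the most sensitive to denominator errors.
#'
#' @param true_coverage True coverage in percent (nonnegative).
#' @param relative_denominator_error Relative error of the denominator as a
#'   fraction, strictly greater than -1.
#' @return Coverage error in percentage points.
#' @export
coverage_error_from_denominator_error <- function(true_coverage,
                                                  relative_denominator_error) {
  if (any(!is.na(relative_denominator_error) &
            relative_denominator_error <= -1)) {
    stop("relative_denominator_error must be greater than -1", call. = FALSE)
  }
  if (any(!is.na(true_coverage) & true_coverage < 0)) {
    stop("true_coverage must be nonnegative", call. = FALSE)
  }
  true_coverage / (1 + relative_denominator_error) - true_coverage
}
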