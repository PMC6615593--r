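## Flag engine: derive the per-country-year statistics (coverage,
## year-to-year differences, reference differences, implied IMR) and
## evaluate the nine quality flags over the eligible reporting grid.

#' Thresholds used by the flag engine
#'
#' All flag thresholds are strict inequalities: a year-to-year difference of
#' exactly 10% does not fire. The auxiliary 5% threshold is not part of the
#' nine flags; it exists so fluctuation tallies can be reported at both 5%
#' and 10%.
#'
#' @param denom_yoy_pct Year-to-year denominator fluctuation threshold
#'   (percent, default 10).
#' @param cov_yoy_pct Year-to-year coverage fluctuation threshold (default 10).
#' @param ref_diff_pct Reference-divergence threshold (default 10).
#' @param aux_yoy_pct Auxiliary fluctuation threshold for tabulation
#'   variants (default 5).
#' @param coverage_cap_pct Coverage cap (default 100).
#' @return A named list of class `denomqc_thresholds`.
#' @export
flag_thresholds <- function(denom_yoy_pct = 10, cov_yoy_pct = 10,
                            ref_diff_pct = 10, aux_yoy_pct = 5,
                            coverage_cap_pct = 100) {
  th <- list(denom_yoy_pct = denom_yoy_pct, cov_yoy_pct = cov_yoy_pct,
             ref_diff_pct = ref_diff_pct, aux_yoy_pct = aux_yoy_pct,
             coverage_cap_pct = coverage_cap_pct)
  if (any(vapply(th, function(v) !is.numeric(v) || length(v) != 1 ||
                   is.na(v) || v <= 0, logical(1)))) {
    stop("all thresholds must be single positive numbers", call. = FALSE)
  }
  structure(th, class = "denomqc_thresholds")
}

#' Read flag thresholds from a YAML config file
#'
#' @param path YAML file whose keys are the arguments of
#'   [flag_thresholds()]; absent keys take their defaults.
#' @return A `denomqc_thresholds` list.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(flag_thresholds))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(flag_thresholds, cfg)
}

## Wide per-country-year table joining reports, eligibility and reference.
## Reported LB = BCG target for BCG-eligible events; SI = DTP3 target for
## DTP3-eligible events; ineligible or unreported cells are NA.
panel_wide <- function(reports, reference, decisions) {
  dec <- decisions[decisions$vaccine %in% c("BCG", "DTP3"), ]
  dec_w <- tidyr::pivot_wider(
    dec[, c("country_code", "year", "vaccine", "included")],
    names_from = "vaccine", values_from = "included")
  names(dec_w)[names(dec_w) == "BCG"] <- "inc_bcg"
  names(dec_w)[names(dec_w) == "DTP3"] <- "inc_dtp3"
  if (is.null(dec_w$inc_bcg)) dec_w$inc_bcg <- FALSE
  if (is.null(dec_w$inc_dtp3)) dec_w$inc_dtp3 <- FALSE
  dec_w$inc_bcg[is.na(dec_w$inc_bcg)] <- FALSE
  dec_w$inc_dtp3[is.na(dec_w$inc_dtp3)] <- FALSE

  rep_w <- tidyr::pivot_wider(
    reports[, c("country_code", "year", "vaccine",
                "doses_administered", "target_population")],
    names_from = "vaccine",
    values_from = c("doses_administered", "target_population"))
  for (col in c("doses_administered_BCG", "doses_administered_DTP3",
                "target_population_BCG", "target_population_DTP1",
                "target_population_DTP3")) {
    if (is.null(rep_w[[col]])) rep_w[[col]] <- NA_real_
  }
  rep_w <- dplyr::rename(rep_w,
    doses_bcg = "doses_administered_BCG",
    doses_dtp3 = "doses_administered_DTP3",
    target_bcg = "target_population_BCG",
    target_dtp1 = "target_population_DTP1",
    target_dtp3 = "target_population_DTP3")

  w <- dplyr::left_join(dec_w, rep_w, by = c("country_code", "year"))
  w <- dplyr::left_join(
    w,
    dplyr::rename(reference[, c("country_code", "year", "live_births",
                                "surviving_infants")],
                  ref_lb = "live_births", ref_si = "surviving_infants"),
    by = c("country_code", "year"))
  w$lb <- ifelse(w$inc_bcg, w$target_bcg, NA_real_)
  w$si <- ifelse(w$inc_dtp3, w$target_dtp3, NA_real_)
  w$doses_bcg <- ifelse(w$inc_bcg, w$doses_bcg, NA_real_)
  w$doses_dtp3 <- ifelse(w$inc_dtp3, w$doses_dtp3, NA_real_)
  dplyr::arrange(w, country_code, year)
}

## year-over-year percent difference down a column, requiring consecutive
## years and a positive, non-missing predecessor; never bridges gaps
lag_yoy <- function(value, year) {
  prev <- dplyr::lag(value)
  prev_year <- dplyr::lag(year)
  ok <- !is.na(prev) & prev > 0 & !is.na(prev_year) & prev_year == year - 1
  out <- rep(NA_real_, length(value))
  out[ok] <- 100 * (value[ok] / prev[ok] - 1)
  out
}

#' Derive the per-country-year statistics underlying the flags
#'
#' Computes, for every country-year on the eligibility grid, administrative
#' BCG and DTP3 coverage, year-to-year percent differences of the reported
#' denominators and of coverage, percent differences of the reported
#' denominators from the reference projections, and the implied infant
#' mortality rate. A statistic is `NA` exactly when a required input is
#' missing or ineligible, or when its predecessor-year value is.
#'
#' @param reports Reported panel tibble ([read_reported_panel()]).
#' @param reference Reference panel tibble ([read_reference_panel()]).
#' @param decisions Eligibility decisions for BCG and DTP3 combined
#'   (`rbind` of the two [apply_eligibility()] decision tibbles).
#' @return Tibble with one row per country-year on the grid.
#' @export
derive_statistics <- function(reports, reference, decisions) {
  w <- panel_wide(reports, reference, decisions)
  w$coverage_bcg <- coverage(w$doses_bcg, w$lb)
  w$coverage_dtp3 <- coverage(w$doses_dtp3, w$si)
  w <- dplyr::group_by(w, country_code)
  w <- dplyr::mutate(
    w,
    yoy_diff_lb = lag_yoy(lb, year),
    yoy_diff_si = lag_yoy(si, year),
    yoy_diff_cov_bcg = lag_yoy(coverage_bcg, year),
    yoy_diff_cov_dtp3 = lag_yoy(coverage_dtp3, year))
  w <- dplyr::ungroup(w)
  w$pct_diff_lb_vs_ref <- ifelse(
    !is.na(w$lb) & !is.na(w$ref_lb),
    percent_difference_vs_reference(w$lb, w$ref_lb), NA_real_)
  w$pct_diff_si_vs_ref <- ifelse(
    !is.na(w$si) & !is.na(w$ref_si),
    percent_difference_vs_reference(w$si, w$ref_si), NA_real_)
  w$implied_imr <- ifelse(
    !is.na(w$lb) & !is.na(w$si) & w$lb > 0,
    implied_imr(w$lb, w$si), NA_real_)
  w
}

## strict exceedance with a relative guard band (~1e-8) so binary
## floating-point noise at an exactly-on-threshold input cannot fire a
## strict inequality; genuine exceedances in count data are far larger
strictly_gt <- function(x, thr) x > thr + 1e-9 * (1 + abs(thr))

## value with the largest absolute magnitude among candidates, rowwise,
## NA-aware; all-NA rows give NA
rowwise_absmax <- function(...) {
  m <- cbind(...)
  out <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    v <- v[!is.na(v)]
    if (length(v) > 0) out[i] <- v[which.max(abs(v))]
  }
  out
}

#' Evaluate the nine denominator quality flags
#'
#' For every country-year with at least one eligible (BCG or DTP3)
#' reporting event, evaluates the nine flags. A flag that cannot be
#' assessed -- missing inputs, no eligible prior year for the fluctuation
#' flags -- is marked `evaluable = FALSE` and never fires. All thresholds
#' are strict: boundary values do not fire.
#'
#' @inheritParams derive_statistics
#' @param thresholds A [flag_thresholds()] list.
#' @return Tibble with columns `country_code, year, flag_id, evaluable,
#'   fired, statistic_value, threshold`, nine rows per eligible
#'   country-year.
#' @export
evaluate_flags <- function(reports, reference, decisions,
                           thresholds = flag_thresholds()) {
  if (!inherits(thresholds, "denomqc_thresholds")) {
    thresholds <- do.call(flag_thresholds, as.list(thresholds))
  }
  s <- derive_statistics(reports, reference, decisions)
  s <- s[s$inc_bcg | s$inc_dtp3, ]

  rec <- function(flag_id, evaluable, statistic, threshold, fired) {
    evaluable[is.na(evaluable)] <- FALSE
    fired <- evaluable & !is.na(fired) & fired
    tibble::tibble(
      country_code = s$country_code, year = s$year, flag_id = flag_id,
      evaluable = evaluable, fired = fired,
      statistic_value = ifelse(evaluable, statistic, NA_real_),
      threshold = threshold)
  }
  th <- thresholds
  yoy_denom <- rowwise_absmax(s$yoy_diff_lb, s$yoy_diff_si)
  yoy_cov <- rowwise_absmax(s$yoy_diff_cov_bcg, s$yoy_diff_cov_dtp3)
  cov_max <- pmax(s$coverage_bcg, s$coverage_dtp3, na.rm = TRUE)
  cov_max[is.na(s$coverage_bcg) & is.na(s$coverage_dtp3)] <- NA_real_

  out <- dplyr::bind_rows(
    rec("F1_LB_MISSING", s$inc_bcg, as.numeric(is.na(s$target_bcg)), NA_real_,
        is.na(s$target_bcg)),
    rec("F2_SI_MISSING", s$inc_dtp3, as.numeric(is.na(s$target_dtp3)), NA_real_,
        is.na(s$target_dtp3)),
    rec("F3_YOY_DENOM_GT10", !is.na(yoy_denom), yoy_denom, th$denom_yoy_pct,
        strictly_gt(abs(yoy_denom), th$denom_yoy_pct)),
    rec("F4_YOY_COV_GT10", !is.na(yoy_cov), yoy_cov, th$cov_yoy_pct,
        strictly_gt(abs(yoy_cov), th$cov_yoy_pct)),
    rec("F5_COV_GT100", !is.na(cov_max), cov_max, th$coverage_cap_pct,
        strictly_gt(cov_max, th$coverage_cap_pct)),
    rec("F6_NEG_IMR", !is.na(s$implied_imr), s$implied_imr, 0,
        strictly_gt(-s$implied_imr, 0)),
    rec("F7_LB_REF_DIFF_GT10", !is.na(s$pct_diff_lb_vs_ref),
        s$pct_diff_lb_vs_ref, th$ref_diff_pct,
        strictly_gt(abs(s$pct_diff_lb_vs_ref), th$ref_diff_pct)),
    rec("F8_SI_REF_DIFF_GT10", !is.na(s$pct_diff_si_vs_ref),
        s$pct_diff_si_vs_ref, th$ref_diff_pct,
        strictly_gt(abs(s$pct_diff_si_vs_ref), th$ref_diff_pct)),
    rec("F9_DTP3_NE_DTP1",
        s$inc_dtp3 & !is.na(s$target_dtp3) & !is.na(s$target_dtp1),
        s$target_dtp3 - s$target_dtp1, NA_real_,
        s$target_dtp3 != s$target_dtp1)
  )
  dplyr::arrange(out, country_code, year,
                 match(flag_id, flag_ids()))
}
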