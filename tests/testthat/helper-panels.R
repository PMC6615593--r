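## Shared fixtures: tiny hand-built panels, a random small-panel generator,
## and an independent brute-force evaluation of the nine flag rules used as
## an oracle against the vectorised engine.

make_meta <- function(countries, region = "AFR", first_year = 2000L) {
  tibble::tibble(
    country_code = countries, region = region,
    membership_start_year = first_year, first_reporting_year = first_year,
    has_reference_estimates = TRUE, bcg_in_schedule = TRUE,
    bcg_target_is_full_birth_cohort = TRUE, bcg_target_age_under_one = TRUE,
    dtp3_target_age_under_one = TRUE, ever_reported_bcg_target = TRUE,
    ever_reported_dtp3_target = TRUE,
    bcg_excluded_years = NA_character_, dtp3_excluded_years = NA_character_)
}

## long reported panel from per-vaccine named vectors of equal length
make_reports <- function(country, years, bcg_target, dtp3_target,
                         dtp1_target = dtp3_target,
                         bcg_doses = NA_real_, dtp3_doses = NA_real_) {
  n <- length(years)
  rec <- function(vac, doses, target) {
    tibble::tibble(country_code = country, year = years, vaccine = vac,
                   doses_administered = rep_len(doses, n),
                   target_population = rep_len(target, n))
  }
  dplyr::bind_rows(rec("BCG", bcg_doses, bcg_target),
                   rec("DTP1", NA_real_, dtp1_target),
                   rec("DTP3", dtp3_doses, dtp3_target))
}

make_reference <- function(countries, years, lb, si = lb * 0.98) {
  g <- expand.grid(country_code = countries, year = years,
                   stringsAsFactors = FALSE)
  tibble::tibble(country_code = g$country_code, year = g$year,
                 live_births = rep_len(lb, nrow(g)),
                 surviving_infants = rep_len(si, nrow(g)))
}

full_decisions <- function(meta, year_range = c(2000L, 2016L)) {
  grid <- build_event_grid(meta, year_range)
  dplyr::bind_rows(apply_eligibility(grid, meta, "BCG")$decisions,
                   apply_eligibility(grid, meta, "DTP3")$decisions)
}

## ---- independent brute-force oracle --------------------------------------
## Re-evaluates each of the nine rules directly from their definitions with
## plain loops and scalar lookups; shares no code with the engine.
oracle_flags <- function(reports, reference, decisions,
                         denom_thr = 10, cov_thr = 10, ref_thr = 10) {
  lookup <- function(c, y, v, field) {
    i <- which(reports$country_code == c & reports$year == y &
                 reports$vaccine == v)
    if (length(i) == 0) NA_real_ else reports[[field]][i[1]]
  }
  incl <- function(c, y, v) {
    i <- which(decisions$country_code == c & decisions$year == y &
                 decisions$vaccine == v)
    length(i) > 0 && any(decisions$included[i])
  }
  ref_val <- function(c, y, field) {
    i <- which(reference$country_code == c & reference$year == y)
    if (length(i) == 0) NA_real_ else reference[[field]][i[1]]
  }
  lb <- function(c, y) if (incl(c, y, "BCG")) lookup(c, y, "BCG", "target_population") else NA_real_
  si <- function(c, y) if (incl(c, y, "DTP3")) lookup(c, y, "DTP3", "target_population") else NA_real_
  cov_of <- function(c, y, v) {
    if (!incl(c, y, v)) return(NA_real_)
    d <- lookup(c, y, v, "doses_administered")
    t <- lookup(c, y, v, "target_population")
    if (is.na(d) || is.na(t)) NA_real_ else 100 * d / t
  }
  yoy <- function(v1, v2) {
    if (is.na(v1) || is.na(v2) || v1 <= 0) NA_real_ else 100 * (v2 / v1 - 1)
  }

  inc_cells <- unique(decisions[decisions$included,
                                c("country_code", "year")])
  out <- list()
  for (r in seq_len(nrow(inc_cells))) {
    c <- inc_cells$country_code[r]; y <- inc_cells$year[r]
    add <- function(id, evaluable, fired) {
      out[[length(out) + 1]] <<- data.frame(
        country_code = c, year = y, flag_id = id,
        evaluable = evaluable, fired = evaluable && isTRUE(fired))
    }
    add("F1_LB_MISSING", incl(c, y, "BCG"),
        incl(c, y, "BCG") && is.na(lookup(c, y, "BCG", "target_population")))
    add("F2_SI_MISSING", incl(c, y, "DTP3"),
        incl(c, y, "DTP3") && is.na(lookup(c, y, "DTP3", "target_population")))
    cand3 <- c(yoy(lb(c, y - 1), lb(c, y)), yoy(si(c, y - 1), si(c, y)))
    cand3 <- cand3[!is.na(cand3)]
    add("F3_YOY_DENOM_GT10", length(cand3) > 0, any(abs(cand3) > denom_thr))
    cand4 <- c(yoy(cov_of(c, y - 1, "BCG"), cov_of(c, y, "BCG")),
               yoy(cov_of(c, y - 1, "DTP3"), cov_of(c, y, "DTP3")))
    cand4 <- cand4[!is.na(cand4)]
    add("F4_YOY_COV_GT10", length(cand4) > 0, any(abs(cand4) > cov_thr))
    cand5 <- c(cov_of(c, y, "BCG"), cov_of(c, y, "DTP3"))
    cand5 <- cand5[!is.na(cand5)]
    add("F5_COV_GT100", length(cand5) > 0, any(cand5 > 100))
    l <- lb(c, y); s <- si(c, y)
    add("F6_NEG_IMR", !is.na(l) && !is.na(s),
        !is.na(l) && !is.na(s) && 1000 * (l - s) / l < 0)
    rl <- ref_val(c, y, "live_births")
    add("F7_LB_REF_DIFF_GT10", !is.na(l) && !is.na(rl),
        !is.na(l) && !is.na(rl) && abs(100 * (l - rl) / rl) > ref_thr)
    rs <- ref_val(c, y, "surviving_infants")
    add("F8_SI_REF_DIFF_GT10", !is.na(s) && !is.na(rs),
        !is.na(s) && !is.na(rs) && abs(100 * (s - rs) / rs) > ref_thr)
    d1 <- lookup(c, y, "DTP1", "target_population")
    add("F9_DTP3_NE_DTP1", !is.na(s) && !is.na(d1),
        !is.na(s) && !is.na(d1) && s != d1)
  }
  do.call(rbind, out)
}

## random panel of at most 5 countries x 5 years with random eligibility,
## missingness and values that straddle every threshold
random_small_panel <- function(seed) {
  set.seed(seed)
  nc <- sample(1:5, 1); nyr <- sample(1:5, 1)
  countries <- paste0("C", seq_len(nc))
  years <- seq(2000L, length.out = nyr)
  meta <- make_meta(countries)
  grid <- build_event_grid(meta, c(min(years), max(years)))
  decisions <- dplyr::bind_rows(lapply(c("BCG", "DTP3"), function(v) {
    inc <- stats::runif(nrow(grid)) > 0.2
    tibble::tibble(country_code = grid$country_code, year = grid$year,
                   vaccine = v, included = inc,
                   exclusion_reason = ifelse(inc, "NONE",
                                             "NEVER_REPORTED_TARGET"))
  }))
  reference <- make_reference(countries, years,
                              lb = round(stats::runif(nc * nyr, 5000, 50000)))
  rows <- list()
  for (c in countries) for (y in years) for (v in c("BCG", "DTP1", "DTP3")) {
    if (stats::runif(1) < 0.1) next  # unreported event
    ref <- reference$live_births[reference$country_code == c &
                                   reference$year == y]
    target <- if (stats::runif(1) < 0.15) NA_real_ else
      max(1, round(ref * stats::runif(1, 0.7, 1.3)))
    doses <- if (stats::runif(1) < 0.15 || is.na(target)) NA_real_ else
      round(target * stats::runif(1, 0.5, 1.2))
    rows[[length(rows) + 1]] <- tibble::tibble(
      country_code = c, year = y, vaccine = v,
      doses_administered = doses, target_population = target)
  }
  empty <- tibble::tibble(country_code = character(), year = integer(),
                          vaccine = character(),
                          doses_administered = numeric(),
                          target_population = numeric())
  reports <- dplyr::bind_rows(c(list(empty), rows))
  list(reports = reports, reference = reference, decisions = decisions)
}

zero_anomaly_rates <- function() {
  stats::setNames(rep(0, 7),
                  c("missing_lb", "missing_si", "denom_jump_gt10",
                    "coverage_gt100", "negative_imr", "ref_divergence_gt10",
                    "dtp_mismatch"))
}
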