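## Synthetic panel generator. Builds a clean, internally consistent
## country-by-year panel first -- reference LB on a smooth per-country
## growth path, SI = LB * (1 - IMR/1000), reported values equal to the
## (rounded) reference and doses consistent with a constant per-country
## true coverage -- then plants anomalies in the reported values only,
## recording every planting in a truth ledger. One seeded RNG stream
## drives all draws in a documented order (country baselines first, then
## anomalies country by country, year by year), so a seed fixes the output
## exactly.

ANOMALY_KINDS <- c("missing_lb", "missing_si", "denom_jump_gt10",
                   "coverage_gt100", "negative_imr", "ref_divergence_gt10",
                   "dtp_mismatch")

#' Configuration for the synthetic panel generator
#'
#' Defaults emulate the real reporting panel: 194 member countries over
#' 2000--2016, region sizes matching the six WHO regions, live-birth
#' cohorts spanning small islands to large countries (drawn log-uniformly),
#' infant mortality between 2 and 80 per 1000, true coverage between 70%
#' and 99% and annual cohort growth between -1% and +3%. Anomaly rates are
#' per country-year probabilities; at most one anomaly is planted per
#' country-year. Anomaly magnitudes are drawn from ranges bounded strictly
#' away from the flag thresholds (margin >= 2 percentage points after
#' growth), so every planted anomaly is recoverable by the flag engine.
#'
#' @param n_countries Number of countries.
#' @param year_range `c(first, last)` years.
#' @param region_weights Named weights for region assignment.
#' @param baseline_lb Range of the year-2000 live-birth cohort (log-uniform).
#' @param imr_per_1000 Range of the per-country infant mortality rate.
#' @param true_coverage Range of the per-country true coverage (percent).
#' @param growth_rate Range of the per-country annual cohort growth rate.
#' @param anomaly_rates Named per-country-year probabilities for the seven
#'   anomaly kinds; their sum must not exceed 1.
#' @param anomaly_magnitudes Named list of magnitude ranges: percent jump
#'   size for `denom_jump_gt10` and `ref_divergence_gt10`, percent coverage
#'   for `coverage_gt100`, the SI/LB ratio for `negative_imr`, and the
#'   percent DTP1/DTP3 target difference for `dtp_mismatch`.
#' @param seed Integer seed.
#' @return A validated list of class `denomqc_config`.
#' @export
generator_config <- function(
    n_countries = 194L,
    year_range = c(2000L, 2016L),
    region_weights = c(AFR = 47, AMR = 35, EMR = 21, EUR = 53,
                       SEAR = 11, WPR = 27),
    baseline_lb = c(2e4, 5e6),
    imr_per_1000 = c(2, 80),
    true_coverage = c(70, 99),
    growth_rate = c(-0.01, 0.03),
    anomaly_rates = c(missing_lb = 0.04, missing_si = 0.04,
                      denom_jump_gt10 = 0.05, coverage_gt100 = 0.06,
                      negative_imr = 0.04, ref_divergence_gt10 = 0.08,
                      dtp_mismatch = 0.05),
    anomaly_magnitudes = list(denom_jump_gt10 = c(15, 50),
                              coverage_gt100 = c(104, 130),
                              negative_imr = c(1.02, 1.15),
                              ref_divergence_gt10 = c(15, 60),
                              dtp_mismatch = c(5, 20)),
    seed = 1L) {
  cfg <- list(n_countries = as.integer(n_countries),
              year_range = as.integer(year_range),
              region_weights = region_weights,
              baseline_lb = baseline_lb, imr_per_1000 = imr_per_1000,
              true_coverage = true_coverage, growth_rate = growth_rate,
              anomaly_rates = anomaly_rates,
              anomaly_magnitudes = anomaly_magnitudes,
              seed = as.integer(seed))
  if (cfg$n_countries < 1) stop("n_countries must be >= 1", call. = FALSE)
  if (length(cfg$year_range) != 2 || cfg$year_range[2] < cfg$year_range[1]) {
    stop("year_range must be c(first, last)", call. = FALSE)
  }
  if (!all(names(region_weights) %in% region_codes())) {
    stop("unknown region in region_weights", call. = FALSE)
  }
  rates <- cfg$anomaly_rates
  if (!all(names(rates) %in% ANOMALY_KINDS)) {
    stop("unknown anomaly kind in anomaly_rates", call. = FALSE)
  }
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("anomaly rates must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  m <- cfg$anomaly_magnitudes
  if (m$denom_jump_gt10[1] < 12 || m$ref_divergence_gt10[1] < 12) {
    stop("jump/divergence magnitudes must exceed the 10% threshold by at ",
         "least 2 percentage points", call. = FALSE)
  }
  if (m$coverage_gt100[1] < 102) {
    stop("coverage_gt100 magnitudes must exceed 100% by at least 2 points",
         call. = FALSE)
  }
  if (m$negative_imr[1] <= 1) {
    stop("negative_imr SI/LB ratio must exceed 1", call. = FALSE)
  }
  if (cfg$true_coverage[2] > 99.5) {
    stop("true_coverage must stay below 99.5% so rounding cannot cross ",
         "the 100% cap", call. = FALSE)
  }
  structure(cfg, class = "denomqc_config")
}

#' Read a generator configuration from a YAML file
#'
#' @param path YAML file whose keys are arguments of [generator_config()].
#' @return A `denomqc_config` list.
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown generator config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$region_weights)) cfg$region_weights <- unlist(cfg$region_weights)
  if (!is.null(cfg$anomaly_rates)) cfg$anomaly_rates <- unlist(cfg$anomaly_rates)
  do.call(generator_config, cfg)
}

#' Generate a synthetic reporting panel with planted anomalies
#'
#' Generates the clean baseline, plants anomalies per the configuration and
#' returns the three pipeline inputs plus the exhaustive truth ledger.
#' Anomalies touch reported values only; the reference panel always
#' satisfies `SI <= LB`. Denominator jumps and reference divergences are
#' single-year spikes that scale targets and doses together (coverage is
#' preserved); a jump is never planted in the first year or directly after
#' another jump/divergence, so its year-to-year signature is always
#' evaluable and above threshold.
#'
#' @param config A [generator_config()] list.
#' @return List with `reports`, `reference`, `meta` (pipeline-ready
#'   tibbles) and `truth` (tibble `country_code, year, anomaly_kind,
#'   planted_value`).
#' @export
generate_panel <- function(config = generator_config()) {
  if (!inherits(config, "denomqc_config")) {
    config <- do.call(generator_config, config)
  }
  set.seed(config$seed)
  years <- seq.int(config$year_range[1], config$year_range[2])
  ny <- length(years)
  n <- config$n_countries
  codes <- vapply(seq_len(n), synthetic_iso3, character(1))

  ## country baselines, drawn country by country
  regions <- sample(names(config$region_weights), n, replace = TRUE,
                    prob = config$region_weights)
  lb0 <- exp(stats::runif(n, log(config$baseline_lb[1]),
                          log(config$baseline_lb[2])))
  imr <- stats::runif(n, config$imr_per_1000[1], config$imr_per_1000[2])
  growth <- stats::runif(n, config$growth_rate[1], config$growth_rate[2])
  cov_bcg <- stats::runif(n, config$true_coverage[1], config$true_coverage[2])
  cov_dtp3 <- stats::runif(n, config$true_coverage[1], config$true_coverage[2])

  meta <- tibble::tibble(
    country_code = codes, region = regions,
    membership_start_year = years[1], first_reporting_year = years[1],
    has_reference_estimates = TRUE, bcg_in_schedule = TRUE,
    bcg_target_is_full_birth_cohort = TRUE, bcg_target_age_under_one = TRUE,
    dtp3_target_age_under_one = TRUE, ever_reported_bcg_target = TRUE,
    ever_reported_dtp3_target = TRUE,
    bcg_excluded_years = NA_character_, dtp3_excluded_years = NA_character_)

  idx <- function(i, t) (i - 1L) * ny + t
  ref_lb <- ref_si <- numeric(n * ny)
  for (i in seq_len(n)) {
    lb_path <- lb0[i] * (1 + growth[i])^(seq_len(ny) - 1)
    ref_lb[idx(i, seq_len(ny))] <- lb_path
    ref_si[idx(i, seq_len(ny))] <- lb_path * (1 - imr[i] / 1000)
  }
  t_bcg <- round(ref_lb)
  t_dtp3 <- round(ref_si)
  t_dtp1 <- t_dtp3
  d_bcg <- round(rep(cov_bcg, each = ny) * t_bcg / 100)
  d_dtp3 <- round(rep(cov_dtp3, each = ny) * t_dtp3 / 100)
  d_dtp1 <- d_dtp3

  ## anomaly planting: countries in order, years in order, at most one
  ## anomaly per country-year
  rates <- config$anomaly_rates[ANOMALY_KINDS]
  rates[is.na(rates)] <- 0
  names(rates) <- ANOMALY_KINDS
  cum <- cumsum(rates)
  mag <- config$anomaly_magnitudes
  truth <- vector("list", 0)
  for (i in seq_len(n)) {
    prev_kind <- ""
    for (t in seq_len(ny)) {
      k <- idx(i, t)
      u <- stats::runif(1)
      kind <- if (u < cum[length(cum)]) {
        ANOMALY_KINDS[which(u < cum)[1]]
      } else ""
      # a jump needs a clean, evaluable previous year for its signature
      if (kind == "denom_jump_gt10" &&
            (t == 1 || prev_kind %in% c("denom_jump_gt10",
                                        "ref_divergence_gt10"))) {
        kind <- ""
      }
      value <- NA_real_
      if (kind == "missing_lb") {
        t_bcg[k] <- NA_real_
        value <- NA_real_
      } else if (kind == "missing_si") {
        t_dtp3[k] <- NA_real_
        value <- NA_real_
      } else if (kind %in% c("denom_jump_gt10", "ref_divergence_gt10")) {
        r <- mag[[kind]]
        m_pct <- stats::runif(1, r[1], r[2])
        up <- sample(c(TRUE, FALSE), 1)
        # downward spikes capped at -85% so the scale factor stays positive
        f <- if (up) 1 + m_pct / 100 else 1 - min(m_pct, 85) / 100
        t_bcg[k] <- round(t_bcg[k] * f)
        t_dtp3[k] <- round(t_dtp3[k] * f)
        t_dtp1[k] <- round(t_dtp1[k] * f)
        d_bcg[k] <- round(d_bcg[k] * f)
        d_dtp3[k] <- round(d_dtp3[k] * f)
        d_dtp1[k] <- round(d_dtp1[k] * f)
        value <- 100 * (f - 1)
      } else if (kind == "coverage_gt100") {
        r <- mag[["coverage_gt100"]]
        pct <- stats::runif(1, r[1], r[2])
        if (stats::runif(1) < 0.5) {
          d_bcg[k] <- ceiling(t_bcg[k] * pct / 100)
        } else {
          d_dtp3[k] <- ceiling(t_dtp3[k] * pct / 100)
        }
        value <- pct
      } else if (kind == "negative_imr") {
        r <- mag[["negative_imr"]]
        ratio <- stats::runif(1, r[1], r[2])
        t_dtp3[k] <- round(t_bcg[k] * ratio)
        t_dtp1[k] <- t_dtp3[k]
        value <- ratio
      } else if (kind == "dtp_mismatch") {
        r <- mag[["dtp_mismatch"]]
        pct <- stats::runif(1, r[1], r[2]) * sample(c(-1, 1), 1)
        t_dtp1[k] <- round(t_dtp3[k] * (1 + pct / 100))
        if (identical(t_dtp1[k], t_dtp3[k])) t_dtp1[k] <- t_dtp3[k] + 1
        value <- pct
      }
      if (nzchar(kind)) {
        truth[[length(truth) + 1]] <- tibble::tibble(
          country_code = codes[i], year = years[t],
          anomaly_kind = kind, planted_value = value)
      }
      prev_kind <- kind
    }
  }
  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else {
    tibble::tibble(country_code = character(), year = integer(),
                   anomaly_kind = character(), planted_value = numeric())
  }

  long <- function(vac, doses, target) {
    tibble::tibble(country_code = rep(codes, each = ny),
                   year = rep(years, times = n), vaccine = vac,
                   doses_administered = doses, target_population = target)
  }
  reports <- dplyr::arrange(
    dplyr::bind_rows(long("BCG", d_bcg, t_bcg),
                     long("DTP1", d_dtp1, t_dtp1),
                     long("DTP3", d_dtp3, t_dtp3)),
    country_code, year, vaccine)
  reference <- tibble::tibble(
    country_code = rep(codes, each = ny), year = rep(years, times = n),
    live_births = ref_lb, surviving_infants = ref_si)
  list(reports = reports, reference = reference, meta = meta, truth = truth)
}

## which flags each anomaly kind fires at its own cell (primary) and which
## it may additionally fire, there or in the following year (induced)
anomaly_flag_map <- function() {
  list(
    missing_lb = list(primary = "F1_LB_MISSING", induced_0 = character(),
                      induced_1 = character()),
    missing_si = list(primary = "F2_SI_MISSING", induced_0 = character(),
                      induced_1 = character()),
    denom_jump_gt10 = list(primary = "F3_YOY_DENOM_GT10",
                           induced_0 = c("F7_LB_REF_DIFF_GT10",
                                         "F8_SI_REF_DIFF_GT10"),
                           induced_1 = "F3_YOY_DENOM_GT10"),
    coverage_gt100 = list(primary = "F5_COV_GT100",
                          induced_0 = "F4_YOY_COV_GT10",
                          induced_1 = "F4_YOY_COV_GT10"),
    negative_imr = list(primary = "F6_NEG_IMR",
                        induced_0 = c("F8_SI_REF_DIFF_GT10",
                                      "F3_YOY_DENOM_GT10", "F4_YOY_COV_GT10"),
                        induced_1 = c("F3_YOY_DENOM_GT10", "F4_YOY_COV_GT10")),
    ref_divergence_gt10 = list(primary = c("F7_LB_REF_DIFF_GT10",
                                           "F8_SI_REF_DIFF_GT10"),
                               induced_0 = "F3_YOY_DENOM_GT10",
                               induced_1 = "F3_YOY_DENOM_GT10"),
    dtp_mismatch = list(primary = "F9_DTP3_NE_DTP1", induced_0 = character(),
                        induced_1 = character())
  )
}

#' Score flag recovery of planted anomalies
#'
#' Compares fired flags against the truth ledger. A planted anomaly is
#' recovered when its primary flag(s) fire at its (country, year). Firings
#' explained as induced side effects -- the following year's half of a
#' planted jump's fluctuation pair, or a secondary flag an anomaly
#' mechanically triggers (for example a denominator jump also diverging
#' from the reference that year) -- are scored as induced, neither true
#' nor false positives. Everything else that fires is a false positive.
#'
#' @param flags Flag tibble from [evaluate_flags()] run on the generated
#'   panel.
#' @param truth Truth ledger from [generate_panel()].
#' @return Tibble with one row per anomaly kind: planted and recovered
#'   counts, recall, true/induced/false firing counts of the primary
#'   flag(s), and precision. Recall and precision are `NA` when undefined
#'   (nothing planted / nothing fired).
#' @export
score_recovery <- function(flags, truth) {
  map <- anomaly_flag_map()
  fired <- flags[flags$fired, c("country_code", "year", "flag_id")]
  fired_key <- paste(fired$country_code, fired$year, fired$flag_id)
  ## cells where each flag is explained (planted primary or induced)
  explained_primary <- character(0)
  explained_any <- character(0)
  for (kind in names(map)) {
    tr <- truth[truth$anomaly_kind == kind, ]
    if (nrow(tr) == 0) next
    for (fl in map[[kind]]$primary) {
      explained_primary <- c(explained_primary,
                             paste(tr$country_code, tr$year, fl))
    }
    for (fl in map[[kind]]$induced_0) {
      explained_any <- c(explained_any, paste(tr$country_code, tr$year, fl))
    }
    for (fl in map[[kind]]$induced_1) {
      explained_any <- c(explained_any,
                         paste(tr$country_code, tr$year + 1, fl))
    }
  }
  explained_any <- union(explained_any, explained_primary)

  rows <- lapply(names(map), function(kind) {
    prim <- map[[kind]]$primary
    tr <- truth[truth$anomaly_kind == kind, ]
    n_planted <- nrow(tr)
    recovered <- 0L
    if (n_planted > 0) {
      recovered <- sum(vapply(seq_len(n_planted), function(j) {
        all(paste(tr$country_code[j], tr$year[j], prim) %in% fired_key)
      }, logical(1)))
    }
    ff <- fired[fired$flag_id %in% prim, ]
    fkey <- paste(ff$country_code, ff$year, ff$flag_id)
    n_true <- sum(fkey %in% paste(rep(tr$country_code, each = length(prim)),
                                  rep(tr$year, each = length(prim)),
                                  prim))
    n_induced <- sum(!(fkey %in% paste(
      rep(tr$country_code, each = length(prim)),
      rep(tr$year, each = length(prim)), prim)) & fkey %in% explained_any)
    n_false <- nrow(ff) - n_true - n_induced
    tibble::tibble(
      anomaly_kind = kind, n_planted = n_planted, n_recovered = recovered,
      recall = if (n_planted > 0) recovered / n_planted else NA_real_,
      n_fired = nrow(ff), n_true = n_true, n_induced = n_induced,
      n_false = n_false,
      precision = if (n_true + n_false > 0) n_true / (n_true + n_false)
                  else NA_real_)
  })
  dplyr::bind_rows(rows)
}
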