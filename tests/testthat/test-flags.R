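get_flag <- function(flags, c, y, id) {
  flags[flags$country_code == c & flags$year == y & flags$flag_id == id, ]
}

test_that("a hand-built inconsistent country-year fires exactly the right flags", {
  # (C1, 2000): reported LB 1000, SI 1100 (so implied IMR -100), reference
  # LB 1000 and SI 980 (SI divergence (1100-980)/980 = 12.2% > 10), DTP1
  # target equal to DTP3's, coverage 90% / 90.9%
  meta <- make_meta("C1")
  reports <- make_reports("C1", 2000L, bcg_target = 1000, dtp3_target = 1100,
                          bcg_doses = 900, dtp3_doses = 1000)
  reference <- make_reference("C1", 2000L, lb = 1000, si = 980)
  decisions <- full_decisions(meta, c(2000L, 2000L))
  flags <- evaluate_flags(reports, reference, decisions)

  expect_true(get_flag(flags, "C1", 2000, "F6_NEG_IMR")$fired)
  expect_equal(get_flag(flags, "C1", 2000, "F6_NEG_IMR")$statistic_value, -100)
  expect_true(get_flag(flags, "C1", 2000, "F8_SI_REF_DIFF_GT10")$fired)
  expect_equal(get_flag(flags, "C1", 2000, "F8_SI_REF_DIFF_GT10")$statistic_value,
               100 * (1100 - 980) / 980)
  expect_false(get_flag(flags, "C1", 2000, "F9_DTP3_NE_DTP1")$fired)
  expect_false(get_flag(flags, "C1", 2000, "F7_LB_REF_DIFF_GT10")$fired)
  expect_false(get_flag(flags, "C1", 2000, "F5_COV_GT100")$fired)
  # no prior year: fluctuation flags are non-evaluable, not fired
  expect_false(get_flag(flags, "C1", 2000, "F3_YOY_DENOM_GT10")$evaluable)
  expect_false(get_flag(flags, "C1", 2000, "F4_YOY_COV_GT10")$evaluable)
})

test_that("a clean country-year fires nothing", {
  meta <- make_meta("C1")
  years <- 2000:2004
  reports <- make_reports("C1", years, bcg_target = 1000, dtp3_target = 980,
                          bcg_doses = 950, dtp3_doses = 930)
  reference <- make_reference("C1", years, lb = 1000, si = 980)
  flags <- evaluate_flags(reports, reference,
                          full_decisions(meta, c(2000L, 2004L)))
  expect_equal(sum(flags$fired), 0L)
  expect_true(all(flags$evaluable[flags$year > 2000]))
})

test_that("thresholds are strict: a boundary value does not fire", {
  meta <- make_meta("C1")
  # LB: 100000 -> 110000 is exactly +10.0%; coverage constant; SI flat
  reports <- make_reports("C1", 2000:2001,
                          bcg_target = c(100000, 110000),
                          dtp3_target = c(98000, 98000),
                          bcg_doses = c(90000, 99000),
                          dtp3_doses = c(90000, 90000))
  reference <- make_reference("C1", 2000:2001,
                              lb = c(100000, 110000), si = c(98000, 98000))
  flags <- evaluate_flags(reports, reference,
                          full_decisions(meta, c(2000L, 2001L)))
  f3 <- get_flag(flags, "C1", 2001, "F3_YOY_DENOM_GT10")
  expect_true(f3$evaluable)
  expect_equal(f3$statistic_value, 10)
  expect_false(f3$fired)
  # coverage exactly 100 does not fire the cap either
  reports2 <- make_reports("C1", 2000L, bcg_target = 1000, dtp3_target = 980,
                           bcg_doses = 1000, dtp3_doses = 900)
  flags2 <- evaluate_flags(reports2, make_reference("C1", 2000L, 1000, 980),
                           full_decisions(meta, c(2000L, 2000L)))
  f5 <- get_flag(flags2, "C1", 2000, "F5_COV_GT100")
  expect_equal(f5$statistic_value, 100)
  expect_false(f5$fired)
  # just past the boundary fires
  reports3 <- make_reports("C1", 2000L, bcg_target = 1000, dtp3_target = 980,
                           bcg_doses = 1001, dtp3_doses = 900)
  flags3 <- evaluate_flags(reports3, make_reference("C1", 2000L, 1000, 980),
                           full_decisions(meta, c(2000L, 2000L)))
  expect_true(get_flag(flags3, "C1", 2000, "F5_COV_GT100")$fired)
})

test_that("a missing year breaks fluctuation pairs and never bridges the gap", {
  meta <- make_meta("C1")
  years <- 2000:2004
  bcg_t <- c(1000, 1000, NA, 2000, 2000)  # 2002 missing; 2001->2003 doubles
  reports <- make_reports("C1", years, bcg_target = bcg_t,
                          dtp3_target = NA_real_,
                          bcg_doses = 900, dtp3_doses = NA_real_)
  reference <- make_reference("C1", years, lb = 1000, si = 980)
  flags <- evaluate_flags(reports, reference,
                          full_decisions(meta, c(2000L, 2004L)))
  f3 <- flags[flags$flag_id == "F3_YOY_DENOM_GT10", ]
  expect_equal(f3$evaluable, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # the doubling between 2001 and 2003 must NOT fire across the gap
  expect_equal(sum(f3$fired), 0L)
  # missingness itself fires F1 at 2002 and F2 everywhere
  expect_true(get_flag(flags, "C1", 2002, "F1_LB_MISSING")$fired)
  expect_true(all(flags$fired[flags$flag_id == "F2_SI_MISSING"]))
})

test_that("F9 is non-evaluable when DTP1's target is missing", {
  meta <- make_meta("C1")
  reports <- make_reports("C1", 2000L, bcg_target = 1000, dtp3_target = 980,
                          dtp1_target = NA_real_,
                          bcg_doses = 900, dtp3_doses = 900)
  flags <- evaluate_flags(reports, make_reference("C1", 2000L, 1000, 980),
                          full_decisions(meta, c(2000L, 2000L)))
  f9 <- get_flag(flags, "C1", 2000, "F9_DTP3_NE_DTP1")
  expect_false(f9$evaluable)
  expect_false(f9$fired)
  # and fires on an actual mismatch
  reports2 <- make_reports("C1", 2000L, bcg_target = 1000, dtp3_target = 980,
                           dtp1_target = 990, bcg_doses = 900,
                           dtp3_doses = 900)
  flags2 <- evaluate_flags(reports2, make_reference("C1", 2000L, 1000, 980),
                           full_decisions(meta, c(2000L, 2000L)))
  expect_true(get_flag(flags2, "C1", 2000, "F9_DTP3_NE_DTP1")$fired)
})

test_that("ineligible events contribute nothing to statistics or flags", {
  meta <- make_meta(c("C1", "C2"))
  meta$ever_reported_bcg_target[2] <- FALSE  # C2 excluded from BCG
  years <- 2000:2001
  reports <- dplyr::bind_rows(
    make_reports("C1", years, bcg_target = 1000, dtp3_target = 980,
                 bcg_doses = 900, dtp3_doses = 900),
    make_reports("C2", years, bcg_target = 5000, dtp3_target = 980,
                 bcg_doses = 9000, dtp3_doses = 900))
  reference <- make_reference(c("C1", "C2"), years, lb = 1000, si = 980)
  flags <- evaluate_flags(reports, reference,
                          full_decisions(meta, c(2000L, 2001L)))
  c2 <- flags[flags$country_code == "C2", ]
  # C2's wild BCG report (coverage 180%, LB 5x reference) is ineligible:
  # its BCG-side flags are non-evaluable and silent
  expect_false(any(c2$evaluable[c2$flag_id == "F1_LB_MISSING"]))
  expect_false(any(c2$fired[c2$flag_id == "F5_COV_GT100"]))
  expect_false(any(c2$fired[c2$flag_id == "F7_LB_REF_DIFF_GT10"]))
  expect_false(any(c2$evaluable[c2$flag_id == "F6_NEG_IMR"]))
})

test_that("threshold configuration is validated and respected", {
  expect_error(flag_thresholds(denom_yoy_pct = 0), "positive")
  expect_error(flag_thresholds(ref_diff_pct = -3), "positive")
  meta <- make_meta("C1")
  reports <- make_reports("C1", 2000:2001, bcg_target = c(1000, 1080),
                          dtp3_target = c(980, 980),
                          bcg_doses = 900, dtp3_doses = 900)
  reference <- make_reference("C1", 2000:2001, lb = c(1000, 1080),
                              si = c(980, 980))
  dec <- full_decisions(meta, c(2000L, 2001L))
  f10 <- evaluate_flags(reports, reference, dec)
  f5 <- evaluate_flags(reports, reference, dec,
                       flag_thresholds(denom_yoy_pct = 5))
  expect_false(get_flag(f10, "C1", 2001, "F3_YOY_DENOM_GT10")$fired)  # 8% < 10
  expect_true(get_flag(f5, "C1", 2001, "F3_YOY_DENOM_GT10")$fired)    # 8% > 5
})
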