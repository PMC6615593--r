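---
title: "Assessing immunization denominator quality with nine consistency flags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing immunization denominator quality with nine consistency flags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denomqc)
```

## The problem

Administrative vaccination coverage is doses administered divided by a
target population. For a birth-dose vaccine such as BCG the denominator is
the live-birth cohort (LB); for vaccines given in infancy such as the
third dose of DTP it is surviving infants (SI = LB minus infant deaths).
Countries report both numerator and denominator annually, and the
denominator is the softer number: it comes from censuses, projections or
registries of varying quality, and a misstated denominator distorts
coverage directly. If the true coverage is $c$ and the denominator carries
a relative error $e$, the calculated coverage is $c/(1+e)$, so the
coverage error is

$$\Delta c = \frac{c}{1+e} - c,$$

which is positive when the denominator is underestimated and grows with
$c$: the closer a programme is to full coverage, the more a denominator
error matters. `coverage_error_from_denominator_error()` implements this
closed form, and its monotonicity in $c$ is asserted by the test suite.

`denomqc` operationalises a denominator quality review as a reproducible
pipeline: an eligibility cascade over a country-by-year reporting grid,
four derived statistics, nine binary flags per country-year, and summary
surfaces (per-indicator tallies, flag-count distributions, regional sums,
direction-of-difference counts).

## The reporting grid and the eligibility cascade

Every (country, year) cell of the analysis window is a *reporting event*:
one opportunity to report a vaccine's doses and target population. Not
every event is analysable, and excluding events silently would make every
downstream tally unauditable, so `apply_eligibility()` assigns every event
exactly one reason, evaluated in fixed precedence:

1. `PRE_MEMBERSHIP_OR_PRE_REPORTING` — years before the country's first
   reporting year (late-joining member states);
2. `NO_REFERENCE_ESTIMATES` — the reference source does not project the
   country's population (typically very small states);
3. vaccine-specific criteria: the vaccine is not in the national schedule,
   the target population is not the full birth cohort, the target age
   group is over one year, or the country never reported a target
   population for the vaccine.

The first matching reason wins, making the ledger deterministic and the
counts reconcilable: included events plus the per-reason exclusions always
equal the grid total. Schedule criteria are evaluated per event, not per
country, because schedules change; year-limited failures are carried in
optional metadata columns (`bcg_excluded_years`, `dtp3_excluded_years`) as
semicolon-separated year lists. `jrf_meta_template()` ships a 194-country
configuration of the 2000–2016 window whose tallies match the documented
arithmetic of the global reporting grid (3,298 events; 2,565 BCG events
across 153 countries; 2,939 DTP3 events across 174 countries); the
country identities in it are synthetic placeholders, only the tallies are
meaningful.

## Statistics and the nine flags

Four statistics are computed per eligible country-year, at full floating
precision (rounding to integer percent happens only in rendered tables):

* coverage: $100 \times \text{doses}/\text{target}$;
* year-to-year percent difference: $100 \times (v_{t}/v_{t-1} - 1)$,
  applied to the LB series, the SI series and both coverage series;
* percent difference from the reference projection:
  $100 \times (\text{reported} - \text{reference})/\text{reference}$,
  negative when the country under-reports relative to the projection;
* implied infant mortality rate:
  $1000 \times (\text{LB} - \text{SI})/\text{LB}$, using the same year's
  reported LB and SI.

The nine flags are: missing reported LB (F1) or SI (F2); a year-to-year
change in a reported denominator (F3) or in coverage (F4) whose magnitude
exceeds 10%; coverage above 100% (F5); a negative implied IMR (F6) — more
surviving infants than live births is infeasible; a reported LB (F7) or SI
(F8) differing from the reference projection by more than 10% in absolute
value; and a DTP3 target population unequal to the same year's DTP1 target
(F9), which should be the identical cohort.

Design choices worth stating explicitly:

* **Strict thresholds.** All comparisons are strict (`> 10%`, `> 100%`,
  `< 0`); a boundary value does not fire. Because a strict comparison at
  an exactly-on-threshold input is vulnerable to binary floating-point
  noise (an exact +10% step computed as `110000/100000` lands a few
  ulps above 10), the engine compares against the threshold plus a
  relative guard band of about $10^{-8}$ — far below any real exceedance
  in count data, and large enough to absorb representation error.
* **Magnitude, not direction, for fluctuations.** F3/F4 fire on the
  absolute value of the signed change: a −12% drop is as suspicious as a
  +12% jump. The signed value is retained in `statistic_value`.
* **Non-evaluable is not clean.** A flag whose inputs are missing, or
  whose fluctuation pair lacks an eligible, non-missing predecessor year,
  is `evaluable = FALSE` and can never fire; a gap in a series breaks both
  adjacent pairs and is never bridged. F9 with a missing DTP1 target is
  non-evaluable, because a mismatch cannot be asserted against a missing
  value.
* **One flag per rule per country-year.** F3 covers both denominator
  series and F4 both coverage series (firing if either exceeds the
  threshold), matching the nine-item rule list; the per-series statistic
  with the largest magnitude is recorded. Tallies at a second threshold
  (the 5% variant conventionally shown beside 10%) are obtained by
  re-running `evaluate_flags()` with `denom_yoy_pct = 5` and binding the
  records before `tabulate_indicator_summary()`.
* **Zero targets are invalid, not missing.** A reported target of 0 is
  rejected at ingest: it would poison divisions and is semantically
  different from not reporting.

## Summary surfaces

`tabulate_indicator_summary()` reports, per flag and threshold variant,
evaluable and fired event counts (percentages rounded half away from
zero, the convention of printed summary tables) and nested country
tallies: flagged in any year, in ≥5 years, in ≥10 years, over the base of
countries with at least one evaluable event for that indicator. The bases
therefore differ across indicators — a fluctuation flag needs two
consecutive reported years, so its base is smaller than a missingness
flag's — and the nesting `≥10 ⊆ ≥5 ⊆ any ⊆ total` is asserted by tests on
arbitrary panels.

`sum_flags_per_country_year()` and `flag_count_distribution()` produce the
countries-by-number-of-flags histogram (bins 0–4 and 5+) whose totals
conserve the number of countries with evaluable flags each year.
`direction_analysis()` splits fired reference-divergence events by sign;
higher plus lower equals fired, always. `regional_aggregate()` sums
reported and reference denominators per region-year over the included
country set; a country-year in the analysis set that failed to report
contributes zero to the reported sum while its reference projection stays
in the reference sum, so non-reporting by a large country appears as a dip
of the reported series against a stable reference series — the
interpretation such plots rely on.

## The synthetic generator and what it does (not) emulate

`generate_panel()` builds a clean panel first: per country a region, a
baseline live-birth cohort (log-uniform between 20 thousand and 5
million, so small islands and large countries coexist), a constant annual
growth rate in [−1%, +3%], a constant infant mortality rate in [2, 80]
per 1000 and constant true coverages in [70%, 99%]. Reference LB follows
the smooth growth path, reference SI is LB × (1 − IMR/1000), reported
targets equal the rounded reference values and doses equal coverage ×
target. On a clean panel the pipeline is provably silent: growth never
reaches the 10% fluctuation threshold, coverage never reaches 100%, and
reported equals reference up to rounding.

Anomalies are then planted in *reported* values only (the reference panel
stays internally consistent, mirroring its role as the comparator), at
most one per country-year, drawn in a fixed order (country baselines
first, then country-by-country, year-by-year anomaly draws) from a single
seeded RNG stream, so a seed fixes the output byte-for-byte. The seven
kinds and their mechanics:

* `missing_lb` / `missing_si`: the target population is removed, doses
  kept — exercising the missing-coverage propagation path;
* `denom_jump_gt10` and `ref_divergence_gt10`: a single-year spike
  scaling all targets *and* doses by a factor drawn 15–50% (jumps) or
  15–60% (divergences) away from 1, in either direction. Scaling doses
  too keeps coverage invariant, so a denominator spike does not leak into
  the coverage-cap flag; it does, mechanically, fire the
  reference-divergence flags in its year and the fluctuation flag in the
  following year (the pair that compares back against the spike). A jump
  is never planted in the first year or directly after another spike, so
  its own-year fluctuation signature is always evaluable and above
  threshold;
* `coverage_gt100`: doses raised to 104–130% of the target for one
  vaccine;
* `negative_imr`: reported SI (DTP3 and DTP1 targets alike, keeping F9
  silent) set to 1.02–1.15 × reported LB, guaranteeing strict negativity
  away from the boundary;
* `dtp_mismatch`: the DTP1 target displaced 5–20% from DTP3's.

All magnitude ranges are bounded away from the flag thresholds by a
configurable margin (at least 2 percentage points after worst-case
growth), which is what makes exact recovery a testable guarantee rather
than a tendency. `score_recovery()` scores each planted anomaly against
its primary flag at its own cell, classifies the mechanical side effects
above as *induced* (neither true nor false positives), and reports
per-kind precision and recall — `NA`, not 1, when nothing was planted or
nothing fired. On default-configured panels the suite requires precision
= recall = 1 for the deterministic kinds and recall = 1 with only induced
extras for jumps.

What the generator does **not** emulate: demographic shocks, spatially or
temporally correlated anomalies, census-revision level shifts (its spikes
revert after one year), numerator-quality problems beyond the planted
coverage excesses, or the real-world correlation between country size and
reporting quality. Passing recovery tests therefore demonstrates that the
engine detects each defined inconsistency wherever it occurs, not that
real reporting systems fail in these particular ways.

## Problem sizes and determinism

The shipped template and acceptance computations use the full 194-country
grid (arithmetic, instantaneous). Stochastic validation uses 50-country ×
17-year panels — about 300 planted anomalies per run, large enough to hit
every anomaly kind and interaction while keeping a full pipeline run
under a few seconds — and the engine-versus-oracle equivalence check uses
100 random panels of at most 5 × 5 with aggressive missingness and
eligibility churn, where a brute-force per-rule checker is feasible and
edge paths (gaps, first years, ineligible cells) are dense. All
randomness flows from explicit integer seeds; `cmd_simulate()` writes a
manifest (inputs, checksums, configuration, seed, package version) so any
run can be reproduced exactly.

## Known limitations

* The implied IMR uses same-year LB and SI; a birth cohort straddling
  calendar years can legitimately push SI above LB in rare cases, which
  this check cannot distinguish from error.
* Reference projections are treated as the comparator, not the truth; a
  large divergence flags a discrepancy, not necessarily a reporting
  error.
* Small countries produce larger percent differences from the same
  absolute errors; the flags are unadjusted for population size.
* The eligibility template reproduces published tallies, not country
  identities; analyses of real data should supply real metadata.
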