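---
title: "Cold exposure and early-life calf growth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cold exposure and early-life calf growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfclim)
```

## The problem

Newborn dairy calves are routinely housed in naturally ventilated buildings
where the perceived temperature regularly falls below the calf's lower
critical temperature (LCT) — the point below which the animal must divert
metabolisable energy from growth into heat production. `calfclim`
operationalises one way of quantifying that stress and relating it to
growth: score every housed hour against an age-specific threshold, summarise
each calf's housing phase as the *proportion of hours spent below the LCT*,
and carry that exposure statistic into growth models for the two management
phases of early rearing — the individual hutch from birth to group-pen entry
(B2G, 6–14 days) and the group igloo pen from entry to roughly a month of
age (G2E).

## The effective-temperature index

Air temperature alone understates cold stress in a draughty, humid barn.
Every recorded hour is therefore converted to an effective temperature

$$ET = 37 - \frac{37 - t}{0.68 - 0.0014\,ur + \dfrac{1}{1.76 + 1.4\,v^{0.75}}}
       - 0.29\,t\left(1 - \frac{ur}{100}\right),$$

with $t$ air temperature (°C), $ur$ relative humidity (%) and $v$ wind speed
(m/s). The index has a fixed point at $t = 37$, $ur = 100$ (any wind), is
strictly increasing in $t$ over the housing range, and is non-increasing in
wind below body temperature — wind amplifies cold. These three properties
are asserted in the test suite over numeric grids, and the implementation is
pinned to two hand-computed oracle values. The index lives in a single pure
function (`effective_temperature()`), and every consumer accepts an `et_fun`
argument, so a different comfort index can be substituted without touching
the exposure logic. The index does not account for radiant (solar) heat;
for fully enclosed or outdoor housing a corrected index should be
substituted.

## The LCT and the exposure statistic

Two LCT definitions are provided. The physiological heat-balance form

$$T_{lc} = (T_r + H'_{e,min} I_e) - H_{min}(I_t + I_e)$$

(`physiological_lct()`) is exposed for reference and sensitivity work, but
it is never parameterised from field data here. The working definition is
the simplified age schedule (`age_lct_schedule()`): 15&nbsp;°C at birth,
declining 0.5&nbsp;°C per day of age, unbounded by default (the study
horizon ends near day 30, where the schedule sits at 0&nbsp;°C; a floor is
configurable for longer horizons).

`exposure_proportion()` scores every available climate hour in a calf's
phase window. Conventions, each of which was a genuine design choice:

* **Age advances at 24-hour anniversaries of the birth timestamp**, not at
  calendar midnight — the schedule is calf-relative ("day 0" is the birth
  day regardless of birth hour).
* **"Below" is strict**: an hour with $ET$ exactly at the LCT is not
  exposed.
* **Hours are half-open**: a stamp marks the start of the hour it
  describes, and the window $[\text{start}, \text{end})$ counts stamps, so
  splitting a window at any interior point conserves both numerator and
  denominator (tested as an invariant).
* **Missing hours drop out of both numerator and denominator.** Gaps of at
  most 3 hours in a climate file are forward-filled and flagged at
  ingestion; longer gaps stay absent, which leaves the proportion unbiased
  under missingness that is unrelated to temperature. Hours removed by
  validation (impossible humidity, negative wind) are never resurrected by
  the gap filler.

Proportions are categorised into the phase-specific quartile schemes
(B2G: ≤0.32, 0.33–0.58, 0.59–0.96, ≥0.97; G2E: ≤0.01, 0.02–0.06,
0.07–0.27, ≥0.28). The printed cut-points are two-decimal values that leave
reals such as 0.325 unassigned; proportions are therefore rounded half-up
to two decimals before matching, which closes every gap (asserted over a
0.001 grid). The first interval is the reference level throughout.

## Growth definitions

B2G growth is the interval rate — weight gain between the birth and
leaving-hutch weighings divided by whole days between them. G2E growth is
the ordinary least-squares slope of weight on age across the twice-weekly
group-pen weighings, which tolerates a changing growth rate across the
phase; on exactly two points the slope equals the interval rate (tested as
an algebraic identity, with an independent normal-equations oracle for the
general case). Average milk-replacer intake is total recorded powder mass
divided by the days from pen entry to last weighing; reconstitution at a
w/v concentration of $c\,\%$ means $10c$ grams per litre, the only reading
under which the farm's 6 L/d at 15% equals 900 g/d.

## Eligibility

The B2G dataset requires a recorded birth weight and a hutch exit at 14
whole days of age or less; the G2E dataset further excludes calves that
died, were sold, returned to a hutch, lack a milk record for any calendar
day between pen entry and last weighing (feeder power failures lose whole
blocks), or have fewer than two group-pen weights. Rules are applied in
that order and only the first failing rule is logged per calf, so exclusion
counts are disjoint and reproducible. "Whole days" is `floor((exit −
birth)/24 h)` everywhere, matching integer reported ages.

## Health status

Wisconsin scores (rectal temperature, ocular discharge, nasal discharge,
head/ear posture, cough; 0–3 each, faecal consistency unavailable in group
housing) classify each assessment as Healthy (rectal ≤ 2, overall ≤ 3),
Intermediate (rectal ≤ 2, overall = 4) or Diseased (rectal = 3, or overall
≥ 5). The three rules partition all 64 valid score pairs — asserted
exhaustively — and a calf "ever showed signs" iff any assessment was
non-Healthy.

## The model chain

Both phases use the same two-stage selection: each candidate variable is
first fitted alone against DLWG and carried forward iff its whole-term
p-value is below 0.20; the survivors form a maximal model which is
backward-eliminated at 0.05. Choices that the published record left open:

* **Whole-term tests.** Multi-level factors are tested by marginal F-tests
  (`drop1`) in the fixed-effects phase and by likelihood-ratio tests of
  nested maximum-likelihood fits in the mixed phase, matching chi-square
  reporting for mixed models; per-level Wald p-values against the reference
  level are reported alongside, mirroring the published table layout.
* **Random effects are structural.** The G2E models carry independent
  (crossed) random intercepts for rearing group, igloo pen and milk-feeder
  system; nesting was not stated in the source design, and crossed
  intercepts are the weaker assumption. They are never candidates for
  elimination; a grouping factor observed at fewer than two levels is
  dropped with a warning. Singular fits (variance estimates on the zero
  boundary) are legitimate and flagged, not errors — at the boundary the
  fixed effects coincide with ordinary least squares, which is tested.
* **Deterministic tie-breaks.** When several terms tie for the largest
  non-significant p-value (notably perfectly collinear duplicates, which
  are assigned p = 1), the term latest in the candidate list is dropped
  first.
* **Estimates are REML**, selection tests are ML; fixed-effect estimates
  are stable to 10⁻⁴ kg/d across optimiser starts (tested with bobyqa vs
  Nelder–Mead).
* **Tukey contrasts** (studentised-range adjustment via `emmeans`) are
  computed only for factors retained in the final model, only within each
  factor's family; no correction is applied across the screening stage,
  matching the source procedure.

## The synthetic cohort generator

No field data accompany the method, so the package carries a generator
whose defaults *are* the study conditions; they are fixed, documented
calibration points, not tuning knobs.

* **Climate**: annual sinusoid (amplitude 6&nbsp;°C, peak at day-of-year
  200) + diurnal sinusoid (amplitude 3&nbsp;°C, peak 15:00) + N(0, 2²)
  noise around a 10.3&nbsp;°C mean, giving a marginal SD of
  ≈ $\sqrt{6^2/2 + 3^2/2 + 2^2} = 5.15$ against the observed 5.2; RH
  N(81.1, 11.3²) clipped to [27, 99]; wind zero-inflated exponential
  (75% calm, mean 0.8 m/s positive part, clipped at 3 m/s). The generator
  reproduces first and second moments and both cycles; it does **not**
  emulate weather fronts, autocorrelated cold spells, or sensor failure
  beyond simple gaps, so passing tests say nothing about those features of
  real records.
* **Cohort**: births uniform over twelve months; birth weights
  N(43.2, 6.2²) truncated to [31, 67] kg; hutch-exit ages 6–14 d with the
  observed frequency profile; covariate mixes from the observed counts.
* **Growth**: B2G DLWG is drawn from the published final-model linear
  predictor (intercept 0.537; category effects 0, −0.061, −0.157, −0.199;
  −0.018 per kg birth weight; +0.028 per day exit age) with residual SD
  0.30 kg/d — the published marginal SD is 0.34, and 0.30 is the residual
  choice consistent with it once the systematic terms are removed. The G2E
  slope uses the published coefficients (entry age 0.009, CMR 0.001,
  near-null category effects) plus random intercepts of SD 0.05 kg/d for
  group, pen and feeder (not reported; an invented, documented knob), a
  calf-level residual SD of 0.15 kg/d, and a generating intercept of
  −0.36 kg/d chosen so the implied mean G2E DLWG at the cohort means
  reproduces the observed 0.60 kg/d. Weighings carry N(0, 0.5²) kg
  measurement error (repeatability was not reported; 0.5 kg is a
  realistic crate error).
* **The exposure covariate is never drawn.** Each calf's category is
  computed from the generated climate through the same
  ET → LCT → proportion → quartile chain the pipeline uses, so parameter
  recovery is an end-to-end test of the whole method, not of a regression
  in isolation.
* **Determinism**: every draw site seeds its own substream keyed by
  purpose, so adding a field never silently reorders existing draws, and a
  fixed seed yields byte-identical study files.
* Birth weight is treated as measured before colostrum feeding (the
  alternative merely shifts the intercept); the per-calf CMR cap follows
  the observed maximum (1223.7 g/d) rather than the nominal feeder
  allowance, since the two are not reconcilable from the published
  summaries.

## Verification scale and what it shows

The acceptance computation regenerates 200 replicate cohorts per phase
(n = 271 hutch calves over a 410-day climate series; n = 221 group calves)
and refits the final models; replicate-mean estimates match the generating
coefficients within Monte-Carlo error (≈ 2·SE/√200, e.g. ±0.02 kg/d for
the B2G intercept). Operating-characteristic tests run a few hundred
replicates at the study's n: the univariable screen retains pure noise at
20% ± 3 pp, backward elimination reaches the intercept-only model at the
nominal rate under the null, and the mixed-model likelihood-ratio test
holds its 5% size. These sizes keep the whole suite within a desk-scale
run while bounding the Monte-Carlo error on every asserted rate below the
assertion's tolerance.

Recovery succeeding on synthetic cohorts demonstrates that the pipeline is
a faithful, invertible implementation of the stated model chain. It does
not validate the substantive findings on real farms: the generator assumes
the published coefficients, independence between climate and husbandry,
and non-informative missingness, none of which can be checked without the
field records.

## Known limitations

* The effective-temperature closed form is transcribed from the cited
  index literature; the original source should be consulted before using
  the index outside the calf-housing range.
* The physiological LCT is provided but unparameterised; the age schedule
  is linear and species-calibrated for dairy-bred calves only.
* Crossed random intercepts are an assumption; with group sizes of ~12 and
  8 pens the group and pen variances are weakly identified, and singular
  fits are common at the generating SD of 0.05 kg/d.
* The G2E generating intercept and residual SD are package choices
  consistent with, but not determined by, the published summaries.
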