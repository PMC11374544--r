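---
title: "Methods: plate-waste accounting, its assumptions and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-waste accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

The package models a plate-waste campaign collected with the aggregate
selective weighing method: leftovers of all children are pooled into seven
food-category bins and weighed per collection day, while serving sizes are
measured as the mean of three weighed servings per dish. The atomic record
is one (date, school, category) aggregate weighing with a children-served
count. The analysis day-unit is a (date, school) pair; a case observed in
two schools over two one-week waves therefore contributes about twenty
day-units, which is the *n* that all daily descriptives and between-case
tests use.

Served mass is average serving times children; waste percentage, waste per
child and intake per child follow by division and subtraction. Two
physically impossible outcomes can arise from aggregate weighing (children
taking seconds, bin contamination): waste above the served mass, and
negative intake. Both are **flagged, never silently clipped** — intake is
floored at zero with a flag so that downstream nutrient subtraction stays
non-negative while the anomaly remains auditable.

## The waste-composition proxy

The central reconstruction, used identically by the nutrition, carbon and
economic stages, is that aggregate category waste is compositionally
identical to the served mix of its category that day. Waste nutrients are
the served category profile scaled by the wasted mass fraction; waste is
decomposed over food items proportionally to the served item mix before
emission factors and market prices are applied. This is the only
reconstruction consistent with weighing waste in aggregate while reporting
per-nutrient, per-item results, but it is an assumption: selective
rejection *within* a category (eating the pasta, leaving the sauce) is not
observable by this method and is not modelled.

Other deliberate simplifications: no cooking-retention or
nutrient-degradation modelling (composition values describe the food as
listed in the composition table); organic foods are assigned conventional
composition values; emission factors are exogenous inputs, not derived
(no life-cycle inventory modelling); prices are annual averages with no
seasonality.

## Parameters that matter

* **Guideline bounds** (`guidelines.csv`) are closed intervals — a value
  exactly at a bound is compliant, the conventional reading of "reaching a
  minimum threshold". Energy-share checks for protein/fat/carbohydrate use
  Atwater factors 4/9/4 kcal/g. The shipped bounds (e.g. 600 kcal minimum)
  are *illustrative placeholders*, not a transcription of any national
  standard: the compliance logic, not a constants table, is the artifact.
  Compliance is judged per menu-day, on both the as-served and the
  as-consumed (waste-adjusted) profile.
* **Emission factors** resolve item-level first, then category-level, then
  error; disposal is a per-kg factor of the configured method (composting
  by default), and transport is the central-kitchen-to-school distance
  applied to the wasted fraction of food. The headline "waste share of the
  supply footprint" uses production emissions in the numerator; an
  all-components variant is reported separately.
* **Starchy per-serving convention**: per-serving factors for the starchy
  category divide by the mean of the starchy and bread serving counts,
  matching the reporting convention for paired bread/first-course servings.
* **Per-meal denominators**: the meal count is a config field, defaulting
  to the total children-lunches observed during collection days — the only
  defensible denominator when the true meal count is not recorded.

## The statistical protocol

Each compared variable is a per-day-unit series. The gate is a
Kolmogorov–Smirnov test of each group against a normal with estimated mean
and SD. Because parameters are estimated, the plain KS null is
anticonservative, so the Lilliefors correction is applied via the
Dallal–Wilkinson (1986) approximation with Stephens' (1974) modified
statistic in the high-p region. The t-test (pooled variance; Welch by
flag) is used only when **both** groups pass at α = 0.05 — the
conjunctive rule is the conservative convention where the protocol wording
leaves it open. Otherwise Mann–Whitney U is used: exact by complete
enumeration of rank assignments when n₁+n₂ ≤ 16 without ties (two-sided
p = P(|U − n₁n₂/2| ≥ |u − n₁n₂/2|)), else the tie-corrected normal
approximation without continuity correction, matching common
statistical-software defaults. Descriptives follow the chosen branch:
mean ± SD, or median with type-7 (Q1, Q3) quantiles. The "other" and
"dessert" categories are accounted but excluded from testing — they are
served too rarely to support day-level inference — and yield explicit skip
results. No multiple-testing correction is applied, matching the protocol
the package implements.

Calibration of the full gated procedure (screen + branch) is itself a
tested property: its type-I error on both normal and exponential null data
must lie in [0.03, 0.07] at nominal 0.05 over 10 000 replicates.

## What the synthetic generator emulates — and what it does not

The generator realises a stated world: two cases with 20 and 19 collection
day-units over two schools, children uniform in 140–220 per day-unit, five
core categories served daily, dessert and "other" on periodic schedules
(making them sparse, as in real menus), three Normal serving measurements
per dish (SD well below the mean), and daily category waste fractions
drawn from Beta distributions. Beta was chosen over Gaussian because
fractions live in [0, 1] and daily waste distributions are skewed —
which is also why the non-parametric branch dominates in practice. The
concentration parameter 50 gives a day-to-day SD of roughly 5–7 percentage
points, a realistic week-to-week variability for canteen waste. The preset
plants category fraction means whose serving-weighted totals are ≈ 24 %
(case A) and ≈ 42 % (case B), with fruit and vegetable fractions above
one half in case B.

The composition, factor, price and guideline tables are internally
consistent toy values chosen to reproduce the *qualitative* structure of
real campaigns — protein dishes have the highest emission factor and price
per kg, fruit and vegetables the lowest; transport and disposal are small
(≈ 2–4.5 % and ≈ 3 %) shares of the waste footprint — and are documented
as synthetic. A green test therefore establishes the correctness of the
accounting, reconstruction and inference machinery on a known world; it
does **not** reproduce any published table's cell values, which depend on
unpublished raw data and confidential prices. The generator also omits
features of real data: within-school correlation of children counts, menu
seasonality, waste-fraction correlation across categories on a day, and
behavioural responses.

## Numerical choices and degenerate inputs

* Masses are grams internally; kg, EUR and CO2e appear only at
  presentation (tables round to 1–2 decimals; all accounting is
  full-precision).
* CSV round trips are bit-identical: doubles are serialised with 17
  significant digits.
* Zero served mass with nonzero waste is an error; zero waste everywhere
  flows through all stages (cost per kg and EF per kg become NA, shares 0).
* Constant samples make normality undefined (classed error); the gate
  treats a degenerate group as non-normal and falls back to Mann–Whitney,
  whose all-tied case returns p = 1.
* Beta concentration ∞ and serving SD 0 give the deterministic limit used
  by exact ground-truth tests; serving SD ≥ mean/2 is rejected as
  infeasible.
* Item-level factor and price rows override category rows, reflecting data
  sources that mix granularities.

## Known limitations

Within-category selective rejection is unobservable by design of the
collection method. The compliance stage ships placeholder bounds.
Emission factors and prices are single-point values with no uncertainty
propagation. Only Global Warming Potential is computed — no biodiversity,
toxicity or water indicators. The per-meal economics depend on a config
meal count whenever the campaign does not record one.
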