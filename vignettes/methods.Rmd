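---
title: "Methods: constraint-based weekly meal planning and its synthetic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based weekly meal planning and its synthetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriplanr)
```

## The model

`nutriplanr` implements a knowledge-based dietary recommender: no learned
components, only expert-validated rules applied to a curated database of
Mediterranean dishes and meals. A *dish* is a standard adult portion with
energy (kcal), protein, fat and carbohydrate content and a set of food
groups from a fixed 16-label vocabulary. A *meal* bundles 1–10 dishes into
one of five daily slots (breakfast, morning snack, lunch, afternoon snack,
dinner), tagged with a cuisine country and per-season validity flags. A
*daily plan* takes one meal per slot; a *weekly plan* is seven daily plans.

### Energy requirements

The only user quantity the planner ultimately needs is the daily energy
requirement (DER). It is derived as

* BMI = weight / height² (kg/m²),
* BMR from the sex-specific Harris-Benedict equations — the profile stores
  height in metres, and the conversion to the centimetres those
  coefficients expect happens inside `compute_bmr()` only,
* DER = BMR × PAL with a flat ±500 kcal adjustment by BMI band:
  +500 below 18.5 (support weight gain), −500 above 24.99 (promote weight
  loss), no adjustment in the inclusive healthy band [18.5, 24.99].

The band thresholds are hard cutoffs, exactly as the operational
definition states; no tapering near the edges is applied. Age is
calendar-year subtraction (only the year of birth is collected), with the
reference year injectable for reproducibility.

### Scoring

Each candidate daily plan is scored by `DNPS = CS + PS + FS + FVS`, lower
being better:

| score | quantity | in-band value | out-of-band penalty | band |
|-------|----------|--------------|---------------------|------|
| CS | \|DER − TK\| (kcal) | — | — | — |
| PS | protein energy / DER | 0 | 50 | [0.15, 0.20] |
| FS | fat energy / DER | 0 | 50 | [0.25, 0.40] |
| FVS | fruit/vegetable dish count | 0 | 100 | [5, 10] |

All band bounds are inclusive. Protein and fat grams are converted to
energy with the standard Atwater factors (4 and 9 kcal/g, configurable);
carbohydrates are deliberately omitted — with protein and fat expressed as
fractions of DER, carbohydrate energy is approximately the remainder. The
caloric term is the raw kcal deviation, not normalised by DER; for large
deviations it therefore dominates the fixed band penalties, which is the
intended behaviour (an energy-inappropriate plan should not be rescued by
good macronutrient ratios). A plan scores exactly 0 iff it hits the
caloric target exactly and satisfies every band.

`TFV` counts *dishes* (not meals) whose groups intersect {fruit, raw
vegetables, cooked vegetables}; a dish carrying several such groups counts
once.

### Candidate generation and sorting

The candidate pool is the Cartesian product of the five filtered per-slot
meal buckets. When the pool size exceeds `sample_cap` (default 100,000),
that many distinct plans are drawn uniformly without replacement under a
seed; otherwise the full product is enumerated — sampling never replaces
an exhaustive pool that already fits. Sorting is ascending by DNPS with
ties broken lexicographically on the 5-tuple of meal ids, which makes the
order deterministic and independent of enumeration order.

### Weekly assembly

`assemble_week()` performs a single greedy first-fit pass over the sorted
candidates, keeping a day iff it passes the within-day rules and would not
push any weekly cap over its limit, and stopping at seven kept days. The
design is deliberately not a search: if the greedy pass exhausts the list
with fewer than seven days, the user receives a failure report (days
selected, tally of first-violated rules) rather than a backtracked plan.
This mirrors the evaluation convention that a stratum with an empty meal
bucket scores exactly 0% acceptable plans.

Rule interpretations that the rule text leaves open, fixed here:

* "meal sequence" is the ordered 5-tuple of meal ids constituting a day,
  so the sequence cap limits whole-day repetition to at most twice weekly;
* weekly group caps count dish occurrences (a day with two rice dishes
  contributes 2) — the dish is the unit that carries groups;
* the lunch–dinner clash rule is per day and applies only to those two
  slots; breakfast and snacks are unconstrained by it;
* the daily egg cap and the dish-repetition caps are enforced
  independently even when they overlap;
* the weekly fish cap uses fish-group membership only (fish-containing
  soups count only if the dish also carries the fish group);
* day order in the returned week is selection order (ascending score); no
  weekday semantics are attached.

Because every weekly rule is an "at most" cap, feasibility is monotone
under removal, and a completed greedy week is provably the
lexicographically first feasible 7-subset of the sorted list: any
lexicographically smaller feasible subset would contain a prefix the
greedy pass already accepted. The test suite exploits this with an
exhaustive subset-enumeration oracle on pools of up to 15 candidates, and
`verify_week()` — an independent from-scratch re-check of all rules —
must return an empty report for every assembled week.

## Filtering semantics

A meal is eligible for a context iff its country matches, its flag for the
single requested season is set, no member dish carries a food group
corresponding to one of the user's allergies (dairy→milk, eggs, fish,
nuts), and, under halal, no member dish carries pork. Allergens are not
stored separately: they are derived from dish food groups, and a meal is
excluded if *any* member dish triggers — the strictest safe reading.
Multiple simultaneous allergies are supported by the engine even though
the evaluation cohort assigns at most one attribute per profile. Country
and season are hard filters, never scores.

## What the synthetic data emulates

### Fixture databases

`generate_fixture_db()` builds a database whose `filter_meals()` output
reproduces a target availability matrix — per-slot eligible-meal counts
for every season × attribute (none, each allergy, halal) combination —
*exactly*, cell for cell. The defaults
(`reference_availability()`, `reference_np_stats()`) mirror the documented
characterization of the project's curated 90-meal Spanish and Turkish
databases (Spanish 20/10/30/10/20 meals per slot, Turkish 20/10/28/12/20).

Construction is in two stages per meal slot:

1. **Season flags.** Starting from all-season meals, flags are stripped
   until each season's unrestricted count matches; the first attempt
   strips from the meals holding the most flags (balanced patterns),
   later attempts strip at random, because some allergen demands require
   uneven pattern mixtures.
2. **Allergen groups.** For each of dairy/eggs/fish/nuts/pork the number
   of group-carrying meals per season is fixed by the matrix
   (unrestricted minus attribute count). Meals are grouped by their
   season-flag pattern and an exact assignment is found by depth-first
   search with interval pruning over pattern classes. If any allergen is
   unsatisfiable the whole stage retries with fresh season flags (up to
   400 seeded attempts) before failing constructively.

An analytic pre-check rejects provably inconsistent targets before any
search: if an attribute's demand in one season exceeds the combined
demand of the other three seasons, the difference must be met by
single-season meals, whose number the unrestricted counts bound. One cell
of the published Spanish matrix (winter nut-free lunches, printed as 8)
fails exactly this test against its own neighbouring cells — under the
schema, a meal's composition cannot change with the season, and the
printed value would require more winter-only nut lunches than the spring
counts allow. The package's reference matrix therefore carries 18 for
that single cell, the value consistent with the adjacent seasons
(22/21/19); every other cell is as published, and the generator raises a
constructive error naming the offending cell for specs like the
uncorrected one.

Nutrients are drawn per meal from normals with slot-weighted means
(breakfast 20%, morning snack 10%, lunch 35%, afternoon snack 10%, dinner
25% of the target day energy — a conventional Mediterranean distribution
of the day's intake) and slot-share-scaled standard deviations, then
corrected by a minimum-norm linear adjustment (Moore-Penrose
pseudo-inverse) so that the mean energy of each season's eligible pool
equals the slot share of that season's target day mean. Because the mean
of a Cartesian-product pool is the sum of per-slot bucket means, the
full-day caloric mean of every season's pool matches its target
essentially exactly — comfortably within the 5% tolerance the test suite
asserts. Fat and protein energy fractions are drawn around their target
day-level means with spreads scaled so day-level variation matches;
carbohydrates absorb the remaining energy, keeping every dish consistent
with the macro-energy validity check (4·protein + 9·fat ≤ 1.05·kcal).
Food groups beyond the allergen-driven ones are assigned structurally:
lunches and dinners get two fruit/vegetable dishes, a protein main
(white/red meat or pulses when no fish or pork is present) and a carb
staple (cereals-dominant, occasionally rice/pasta/tubers); breakfasts and
snacks carry cereals and a fruit/vegetable dish with probability 0.8.
These choices make typical days land inside the 5–10 fruit-and-vegetable
band while still exercising every weekly rule.

What the fixtures do *not* emulate: actual recipes and their true
nutrient correlations (e.g. fat and energy co-vary in real dishes),
dish sharing across meals of different slots, within-country regional
variation, and the long tails of real nutrient distributions. Passing
tests on fixtures therefore demonstrate the *pipeline's* correctness and
the qualitative stratum structure (empty buckets → 0% acceptable, rich
buckets → high acceptability), not the exact published percentages, which
depend on the unpublished recipe content.

### Cohorts

`generate_cohort()` creates 1,000 profiles per country × sex stratum
(4,000 total) with a *deterministic* allergy/preference allocation — per
1,000 users: 60 milk, 25 eggs, 20 fish, 25 nuts, plus 30 halal in Spain
or 500 in Türkiye, remainder unrestricted, at most one attribute per
profile — matching the documented exact integer counts rather than
Bernoulli sampling. DER is drawn directly (profiles' anthropometrics are
not needed once DER is fixed) from sex-specific normals: mean 2,500 kcal,
sd 1000/3 for men; mean 2,000 kcal, sd 4000/15 for women. The printed
form of the generating rule (a density multiplied by 1,000) is
dimensionally inconsistent with the documented histograms; the only
reading consistent with their axes and the stated μ, σ (in thousands of
kcal) is direct normal sampling at that scale, which is what the package
implements. Draws are truncated to [1000, 4000] kcal by redraw — a
pragmatic guard matching the displayed histogram support.

## Evaluation harness

`run_experiment()` attempts one weekly plan per profile per requested
season, derives an independent sub-seed per profile-season from the
master seed (so any stratum reproduces in isolation), and never raises on
failure — incomplete weeks are counted. A weekly plan is *acceptable* iff
assembly returned exactly seven days. Per-stratum metrics are computed on
the accepted daily plans only:

* **mean caloric agreement** — the metric has no published closed form,
  so the package defines and documents it as
  `mean(100 · max(0, 1 − |TK − DER| / DER))`: 100 at exact caloric match,
  decreasing linearly in relative error, floored at 0;
* **within-range rates** — the percentage of accepted daily plans with
  TFP ∈ [0.25, 0.40], TPP ∈ [0.15, 0.20] and TFV ∈ [5, 10], computed per
  daily plan (not per weekly average);
* report arithmetic invariants: accepted ≤ attempted and daily = 7 ×
  accepted weekly, asserted by tests on every run.

`filtering_accuracy_audit()` re-checks every meal of every accepted plan
against the four hard criteria (country, season, allergy, preference)
with the resolved database, independent of the filter implementation. For
an uncorrupted pipeline it reports 100% on every applied criterion — the
filter-soundness property restated as a measurement — and the tests also
verify that deliberately injected violations are itemised.

## Numerical and degenerate-input choices

* Macro-energy validity allows 5% slack (4·protein + 9·fat ≤ 1.05·kcal)
  to absorb rounding in food-composition sources.
* Empty filter buckets are legal everywhere: enumeration returns an empty
  plan set with a `no_candidates` attribute, assembly returns a 0-day
  failure report, and strata aggregate to 0% with `NA` nutrient metrics.
* An empty meals list is a valid database (with a warning); an empty
  accepted-plan set yields `NA` metrics and a vacuous audit.
* Sampling without replacement decodes linear indices in mixed radix when
  the pool size fits in integer range and falls back to seeded
  rejection-sampling of distinct tuples beyond it.
* Sorting uses radix order on (score, meal-id tuple), so results are
  locale-independent and reproducible across platforms.
* Config files (YAML/JSON) are validated field-by-field against the
  constructors' signatures; unknown fields and out-of-range values are
  rejected by name.

## Problem sizes used by the test suite

The suite keeps runtimes modest by scaling the *cohort*, never the rules:
full 90-meal fixture databases and the complete 4,000-profile cohort
construction are tested as such (both are fast), the exhaustive
enumeration check runs on the smallest full season pool (185,220 plans),
and the cohort *evaluation* runs use 3 profiles per stratum over all four
seasons with a 2,000-plan sampling cap. Randomized assembler/verifier
agreement uses 1,000+ runs on small synthetic databases (5–6 meals per
slot); the exhaustive assembly oracle enumerates all 7-subsets of crafted
pools of 10–15 candidates.

## Known limitations

* Greedy assembly is first-fit, not optimal: a feasible week can exist
  that the greedy pass misses, in which case the user gets a failure
  report. No backtracking or ILP search is attempted by design.
* The caloric score's dominance over band penalties is unbounded; with
  very sparse pools the top-ranked candidates may all share near-identical
  meals, which the diversity caps then prune heavily.
* Fixture nutrient draws are independent across meals; real menus
  correlate slot contents (e.g. lighter dinners after heavy lunches).
* The cohort draws DER directly; anthropometric covariates (height,
  weight, age) of simulated users are not individually meaningful.
* Family-level planning, micronutrients, portion scaling and multilingual
  metadata are out of scope.
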