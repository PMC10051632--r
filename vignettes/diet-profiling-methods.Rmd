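---
title: "Diet quality profiling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet quality profiling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietprofiler)
```

## The scoring model

`dietprofiler` ranks a whole diet — not individual foods — on a
three-level quality scale with an associated traffic-light color. The
scorer consumes five quantities derived from one day (or a person-average)
of intake:

* **CH/Fb**, the ratio of available carbohydrate (g) to total dietary
  fiber (g). A proxy for how much of the carbohydrate supply comes with a
  fiber-rich food matrix versus free/added sugars; a 10:1 ratio is the
  healthy anchor.
* **SFA %E**, percent of total energy from saturated fatty acids;
  anchored at the 10 %E guideline.
* **Sodium** (mg/day), anchored at the 2000 mg/day adult guideline.
* **P/Bw**, protein grams per kg body weight per day, anchored at the
  EFSA population reference intake of 0.83 g/kg/day.
* **Fiber** (g/day), anchored at the 25 g/day adequate intake.

Each item is mapped to 0–5 points. The three "unhealthy" items (CH/Fb,
SFA, sodium) score more points as intake worsens and sum to **Points A**
(0–15); the two "healthy" items (protein, fiber) score more points as
intake improves and sum to **Points B** (0–10). The final score is

$$FS = \begin{cases} A - B & A < 7 \\ A - \text{fiber points} & A \ge 7 \end{cases}$$

The exclusion branch withdraws protein from the positive side once the
unhealthy load is high, because a high-protein diet built on unhealthy
sources should not be rewarded. $FS \le 3$ maps to category 1 (green),
$4 \le FS \le 7$ to category 2 (yellow) and $FS \ge 8$ to category 3
(orange).

Two secondary analyses refine the verdict for categories 1–2 only (a
category-3 diet needs wholesale change before fine-tuning is meaningful):

* the **balanced macronutrient distribution** check classifies the ratio
  of fat %E to carbohydrate %E as balanced ("B") inside the closed
  interval [0.33, 0.77] — the envelope of the EFSA adequacy ranges of
  20–35 %E fat and 45–60 %E carbohydrate — and unbalanced ("U") outside;
* the **food-group comparison** expresses each of 12 food groups as a
  percent of total energy and flags deviations from a reference pattern.

## Cut-off tables and their interpolation

Only the end anchors of each item's scale are fixed by published
guidance (e.g. sodium ≤ 2000 mg → 0 points, > 3200 mg → 5 points). The
intermediate bins are evenly spaced between the anchors — the
minimal-assumption interpolation — and live in one editable table
(`default_cutoffs()`, YAML-overridable via `read_cutoffs()`), so a user
with different reference values can replace any bin without touching
code:

| item | 0 points | 1 | 2 | 3 | 4 | 5 points |
|---|---|---|---|---|---|---|
| CH/Fb | ≤ 10 | (10,12] | (12,14] | (14,16] | (16,18] | > 18 |
| SFA %E | ≤ 10 | (10,12] | (12,14] | (14,16] | (16,18] | > 18 |
| sodium mg | ≤ 2000 | (2000,2300] | (2300,2600] | (2600,2900] | (2900,3200] | > 3200 |
| fiber g | ≤ 5 | (5,10] | (10,15] | (15,20] | (20,25] | > 25 |

Protein is non-monotone: 0 points below the 0.6 g/kg/day average
requirement, 2 points in the deficit band [0.6, 0.83), the full 5 points
on [0.83, 1.0], then declining one point per 0.2 g/kg/day band down to 0
beyond 1.8. Keeping 5 points up to 1.0 (rather than only at exactly
0.83) reflects that the reference intake is a minimum covering 97.5% of
the population, not a ceiling; the table is configurable for users who
prefer a narrower optimum.

Boundary conventions: "≤" anchors are inclusive on the good side, ">"
anchors exclusive, and intermediate bins are left-open/right-closed.
Inputs are compared at full precision — 10.0001 scores 1 point, not 0.
The exclusion threshold applies at exactly A = 7.

## Derived quantities and degenerate inputs

Energy is reconstructed with the Atwater factors (9 kcal/g fat, 4 kcal/g
protein and available carbohydrate, 2 kcal/g fiber, 7 kcal/g alcohol)
unless the record supplies its own total, in which case the supplied
value is used for all percent-energy denominators and a warning is
raised when it disagrees with the reconstruction by more than 5%
(dietary software usually reports an energy total computed from a richer
food decomposition than the record carries).

Conventions worth stating explicitly:

* `carbohydrate_g` means **available carbohydrate excluding fiber**,
  consistent with the separate 4 vs 2 kcal/g factors. Records reporting
  total carbohydrate can set `carbohydrate_includes_fiber = TRUE` and
  fiber is subtracted before use.
* A **zero-fiber** diet has an undefined CH/Fb ratio; it is assigned
  `Inf`, which scores the worst bin. A diet with no fiber at all is
  strictly worse than any finite ratio.
* The **19 g lactation protein allowance** is subtracted (floored at
  zero) from reported protein before the P/Bw item is scored, so a
  lactating woman is scored as a normal adult. The adjustment affects
  only the scored ratio, never percent-energy accounting or energy.
* Alcohol energy participates in the percent-energy denominator whenever
  `alcohol_g > 0`.
* The balance bounds are derived by truncation, not rounding
  (35/45 = 0.777… → 0.77), so `bounds_from_energy_ranges()` reproduces
  the published interval exactly, and classification compares against
  the stored 2-decimal bounds.

## Advice plans

`build_plan()` turns a score breakdown into stable machine-readable
codes rather than prose, so a downstream app can render them. Category 3
emits `IMPROVE_HABITS` plus one code per "weak aspect"; the
operationalisation of weak is ≥ 3 points on an unhealthy item or ≤ 2 on
a healthy one (configurable). Categories 1–2 require the balance result
(`WATCH_MACRO_DISTRIBUTION` on "U") and accept optional food-group
deviations (`EXCESS_*`/`DEFICIT_*` per group). The balance check is
mandatory at categories 1–2 because it is always computable from the
nutrient record; the food-group comparison is optional because itemised,
group-tagged intake data are not always collected.

## The food-group reference

The reference pattern is built by `build_reference()` as the per-group
mean of exemplary daily menus. The package ships three **synthetic
example Mediterranean-style menus** (`example_menus()`) assembled from
typical food-composition values; each scores green, and their average is
the example reference (`example_reference_path()`). They are
illustrative, not a published reference pattern. The per-group tolerance
band defaults to ±3 percent-energy points — narrow enough to flag the
shifts of a few points that distinguish dietary patterns, wide enough to
absorb day-to-day variation — and is configurable.

## The synthetic cohort generator

No real cohort data ship with the package, so `generate_cohort()`
produces a statistical stand-in for a lactating-women cohort in which
every downstream stage can be exercised. Each subject is drawn from one
of three diet **archetypes** (green / yellow / orange) with probabilities
0.39/0.31/0.31 by default (rounded percentages; normalised internally).
Rather than drawing grams directly, each archetype specifies
distributions for the five scored quantities plus a fat %E share, and the
gram intakes follow from the Atwater identity
(`nutrient_day_from_targets()`); energy therefore *emerges* from the
targets. At the default parameters the archetype means imply roughly
1800, 2250 and 2450 kcal/day for green, yellow and orange subjects — a
pooled mean near 2150 kcal/day — with pooled BMI near 24 kg/m² and fat
shares well above the adequacy range, the profile of a realistic
European cohort of lactating women with imperfect diets.

Three monthly 24 h recalls per subject are simulated as independent
multiplicative log-normal perturbations of the habitual intake (fat and
SFA share a factor, since fat composition is stable within a subject) and
averaged into the scoring input, mirroring the average-of-recalls design
of monthly follow-up studies. The default within-subject coefficient of
variation (0.06) is deliberately small so that the archetypes remain
identifiable after averaging — the generator's calibration target is
that a pure-archetype draw lands in its intended category with
probability ≥ 0.9. Real 24 h recalls vary substantially more from day to
day; the generator is a construct-validity harness, not an emulation of
recall noise, and passing tests say nothing about classification
stability under realistic intra-person variance.

Breast-milk leptin follows
$\log L_{im} = \alpha + \beta_a (\mathrm{BMI}_i - 24) + u_i + \varepsilon_{im}$
with subject effect $u_i \sim N(0, 0.15^2)$ and month noise
$\varepsilon_{im} \sim N(0, 0.20^2)$. The BMI coupling $\beta_a$ is 0 for
the green archetype and 0.06/0.09 for yellow/orange: by construction, a
high-quality diet decouples milk leptin from maternal adiposity while
lower-quality diets do not. The effect sizes are design choices (chosen
so the coupling is detectable in strata of a few dozen subjects), not
estimates of any real effect.

## The statistics harness

`summarize_by_dpa()` reports mean ± SEM per category. `compare_groups()`
follows the classical workflow: Levene pretest of variance homogeneity
at α = 0.05, natural-log transform on rejection (shifting by
`1 - min(x)` first when non-positive values are present), one-way ANOVA,
and unprotected pairwise LSD comparisons using the pooled ANOVA error,
summarised as a compact letter display (groups sharing a letter do not
differ at α). No multiplicity correction is applied across variables or
strata; that matches the exploratory character of a cohort
characterisation and is stated here so nobody mistakes the p-values for
confirmatory ones. `stratified_spearman()` computes Spearman's rank
correlation between BMI and milk leptin per category × month, using the
asymptotic p-value (ties make the exact null distribution unavailable).

## Problem sizes used in the test suite

The suite exercises the aggregation rule exhaustively (all $6^5$
item-point combinations against an independently written brute-force
oracle), monotonicity on 10,000 random diet pairs, archetype recovery on
cohorts of a few hundred subjects, the category mix and stratified
correlation pattern on a 590-subject cohort, and the ANOVA type-I error
on 1,000 null replicates of three groups of 200. These sizes give the
stochastic checks comfortable power while keeping a full run of the
suite within a few minutes on a laptop.

## Known limitations

* Micronutrients, polyunsaturated fat quality and ultra-processing are
  outside the scoring model; the items were chosen to be computable from
  any food-composition table or label.
* The interpolated intermediate bins are documented approximations
  between published anchors, not themselves published values.
* The generator's archetypes are intentionally well-separated; real
  diets straddle category boundaries far more often.
* Scoring a menu (rather than a person) requires a reference body
  weight; the package default is 65 kg.
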