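# dietprofiler

Rule-based diet-quality profiling for whole diets, designed for the kind
of scoring that digital nutrition platforms need: fast, transparent, and
computable from the nutrient totals any food-composition database or
label provides.

A diet is summarised by five items — the carbohydrate-to-fiber ratio
(CH/Fb), saturated fat as percent of energy (SFA %E), sodium (mg/day),
protein per kg body weight (P/Bw, g/kg/day) and total fiber (g/day) —
each scored 0–5 against cut-offs anchored on EFSA/WHO reference intakes
(e.g. sodium ≤ 2000 mg → 0 points, > 3200 mg → 5; P/Bw optimal at the
0.83 g/kg/day population reference intake). The three unhealthy items
sum to Points A, the two healthy ones to Points B, and the final score
is

    FS = A − B            if A < 7
    FS = A − fiber points if A ≥ 7   (protein no longer counts)

FS ≤ 3 gives category 1 (green), 4–7 category 2 (yellow), FS ≥ 8
category 3 (orange). For green/yellow diets two refinements run: a
macronutrient-balance check labelling the fat%E/carbohydrate%E ratio
"B" inside [0.33, 0.77] and "U" outside, and a food-group comparison of
12 energy shares against a reference pattern. Every verdict is
accompanied by machine-readable advice codes. A seeded synthetic-cohort
generator (diet + BMI + breast-milk leptin) and a statistics harness
(ANOVA with LSD letters, stratified Spearman correlation) make the whole
pipeline testable without access to any real cohort.

Lactating women are scored as normal adults after subtracting the EFSA
19 g/day extra protein allowance from the P/Bw input.

## Worked example

```r
library(dietprofiler)

day <- nutrient_day(carbohydrate_g = 190, fiber_g = 12, fat_g = 105,
                    sfa_g = 33, protein_g = 88, sodium_mg = 2900,
                    body_weight_kg = 66, lactating = TRUE)
derive_quantities(day)
#> <derived_quantities>
#>   energy 2081 kcal; CH/Fb 15.83; SFA 14.3 %E; fat 45.4 %E; CH 36.5 %E; protein 16.9 %E
#>   P/Bw 1.05 g/kg/day; F/CH 1.24
score_day(day)
#> <dpa_breakdown> category 2 (yellow), final score 7
#>   points: CH/Fb 3, SFA 3, sodium 3 | protein 4 (excluded), fiber 2
#>   Points A = 9, Points B = 6
```

The CH/Fb ratio of 15.8 (3 points), 14.3 %E from SFA (3) and 2900 mg
sodium (3) put Points A at 9, so protein is excluded from the positive
side and FS = 9 − 2 = 7: a yellow diet, one point short of orange. Since
the category is below 3, the balance check applies: F/CH = 1.24 is far
above 0.77, so the diet is also flagged unbalanced:

```r
classify_bmdp(derive_quantities(day)$fch_ratio)$label
#> [1] "U"
```

A full cohort run, from simulation to stratified statistics:

```r
scored <- score_cohort(generate_cohort(n = 59, seed = 1))
table(scored$dpa_category)
#>  1  2  3
#> 22 17 20
summarize_by_dpa(scored, vars = "energy_kcal")
#>   dpa_category variable     n  mean   sem
#> 1            1 energy_kcal 22 1808. 47.6
#> 2            2 energy_kcal 17 2174. 35.1
#> 3            3 energy_kcal 20 2298. 69.0
stratified_spearman(scored) |> dplyr::filter(month == 1)
#>   dpa_category month n     rho       p
#> 1            1     1 22 -0.0841 0.710
#> 2            2     1 17  0.706  0.00154
#> 3            3     1 20  0.505  0.0231
```

Energy rises with worsening category, and the BMI–milk-leptin rank
correlation is significant only in the yellow/orange strata — the
generator constructs a high-quality diet as decoupling milk leptin from
maternal BMI.

## Command line

```sh
Rscript inst/cli/dpa.R simulate --n 59 --seed 1 --out cohort.csv
Rscript inst/cli/dpa.R score cohort.csv --reference inst/extdata/reference_mediterranean_example.yaml --out report.json
Rscript inst/cli/dpa.R cohort cohort.csv --out summary.json
Rscript inst/cli/dpa.R reference-build menu1.csv menu2.csv --out reference.yaml
```

Exit codes: 0 success, 2 input validation failure, 1 internal error.
Cut-off tables and balance bounds are YAML-overridable (`--cutoffs`).

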