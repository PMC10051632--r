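#' Atwater energy conversion factors (kcal/g)
#'
#' Fat 9, protein 4, available carbohydrate 4, dietary fiber 2, alcohol 7.
#' These match the factors applied by common dietary-assessment software,
#' with fiber counted separately from available carbohydrate.
#' @export
atwater_factors <- c(fat = 9, protein = 4, carbohydrate = 4, fiber = 2, alcohol = 7)

#' Energy from macronutrient masses
#'
#' Computes dietary energy by the Atwater factors: 9 kcal/g fat, 4 kcal/g
#' protein and available carbohydrate, 2 kcal/g fiber, 7 kcal/g alcohol.
#' Vectorised over its arguments.
#'
#' @param fat_g,protein_g,carbohydrate_g,fiber_g,alcohol_g Daily masses in
#'   grams; `carbohydrate_g` is available carbohydrate, excluding fiber.
#' @return Energy in kcal/day.
#' @export
#' @examples
#' energy_from_macros(10, 10, 10, 5, 0) # 180 kcal
energy_from_macros <- function(fat_g, protein_g, carbohydrate_g, fiber_g = 0,
                               alcohol_g = 0) {
  check_nonneg(fat_g, "fat_g")
  check_nonneg(protein_g, "protein_g")
  check_nonneg(carbohydrate_g, "carbohydrate_g")
  check_nonneg(fiber_g, "fiber_g")
  check_nonneg(alcohol_g, "alcohol_g")
  9 * fat_g + 4 * protein_g + 4 * carbohydrate_g + 2 * fiber_g + 7 * alcohol_g
}

#' Lactation protein adjustment
#'
#' During the first months of lactation EFSA stipulates a 19 g/day extra
#' protein requirement. Before the protein/body-weight ratio is scored,
#' that extra allowance is subtracted from the reported intake (floored at
#' zero) so a lactating woman is scored as if she were a non-lactating
#' adult. The adjustment applies only to the scoring input; percent-energy
#' accounting always uses the unadjusted intake.
#'
#' @param protein_g Reported protein intake, g/day.
#' @param lactating Logical; apply the adjustment?
#' @param extra_g Size of the lactation allowance, g/day (default 19).
#' @return Adjusted protein, g/day.
#' @export
#' @examples
#' lactation_adjusted_protein(80, TRUE)  # 61
#' lactation_adjusted_protein(10, TRUE)  # 0, floored
lactation_adjusted_protein <- function(protein_g, lactating, extra_g = 19) {
  check_nonneg(protein_g, "protein_g")
  ifelse(lactating, pmax(protein_g - extra_g, 0), protein_g)
}

#' Construct a validated one-day (or person-average) nutrient record
#'
#' The basic input unit of the scorer: daily totals of available
#' carbohydrate, fiber, fat, saturated fat, protein (all g), sodium (mg),
#' optional alcohol and sugars, together with body weight and a lactation
#' flag. If `energy_kcal` is not supplied it is reconstructed from the
#' Atwater factors; if it is supplied and disagrees with the Atwater
#' reconstruction by more than 5% a warning is raised but the supplied
#' value is kept (dietary software usually reports its own energy total).
#'
#' @param carbohydrate_g Available carbohydrate, g/day (excluding fiber;
#'   see `carbohydrate_includes_fiber`).
#' @param fiber_g Total dietary fiber, g/day.
#' @param fat_g Total fat, g/day.
#' @param sfa_g Saturated fatty acids, g/day (must not exceed `fat_g`).
#' @param protein_g Protein, g/day.
#' @param sodium_mg Sodium, mg/day.
#' @param body_weight_kg Body weight, kg.
#' @param alcohol_g Alcohol, g/day (default 0).
#' @param sugars_g Total sugars, g/day (optional, descriptive only; must
#'   not exceed carbohydrate).
#' @param energy_kcal Total energy, kcal/day (optional).
#' @param lactating Logical lactation flag (default `FALSE`).
#' @param carbohydrate_includes_fiber If `TRUE`, `carbohydrate_g` was
#'   reported as total carbohydrate including fiber and fiber is subtracted
#'   before use.
#' @return An object of class `nutrient_day` (a named list).
#' @export
#' @examples
#' nutrient_day(carbohydrate_g = 190, fiber_g = 18, fat_g = 98, sfa_g = 30,
#'              protein_g = 82, sodium_mg = 2500, body_weight_kg = 65)
nutrient_day <- function(carbohydrate_g, fiber_g, fat_g, sfa_g, protein_g,
                         sodium_mg, body_weight_kg, alcohol_g = 0,
                         sugars_g = NA_real_, energy_kcal = NA_real_,
                         lactating = FALSE,
                         carbohydrate_includes_fiber = FALSE) {
  check_nonneg(fiber_g, "fiber_g")
  if (isTRUE(carbohydrate_includes_fiber)) {
    carbohydrate_g <- carbohydrate_g - fiber_g
    if (any(carbohydrate_g < 0)) {
      stop_validation("carbohydrate_g < fiber_g after removing fiber from total carbohydrate")
    }
  }
  check_nonneg(carbohydrate_g, "carbohydrate_g")
  check_nonneg(fat_g, "fat_g")
  check_nonneg(sfa_g, "sfa_g")
  check_nonneg(protein_g, "protein_g")
  check_nonneg(sodium_mg, "sodium_mg")
  check_nonneg(alcohol_g, "alcohol_g")
  check_positive(body_weight_kg, "body_weight_kg")
  if (sfa_g > fat_g + 1e-9) {
    stop_validation("sfa_g (%s) must not exceed fat_g (%s)", sfa_g, fat_g)
  }
  if (!is.na(sugars_g)) {
    check_nonneg(sugars_g, "sugars_g")
    if (sugars_g > carbohydrate_g + 1e-9) {
      stop_validation("sugars_g (%s) must not exceed carbohydrate_g (%s)",
                      sugars_g, carbohydrate_g)
    }
  }
  if (!is.na(energy_kcal)) check_nonneg(energy_kcal, "energy_kcal")
  structure(
    list(carbohydrate_g = as.numeric(carbohydrate_g),
         fiber_g = as.numeric(fiber_g),
         fat_g = as.numeric(fat_g),
         sfa_g = as.numeric(sfa_g),
         protein_g = as.numeric(protein_g),
         sodium_mg = as.numeric(sodium_mg),
         alcohol_g = as.numeric(alcohol_g),
         sugars_g = as.numeric(sugars_g),
         energy_kcal = as.numeric(energy_kcal),
         body_weight_kg = as.numeric(body_weight_kg),
         lactating = isTRUE(lactating)),
    class = "nutrient_day"
  )
}

#' @export
print.nutrient_day <- function(x, ...) {
  cat("<nutrient_day>",
      sprintf("  CH %.1f g, fiber %.1f g, fat %.1f g (SFA %.1f g), protein %.1f g",
              x$carbohydrate_g, x$fiber_g, x$fat_g, x$sfa_g, x$protein_g),
      sprintf("  sodium %.0f mg, alcohol %.1f g, body weight %.1f kg%s",
              x$sodium_mg, x$alcohol_g, x$body_weight_kg,
              if (x$lactating) ", lactating" else ""),
      sep = "\n")
  invisible(x)
}

#' Derived nutritional quantities for scoring
#'
#' From a daily nutrient record computes everything the scorer consumes:
#' total energy (supplied or Atwater-reconstructed), the carbohydrate/fiber
#' ratio, percent of energy from fat, carbohydrate, protein and saturated
#' fat, the lactation-adjusted protein/body-weight ratio, and the
#' fat-to-carbohydrate energy ratio used by the macronutrient-balance
#' check.
#'
#' A zero-fiber diet has an undefined carbohydrate/fiber ratio; it is
#' assigned `Inf`, which the scorer maps to the worst bin (a diet with no
#' fiber at all is strictly worse than any finite ratio).
#'
#' @param day A [nutrient_day()] object.
#' @return A list of class `derived_quantities` with elements
#'   `energy_kcal`, `chfb_ratio`, `sfa_pct_energy`, `fat_pct_energy`,
#'   `ch_pct_energy`, `protein_pct_energy`, `pbw_ratio`, `fch_ratio`.
#' @export
derive_quantities <- function(day) {
  stopifnot(inherits(day, "nutrient_day"))
  atwater <- energy_from_macros(day$fat_g, day$protein_g, day$carbohydrate_g,
                                day$fiber_g, day$alcohol_g)
  energy <- if (!is.na(day$energy_kcal)) {
    if (atwater > 0 && abs(day$energy_kcal - atwater) / atwater > 0.05) {
      warning(sprintf(
        "supplied energy (%.0f kcal) differs from Atwater reconstruction (%.0f kcal) by > 5%%; using supplied value",
        day$energy_kcal, atwater))
    }
    day$energy_kcal
  } else {
    atwater
  }
  any_mass <- day$fat_g > 0 || day$carbohydrate_g > 0 || day$protein_g > 0 ||
    day$sfa_g > 0
  if (energy <= 0 && any_mass) {
    stop_validation("total energy is zero but nutrient masses are nonzero; cannot form %% energy shares")
  }
  pct <- function(kcal) if (energy > 0) 100 * kcal / energy else 0
  fat_pct <- pct(9 * day$fat_g)
  ch_pct <- pct(4 * day$carbohydrate_g)
  chfb <- if (day$fiber_g > 0) day$carbohydrate_g / day$fiber_g else Inf
  structure(
    list(energy_kcal = energy,
         chfb_ratio = chfb,
         sfa_pct_energy = pct(9 * day$sfa_g),
         fat_pct_energy = fat_pct,
         ch_pct_energy = ch_pct,
         protein_pct_energy = pct(4 * day$protein_g),
         pbw_ratio = lactation_adjusted_protein(day$protein_g, day$lactating) /
           day$body_weight_kg,
         fch_ratio = if (ch_pct > 0) fat_pct / ch_pct else Inf),
    class = "derived_quantities"
  )
}

#' @export
print.derived_quantities <- function(x, ...) {
  cat("<derived_quantities>",
      sprintf("  energy %.0f kcal; CH/Fb %.2f; SFA %.1f %%E; fat %.1f %%E; CH %.1f %%E; protein %.1f %%E",
              x$energy_kcal, x$chfb_ratio, x$sfa_pct_energy, x$fat_pct_energy,
              x$ch_pct_energy, x$protein_pct_energy),
      sprintf("  P/Bw %.2f g/kg/day; F/CH %.2f", x$pbw_ratio, x$fch_ratio),
      sep = "\n")
  invisible(x)
}

#' Build a nutrient record that realises target scoring inputs
#'
#' Inverse construction used by examples, tests and the synthetic cohort:
#' given the quantities the scorer actually sees (carbohydrate/fiber ratio,
#' SFA % energy, sodium, protein/body-weight ratio, fiber grams) plus a
#' target fat % energy, solves for a consistent set of gram intakes.
#' With available carbohydrate `CH = chfb * fiber`, protein fixed by the
#' P/Bw target (plus the 19 g lactation allowance when `lactating`), and
#' fat share f of energy, total energy satisfies
#' `E = (4 (CH + protein) + 2 fiber) / (1 - f)`.
#'
#' @param chfb_ratio Target carbohydrate/fiber ratio.
#' @param sfa_pct_energy Target % of energy from saturated fat; must be
#'   at most `fat_pct_energy`.
#' @param sodium_mg Sodium, mg/day.
#' @param pbw_ratio Target (post-adjustment) protein/body-weight ratio.
#' @param fiber_g Fiber, g/day.
#' @param fat_pct_energy Target % of energy from total fat (default 30).
#' @param body_weight_kg Body weight, kg (default 65).
#' @param lactating Lactation flag; when `TRUE` the generated protein
#'   intake includes the 19 g allowance so the scored ratio still equals
#'   `pbw_ratio`.
#' @return A [nutrient_day()] object whose [derive_quantities()] reproduce
#'   the targets.
#' @export
#' @examples
#' d <- nutrient_day_from_targets(8, 8, 1500, 0.83, 30)
#' derive_quantities(d)$chfb_ratio # 8
nutrient_day_from_targets <- function(chfb_ratio, sfa_pct_energy, sodium_mg,
                                      pbw_ratio, fiber_g,
                                      fat_pct_energy = 30,
                                      body_weight_kg = 65,
                                      lactating = FALSE) {
  check_nonneg(chfb_ratio, "chfb_ratio")
  check_prob_range(fat_pct_energy, "fat_pct_energy", 0, 99)
  if (sfa_pct_energy > fat_pct_energy) {
    stop_validation("sfa_pct_energy must not exceed fat_pct_energy")
  }
  ch <- chfb_ratio * fiber_g
  protein <- pbw_ratio * body_weight_kg + if (lactating) 19 else 0
  f <- fat_pct_energy / 100
  energy <- (4 * (ch + protein) + 2 * fiber_g) / (1 - f)
  fat <- f * energy / 9
  sfa <- sfa_pct_energy / 100 * energy / 9
  nutrient_day(carbohydrate_g = ch, fiber_g = fiber_g, fat_g = fat,
               sfa_g = sfa, protein_g = protein, sodium_mg = sodium_mg,
               body_weight_kg = body_weight_kg, lactating = lactating)
}
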