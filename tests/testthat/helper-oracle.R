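# Independent brute-force re-implementation of the points aggregation and
# category rule, written as literal prose-following control flow so it can
# serve as an oracle for the vectorised implementation.
oracle_aggregate <- function(chfb, sfa, sodium, protein, fiber) {
  a <- 0
  for (unhealthy in c(chfb, sfa, sodium)) a <- a + unhealthy
  b <- protein + fiber
  if (a < 7) {
    fs <- a - b
    excluded <- FALSE
  } else {
    fs <- a - fiber
    excluded <- TRUE
  }
  if (fs <= 3) {
    category <- 1; colour <- "green"
  } else if (fs <= 7) {
    category <- 2; colour <- "yellow"
  } else {
    category <- 3; colour <- "orange"
  }
  list(points_a = a, points_b = b, protein_excluded = excluded,
       final_score = fs, dpa_category = category, color = colour)
}

# quick builder for a valid daily record
make_day <- function(carbohydrate_g = 190, fiber_g = 18, fat_g = 98,
                     sfa_g = 30, protein_g = 82, sodium_mg = 2500,
                     body_weight_kg = 65, ...) {
  nutrient_day(carbohydrate_g = carbohydrate_g, fiber_g = fiber_g,
               fat_g = fat_g, sfa_g = sfa_g, protein_g = protein_g,
               sodium_mg = sodium_mg, body_weight_kg = body_weight_kg, ...)
}
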