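test_that("Atwater energy reconstruction matches hand sums", {
  expect_equal(energy_from_macros(0, 0, 0, 0, 0), 0)
  expect_equal(energy_from_macros(10, 10, 10, 5, 0), 180) # 90+40+40+10
  expect_equal(energy_from_macros(1, 0, 0, 0, 1), 16)     # 9+7
  expect_error(energy_from_macros(-1, 0, 0), class = "dietprofiler_validation_error")
  expect_error(energy_from_macros(0, 0, 0, 0, -2), "alcohol_g",
               class = "dietprofiler_validation_error")
})

test_that("energy is linear: doubling all masses doubles energy", {
  set.seed(11)
  for (i in 1:20) {
    x <- runif(5, 0, 200)
    e1 <- energy_from_macros(x[1], x[2], x[3], x[4], x[5])
    e2 <- energy_from_macros(2 * x[1], 2 * x[2], 2 * x[3], 2 * x[4], 2 * x[5])
    expect_gte(e1, 0)
    expect_equal(e2, 2 * e1)
  }
})

test_that("lactation adjustment subtracts 19 g with a floor at zero", {
  expect_equal(lactation_adjusted_protein(80, TRUE), 61)
  expect_equal(lactation_adjusted_protein(80, FALSE), 80)
  expect_equal(lactation_adjusted_protein(10, TRUE), 0)
  # vectorised over the flag
  expect_equal(lactation_adjusted_protein(c(80, 80), c(TRUE, FALSE)), c(61, 80))
})

test_that("derived quantities reproduce hand-computed shares and ratios", {
  day <- make_day(carbohydrate_g = 189.7, fiber_g = 18, fat_g = 97.9,
                  sfa_g = 30, protein_g = 82.1, sodium_mg = 2500)
  dq <- derive_quantities(day)
  # hand arithmetic: E = 9*97.9 + 4*82.1 + 4*189.7 + 2*18 = 2004.3 kcal
  expect_equal(dq$energy_kcal, 2004.3)
  expect_equal(dq$fat_pct_energy, 100 * 9 * 97.9 / 2004.3, tolerance = 1e-10)
  expect_equal(round(dq$fat_pct_energy, 1), 44.0)
  expect_equal(round(dq$protein_pct_energy, 1), 16.4)
  expect_equal(round(dq$ch_pct_energy, 1), 37.9)
  expect_equal(dq$chfb_ratio, 189.7 / 18)
})

test_that("chfb ratio divides carbohydrate by fiber, Inf when fiber is zero", {
  expect_equal(derive_quantities(make_day(carbohydrate_g = 100, fiber_g = 10))$chfb_ratio, 10)
  expect_equal(derive_quantities(make_day(fiber_g = 0))$chfb_ratio, Inf)
})

test_that("fch ratio is the ratio of the energy shares", {
  day <- make_day()
  dq <- derive_quantities(day)
  expect_equal(dq$fch_ratio, dq$fat_pct_energy / dq$ch_pct_energy)
  expect_equal(round(43.8 / 37.9, 2), 1.16) # magnitude check of the definition
})

test_that("with no alcohol the four Atwater energy shares sum to 100", {
  set.seed(21)
  for (i in 1:25) {
    day <- make_day(carbohydrate_g = runif(1, 50, 400),
                    fiber_g = runif(1, 1, 60), fat_g = runif(1, 20, 150),
                    sfa_g = 5, protein_g = runif(1, 20, 150))
    dq <- derive_quantities(day)
    fiber_share <- 100 * 2 * day$fiber_g / dq$energy_kcal
    expect_equal(dq$fat_pct_energy + dq$ch_pct_energy +
                   dq$protein_pct_energy + fiber_share, 100)
  }
})

test_that("ratios are invariant to a common scaling of all masses", {
  day1 <- make_day()
  day2 <- make_day(carbohydrate_g = 190 * 3, fiber_g = 18 * 3, fat_g = 98 * 3,
                   sfa_g = 90, protein_g = 82 * 3, sodium_mg = 2500)
  dq1 <- derive_quantities(day1); dq2 <- derive_quantities(day2)
  expect_equal(dq1$chfb_ratio, dq2$chfb_ratio)
  expect_equal(dq1$fch_ratio, dq2$fch_ratio, tolerance = 1e-12)
})

test_that("lactation never increases the scored protein ratio", {
  for (p in c(5, 19, 40, 120)) {
    d_lac <- make_day(protein_g = p, lactating = TRUE)
    d_non <- make_day(protein_g = p, lactating = FALSE)
    expect_lte(derive_quantities(d_lac)$pbw_ratio,
               derive_quantities(d_non)$pbw_ratio)
  }
})

test_that("the 19 g adjustment affects only the scored ratio, not %E", {
  d_lac <- make_day(protein_g = 82, lactating = TRUE)
  d_non <- make_day(protein_g = 82, lactating = FALSE)
  expect_equal(derive_quantities(d_lac)$protein_pct_energy,
               derive_quantities(d_non)$protein_pct_energy)
  expect_equal(derive_quantities(d_lac)$pbw_ratio, (82 - 19) / 65)
})

test_that("record validation enforces the declared invariants", {
  expect_error(make_day(sodium_mg = -5), "sodium_mg",
               class = "dietprofiler_validation_error")
  expect_error(make_day(body_weight_kg = 0), class = "dietprofiler_validation_error")
  expect_error(make_day(sfa_g = 120, fat_g = 98), "sfa_g",
               class = "dietprofiler_validation_error")
  expect_error(make_day(sugars_g = 300), "sugars_g",
               class = "dietprofiler_validation_error")
  # total carbohydrate including fiber is converted to available carbohydrate
  d <- make_day(carbohydrate_g = 208, fiber_g = 18,
                carbohydrate_includes_fiber = TRUE)
  expect_equal(d$carbohydrate_g, 190)
})

test_that("supplied energy wins the %E denominator but a >5% gap warns", {
  quiet <- make_day(energy_kcal = 2000) # Atwater approx 2004.3: within 5%
  expect_silent(dq <- derive_quantities(quiet))
  expect_equal(dq$energy_kcal, 2000)
  loud <- make_day(energy_kcal = 1500)
  expect_warning(dq2 <- derive_quantities(loud), "Atwater")
  expect_equal(dq2$energy_kcal, 1500)
})

test_that("target-realising construction round-trips the scoring inputs", {
  d <- nutrient_day_from_targets(8, 8, 1500, 0.83, 30)
  dq <- derive_quantities(d)
  expect_equal(dq$chfb_ratio, 8)
  expect_equal(dq$sfa_pct_energy, 8, tolerance = 1e-12)
  expect_equal(dq$pbw_ratio, 0.83)
  expect_equal(dq$fat_pct_energy, 30, tolerance = 1e-12)
})
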