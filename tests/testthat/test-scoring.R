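test_that("published end cut-offs score exactly as printed", {
  # carbohydrate/fiber: <=10 best, >18 worst
  expect_equal(score_chfb(9), 0L)
  expect_equal(score_chfb(10), 0L)
  expect_equal(score_chfb(19), 5L)
  # SFA % energy: <=10 best, >18 worst
  expect_equal(score_sfa(9), 0L)
  expect_equal(score_sfa(10), 0L)
  expect_equal(score_sfa(19), 5L)
  # sodium: <=2000 mg best, >3200 mg worst
  expect_equal(score_sodium(2000), 0L)
  expect_equal(score_sodium(3300), 5L)
  expect_equal(score_sodium(0), 0L)
  # protein/body weight: 0.83 optimal, 0.6-0.829 deficit band, <0.6 floor
  expect_equal(score_protein(0.83), 5L)
  expect_equal(score_protein(0.7), 2L)
  expect_equal(score_protein(0.5), 0L)
  # fiber: >25 g best, <=5 g worst
  expect_equal(score_fiber(30), 5L)
  expect_equal(score_fiber(4), 0L)
})

test_that("interpolated bins are left-open/right-closed between the anchors", {
  expect_equal(score_chfb(c(10.0001, 12, 12.5, 14, 16, 18)),
               c(1L, 1L, 2L, 2L, 3L, 4L))
  expect_equal(score_sodium(c(2000.5, 2300, 2600, 2900, 3200)),
               c(1L, 1L, 2L, 3L, 4L))
  expect_equal(score_fiber(c(5, 5.5, 10, 25, 25.0001)),
               c(0L, 1L, 1L, 4L, 5L))
  expect_equal(score_protein(c(0.829, 1.0, 1.01, 1.4, 1.8, 1.81)),
               c(2L, 5L, 4L, 3L, 1L, 0L))
})

test_that("a zero-fiber diet scores the worst carbohydrate/fiber bin", {
  expect_equal(score_chfb(Inf), 5L)
  bd <- score_day(make_day(fiber_g = 0))
  expect_equal(bd$chfb_points, 5L)
})

test_that("banded scorers are monotone and reject invalid input", {
  x <- sort(runif(200, 0, 40))
  expect_true(all(diff(score_chfb(x)) >= 0))
  expect_true(all(diff(score_fiber(x)) >= 0))
  expect_error(score_chfb(-1), class = "dietprofiler_validation_error")
  expect_error(score_sfa(120), class = "dietprofiler_validation_error")
  expect_error(score_sodium(-10), class = "dietprofiler_validation_error")
  expect_error(score_protein(-0.1), class = "dietprofiler_validation_error")
})

test_that("aggregation follows the A/B rule with the protein exclusion", {
  r <- aggregate_points(0, 0, 0, 5, 5)
  expect_equal(r$points_a, 0L); expect_equal(r$points_b, 10L)
  expect_false(r$protein_excluded); expect_equal(r$final_score, -10L)

  r <- aggregate_points(5, 0, 5, 5, 5) # A = 10 >= 7: protein dropped
  expect_true(r$protein_excluded)
  expect_equal(r$final_score, 5L)

  r <- aggregate_points(5, 5, 5, 0, 0)
  expect_equal(r$final_score, 15L)

  # boundary: A = 7 exactly triggers the exclusion branch
  r <- aggregate_points(5, 2, 0, 5, 0)
  expect_true(r$protein_excluded)
  expect_equal(r$final_score, 7L)
  expect_error(aggregate_points(6, 0, 0, 0, 0),
               class = "dietprofiler_validation_error")
})

test_that("final-score categories partition -10..15 as printed", {
  res <- categorize_fs(-10:15)
  expect_equal(res$dpa_category[match(3, -10:15)], 1L)
  expect_equal(res$dpa_category[match(4, -10:15)], 2L)
  expect_equal(res$dpa_category[match(7, -10:15)], 2L)
  expect_equal(res$dpa_category[match(8, -10:15)], 3L)
  expect_true(all(res$dpa_category %in% 1:3))
  expect_true(all(diff(res$dpa_category) >= 0)) # non-decreasing in FS
  expect_equal(unname(c(table(res$color))[c("green", "yellow", "orange")]),
               c(sum(-10:15 <= 3), 4L, 8L))
  expect_error(categorize_fs(16), "range")
  expect_error(categorize_fs(-11), "range")
})

test_that("the full scorer reproduces the ideal and worst reference diets", {
  ideal <- score_profile(8, 8, 1500, 0.83, 30)
  expect_equal(ideal$final_score, -10L)
  expect_equal(ideal$dpa_category, 1L)
  expect_equal(ideal$color, "green")

  worst <- score_profile(Inf, 20, 4000, 0.4, 0)
  expect_equal(worst$final_score, 15L)
  expect_equal(worst$dpa_category, 3L)
  expect_equal(worst$color, "orange")
})

test_that("score_day is deterministic and agrees with score_profile", {
  day <- nutrient_day_from_targets(12.5, 13, 2400, 0.9, 17)
  b1 <- score_day(day); b2 <- score_day(day)
  expect_identical(b1[names(b1) != "derived"], b2[names(b2) != "derived"])
  dq <- derive_quantities(day)
  via_profile <- score_profile(dq$chfb_ratio, dq$sfa_pct_energy,
                               day$sodium_mg, dq$pbw_ratio, day$fiber_g)
  expect_equal(b1$final_score, via_profile$final_score)
  expect_equal(b1$dpa_category, via_profile$dpa_category)
})

test_that("exhaustive enumeration of item points matches the brute-force oracle", {
  grid <- expand.grid(chfb = 0:5, sfa = 0:5, sodium = 0:5,
                      protein = 0:5, fiber = 0:5)
  got <- aggregate_points(
    grid$chfb, grid$sfa, grid$sodium, grid$protein, grid$fiber)
  cats <- categorize_fs(got$final_score)
  want <- mapply(function(c1, c2, c3, p, f) {
    o <- oracle_aggregate(c1, c2, c3, p, f)
    list(o$points_a, o$final_score, o$protein_excluded, o$dpa_category,
         o$color)
  }, grid$chfb, grid$sfa, grid$sodium, grid$protein, grid$fiber)
  expect_identical(got$points_a, as.integer(want[1, ]))
  expect_identical(got$final_score, as.integer(want[2, ]))
  expect_identical(got$protein_excluded, as.logical(want[3, ]))
  expect_identical(cats$dpa_category, as.integer(want[4, ]))
  expect_identical(cats$color, as.character(want[5, ]))
})

test_that("worsening one unhealthy input never lowers the final score", {
  set.seed(101)
  n <- 10000
  base <- data.frame(chfb = runif(n, 0, 30), sfa = runif(n, 0, 30),
                     sodium = runif(n, 0, 5000), pbw = runif(n, 0, 2.5),
                     fiber = runif(n, 0, 40))
  which_item <- sample(1:3, n, replace = TRUE)
  bump <- runif(n, 0, 10)
  worse <- base
  worse$chfb <- worse$chfb + ifelse(which_item == 1, bump, 0)
  worse$sfa <- pmin(worse$sfa + ifelse(which_item == 2, bump, 0), 100)
  worse$sodium <- worse$sodium + ifelse(which_item == 3, bump * 200, 0)
  fs0 <- score_profile(base$chfb, base$sfa, base$sodium, base$pbw,
                       base$fiber)$final_score
  fs1 <- score_profile(worse$chfb, worse$sfa, worse$sodium, worse$pbw,
                       worse$fiber)$final_score
  expect_true(all(fs1 >= fs0))
})

test_that("more fiber never raises the final score", {
  set.seed(102)
  n <- 5000
  chfb <- runif(n, 0, 30); sfa <- runif(n, 0, 25)
  sodium <- runif(n, 0, 4500); pbw <- runif(n, 0, 2.5)
  fiber <- runif(n, 0, 35)
  fs0 <- score_profile(chfb, sfa, sodium, pbw, fiber)$final_score
  fs1 <- score_profile(chfb, sfa, sodium, pbw, fiber + runif(n, 0, 15))$final_score
  expect_true(all(fs1 <= fs0))
})

test_that("crossing the exclusion threshold jumps the score discontinuously", {
  # with protein points > 0, moving A from 6 to 7 raises FS by 1 + protein pts
  for (pp in 1:5) {
    for (fp in 0:5) {
      fs6 <- aggregate_points(5, 1, 0, pp, fp)$final_score # A = 6
      fs7 <- aggregate_points(5, 2, 0, pp, fp)$final_score # A = 7
      expect_equal(fs7 - fs6, 1L + pp)
    }
  }
})

test_that("custom cut-off tables flow through the scorer", {
  ct <- default_cutoffs()
  ct$sodium$breaks <- c(1500, 1800, 2100, 2400, 2700)
  expect_equal(score_sodium(2000, ct), 2L)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_cutoffs(ct, tmp)
  expect_equal(read_cutoffs(tmp)$sodium$breaks, ct$sodium$breaks)
  expect_equal(score_protein(0.83, read_cutoffs(tmp)), 5L)
})

test_that("score_cohort scores a record table row-wise", {
  recs <- tibble::tibble(
    carbohydrate_g = c(224, 570), fiber_g = c(28, 30), fat_g = c(59, 150),
    sfa_g = c(16, 40), protein_g = c(54, 54), sodium_mg = c(1500, 3300),
    body_weight_kg = c(65, 65))
  out <- score_cohort(recs)
  expect_equal(nrow(out), 2)
  expect_equal(out$chfb_points, score_chfb(recs$carbohydrate_g / recs$fiber_g))
  expect_true(all(c("final_score", "dpa_category", "fch_ratio") %in% names(out)))
  expect_error(score_cohort(recs[, -1]), "carbohydrate_g",
               class = "dietprofiler_validation_error")
})
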