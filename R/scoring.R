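#' Per-item diet scoring
#'
#' Each item converts a nutritional quantity into 0-5 points using the
#' cut-off tables of [default_cutoffs()]. For the three "unhealthy" items
#' (carbohydrate/fiber ratio, SFA % energy, sodium) more points mean a
#' worse diet; for fiber more points mean a better diet; protein points
#' peak at the EFSA reference intake of 0.83 g/kg/day. Inputs are compared
#' to cut-offs at full precision (no pre-rounding), with "<=" anchors
#' inclusive on the good side and ">" anchors exclusive, so e.g. a
#' carbohydrate/fiber ratio of exactly 10 scores 0 and 10.0001 scores 1.
#'
#' All scorers are vectorised.
#'
#' @param chfb_ratio Carbohydrate/fiber ratio (g/g); `Inf` (zero-fiber
#'   diet) scores the worst bin.
#' @param sfa_pct_energy Percent of total energy from saturated fat.
#' @param sodium_mg Sodium intake, mg/day.
#' @param pbw_ratio Protein/body-weight ratio, g/kg/day (lactation-adjusted
#'   where applicable).
#' @param fiber_g Total fiber, g/day.
#' @param cutoffs A cut-off list, by default [default_cutoffs()].
#' @return Integer points in 0..5.
#' @name item_scores
#' @examples
#' score_chfb(c(9, 10, 10.5, 19))  # 0 0 1 5
#' score_protein(c(0.5, 0.7, 0.83, 1.9))  # 0 2 5 0
NULL

score_banded <- function(x, breaks) {
  # points = number of breaks strictly exceeded; left-open/right-closed bins
  pts <- rowSums(outer(x, breaks, ">"))
  as.integer(pts)
}

#' @rdname item_scores
#' @export
score_chfb <- function(chfb_ratio, cutoffs = default_cutoffs()) {
  if (any(is.na(chfb_ratio)) || any(chfb_ratio < 0)) {
    stop_validation("chfb_ratio must be >= 0 (Inf allowed for zero-fiber diets)")
  }
  score_banded(chfb_ratio, cutoffs$chfb$breaks)
}

#' @rdname item_scores
#' @export
score_sfa <- function(sfa_pct_energy, cutoffs = default_cutoffs()) {
  check_prob_range(sfa_pct_energy, "sfa_pct_energy", 0, 100)
  score_banded(sfa_pct_energy, cutoffs$sfa$breaks)
}

#' @rdname item_scores
#' @export
score_sodium <- function(sodium_mg, cutoffs = default_cutoffs()) {
  check_nonneg(sodium_mg, "sodium_mg")
  score_banded(sodium_mg, cutoffs$sodium$breaks)
}

#' @rdname item_scores
#' @export
score_fiber <- function(fiber_g, cutoffs = default_cutoffs()) {
  check_nonneg(fiber_g, "fiber_g")
  score_banded(fiber_g, cutoffs$fiber$breaks)
}

#' @rdname item_scores
#' @export
score_protein <- function(pbw_ratio, cutoffs = default_cutoffs()) {
  check_nonneg(pbw_ratio, "pbw_ratio")
  tab <- cutoffs$protein
  vapply(pbw_ratio, function(x) {
    for (i in seq_len(nrow(tab))) {
      lo_ok <- if (tab$min_closed[i]) x >= tab$min[i] else x > tab$min[i]
      hi_ok <- if (tab$max_closed[i]) x <= tab$max[i] else x < tab$max[i]
      if (lo_ok && hi_ok) return(as.integer(tab$points[i]))
    }
    stop_validation("pbw_ratio %s not covered by the protein cut-off table", x)
  }, integer(1))
}

#' Aggregate item points into the final score
#'
#' The three unhealthy items sum to Points A (0-15) and the two healthy
#' items to Points B (0-10). If A < 7 the final score is A - B. If A >= 7
#' the diet already carries a heavy unhealthy load and protein no longer
#' counts as a positive item (to avoid rewarding protein from unhealthy
#' sources): the final score is A minus the fiber points only.
#'
#' @param chfb_points,sfa_points,sodium_points,protein_points,fiber_points
#'   Item points, each in 0..5. Vectorised.
#' @param exclusion_threshold Points A at or above which protein is
#'   excluded from the positive side (default 7).
#' @return A tibble with columns `points_a`, `points_b`,
#'   `protein_excluded`, `final_score`.
#' @export
#' @examples
#' aggregate_points(0, 0, 0, 5, 5)$final_score   # -10
#' aggregate_points(5, 0, 5, 5, 5)$final_score   # 5: A = 10 excludes protein
aggregate_points <- function(chfb_points, sfa_points, sodium_points,
                             protein_points, fiber_points,
                             exclusion_threshold = 7) {
  pts <- cbind(chfb_points, sfa_points, sodium_points, protein_points,
               fiber_points)
  if (any(is.na(pts)) || any(pts < 0) || any(pts > 5) || any(pts != round(pts))) {
    stop_validation("item points must be integers in 0..5")
  }
  a <- chfb_points + sfa_points + sodium_points
  b <- protein_points + fiber_points
  excluded <- a >= exclusion_threshold
  fs <- ifelse(excluded, a - fiber_points, a - b)
  tibble::tibble(points_a = as.integer(a), points_b = as.integer(b),
                 protein_excluded = excluded, final_score = as.integer(fs))
}

#' Map a final score to the 3-level category and color
#'
#' Final scores of 3 or less rank category 1 (green, good quality), 4-7
#' rank 2 (yellow, sub-optimal), and 8 or more rank 3 (orange, poor
#' quality).
#'
#' @param final_score Integer final score(s) in -10..15.
#' @return A tibble with integer `dpa_category` (1, 2 or 3) and character
#'   `color` ("green", "yellow", "orange").
#' @export
#' @examples
#' categorize_fs(c(3, 4, 7, 8))
categorize_fs <- function(final_score) {
  if (any(is.na(final_score)) || any(final_score != round(final_score))) {
    stop("final_score must be integer-valued")
  }
  if (any(final_score < -10) || any(final_score > 15)) {
    stop("final_score outside the reachable range -10..15; inconsistent item points upstream")
  }
  cat <- ifelse(final_score <= 3, 1L, ifelse(final_score <= 7, 2L, 3L))
  tibble::tibble(dpa_category = cat,
                 color = c("green", "yellow", "orange")[cat])
}

#' Score a diet from the five item inputs
#'
#' Runs the complete scorer (item points, Points A/B aggregation with the
#' protein-exclusion rule, category and color) on the quantities the items
#' consume. Vectorised: pass equal-length vectors to score a cohort.
#'
#' @inheritParams item_scores
#' @return A tibble with one row per diet: the five `*_points` columns,
#'   `points_a`, `points_b`, `protein_excluded`, `final_score`,
#'   `dpa_category` and `color`.
#' @export
#' @examples
#' score_profile(8, 8, 1500, 0.83, 30)   # category 1, green
#' score_profile(19, 9, 3300, 0.83, 30)  # A = 10: protein excluded, category 2
score_profile <- function(chfb_ratio, sfa_pct_energy, sodium_mg, pbw_ratio,
                          fiber_g, cutoffs = default_cutoffs()) {
  items <- tibble::tibble(
    chfb_points = score_chfb(chfb_ratio, cutoffs),
    sfa_points = score_sfa(sfa_pct_energy, cutoffs),
    sodium_points = score_sodium(sodium_mg, cutoffs),
    protein_points = score_protein(pbw_ratio, cutoffs),
    fiber_points = score_fiber(fiber_g, cutoffs)
  )
  agg <- aggregate_points(items$chfb_points, items$sfa_points,
                          items$sodium_points, items$protein_points,
                          items$fiber_points)
  dplyr::bind_cols(items, agg, categorize_fs(agg$final_score))
}

#' Score a single daily nutrient record
#'
#' Derives the scoring quantities from a [nutrient_day()] record (energy,
#' carbohydrate/fiber ratio, SFA % energy, lactation-adjusted
#' protein/body-weight ratio) and runs the full scorer.
#'
#' @param day A [nutrient_day()] object.
#' @param cutoffs Cut-off tables, by default [default_cutoffs()].
#' @return A list of class `dpa_breakdown` with the item points, `points_a`,
#'   `points_b`, `protein_excluded`, `final_score`, `dpa_category`, `color`
#'   and the `derived` quantities.
#' @export
#' @examples
#' day <- nutrient_day_from_targets(8, 8, 1500, 0.83, 30)
#' score_day(day)
score_day <- function(day, cutoffs = default_cutoffs()) {
  dq <- derive_quantities(day)
  row <- score_profile(dq$chfb_ratio, dq$sfa_pct_energy, day$sodium_mg,
                       dq$pbw_ratio, day$fiber_g, cutoffs)
  structure(c(as.list(row), list(derived = dq)), class = "dpa_breakdown")
}

#' @export
print.dpa_breakdown <- function(x, ...) {
  cat(sprintf("<dpa_breakdown> category %d (%s), final score %d\n",
              x$dpa_category, x$color, x$final_score),
      sprintf("  points: CH/Fb %d, SFA %d, sodium %d | protein %d%s, fiber %d\n",
              x$chfb_points, x$sfa_points, x$sodium_points, x$protein_points,
              if (x$protein_excluded) " (excluded)" else "", x$fiber_points),
      sprintf("  Points A = %d, Points B = %d\n", x$points_a, x$points_b),
      sep = "")
  invisible(x)
}

#' Score a table of diet records
#'
#' Vectorised scoring of a cohort: takes a data frame with the
#' [nutrient_day()] columns (one row per subject or person-day), derives
#' the scoring quantities row-wise and appends the full score breakdown.
#'
#' @param records A data frame with columns `carbohydrate_g`, `fiber_g`,
#'   `fat_g`, `sfa_g`, `protein_g`, `sodium_mg`, `body_weight_kg` and
#'   optionally `alcohol_g`, `sugars_g`, `energy_kcal`, `lactating`.
#' @param cutoffs Cut-off tables.
#' @return The input tibble plus derived-quantity columns (`energy_kcal`,
#'   `chfb_ratio`, `sfa_pct_energy`, `fat_pct_energy`, `ch_pct_energy`,
#'   `protein_pct_energy`, `pbw_ratio`, `fch_ratio`) and the score columns
#'   of [score_profile()].
#' @export
score_cohort <- function(records, cutoffs = default_cutoffs()) {
  records <- tibble::as_tibble(records)
  need <- c("carbohydrate_g", "fiber_g", "fat_g", "sfa_g", "protein_g",
            "sodium_mg", "body_weight_kg")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop_validation("records are missing columns: %s",
                    paste(missing_cols, collapse = ", "))
  }
  if (!"alcohol_g" %in% names(records)) records$alcohol_g <- 0
  if (!"lactating" %in% names(records)) records$lactating <- FALSE
  if (!"energy_kcal" %in% names(records)) records$energy_kcal <- NA_real_
  dq <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    day <- nutrient_day(carbohydrate_g = r$carbohydrate_g, fiber_g = r$fiber_g,
                        fat_g = r$fat_g, sfa_g = r$sfa_g,
                        protein_g = r$protein_g, sodium_mg = r$sodium_mg,
                        body_weight_kg = r$body_weight_kg,
                        alcohol_g = r$alcohol_g, energy_kcal = r$energy_kcal,
                        lactating = isTRUE(r$lactating))
    unlist(derive_quantities(day))
  })
  dq <- tibble::as_tibble(do.call(rbind, dq))
  scores <- score_profile(dq$chfb_ratio, dq$sfa_pct_energy, records$sodium_mg,
                          dq$pbw_ratio, records$fiber_g, cutoffs)
  dplyr::bind_cols(records[setdiff(names(records), "energy_kcal")], dq, scores)
}
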