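#' Build a structured dietary-advice plan from a score breakdown
#'
#' Implements the three-tier output logic. Category 3 (orange) diets are of
#' such low quality that neither the macronutrient-balance check nor the
#' food-group comparison is run; the plan flags the items driving the bad
#' score and emits `IMPROVE_HABITS` plus one code per flagged item (e.g.
#' `EXCESS_SODIUM`, `LOW_FIBER`). Categories 1-2 run the balance check
#' (required) and, when food-group data are available, the food-group
#' comparison: category 2 plans carry `ADJUST_DIET`, category 1 plans
#' `MAINTAIN` when everything fits (balanced and no group deviations) or
#' `MAINTAIN_QUALITY` otherwise; an unbalanced "U" label adds
#' `WATCH_MACRO_DISTRIBUTION` and each group deviation adds a
#' `DEFICIT_*`/`EXCESS_*` code.
#'
#' Flagging thresholds operationalise "weak aspects of the diet": an
#' unhealthy item is flagged at `unhealthy_min` points or more and a
#' healthy item at `healthy_max` points or fewer.
#'
#' @param breakdown A `dpa_breakdown` from [score_day()], or a one-row
#'   tibble from [score_profile()].
#' @param bmdp A one-row result of [classify_bmdp()]; required for
#'   categories 1-2, forbidden for category 3.
#' @param deviations Optional result of [compare_to_reference()]; only
#'   allowed for categories 1-2 (food-group data are not always collected,
#'   so it may be omitted there).
#' @param unhealthy_min Points at/above which an unhealthy item is flagged
#'   (default 3).
#' @param healthy_max Points at/below which a healthy item is flagged
#'   (default 2).
#' @return A list of class `advice_plan` with `dpa_category`, `color`,
#'   `checks_run`, `flagged_items` (tibble: item, points, concern),
#'   `bmdp_label`, `group_deviations`, `advice_codes`.
#' @export
#' @examples
#' bd <- score_day(nutrient_day_from_targets(8, 8, 1500, 0.83, 30))
#' build_plan(bd, bmdp = classify_bmdp(0.5))
build_plan <- function(breakdown, bmdp = NULL, deviations = NULL,
                       unhealthy_min = 3, healthy_max = 2) {
  bd <- if (inherits(breakdown, "dpa_breakdown")) breakdown else as.list(breakdown)
  category <- bd$dpa_category
  if (category == 3) {
    if (!is.null(bmdp) || !is.null(deviations)) {
      stop("macronutrient-balance or food-group results supplied for a category-3 diet: these checks are not run at the lowest quality tier")
    }
  } else if (is.null(bmdp)) {
    stop("categories 1-2 require the macronutrient-balance result (bmdp)")
  }

  item_points <- c(chfb = bd$chfb_points, sfa = bd$sfa_points,
                   sodium = bd$sodium_points, protein = bd$protein_points,
                   fiber = bd$fiber_points)
  concern_codes <- c(chfb = "EXCESS_LOW_FIBER_CARBS", sfa = "EXCESS_SFA",
                     sodium = "EXCESS_SODIUM", protein = "SUBOPTIMAL_PROTEIN",
                     fiber = "LOW_FIBER")
  unhealthy <- c("chfb", "sfa", "sodium")
  flagged <- c(unhealthy[item_points[unhealthy] >= unhealthy_min],
               c("protein", "fiber")[item_points[c("protein", "fiber")] <= healthy_max])
  flagged_items <- tibble::tibble(
    item = flagged,
    points = as.integer(item_points[flagged]),
    concern = unname(concern_codes[flagged])
  )

  group_codes <- character(0)
  if (!is.null(deviations)) {
    dev <- deviations[deviations$status != "fit", , drop = FALSE]
    if (nrow(dev)) {
      group_codes <- paste0(toupper(dev$status), "_",
                            gsub("[^A-Za-z]+", "_", toupper(dev$group)))
    }
  }

  if (category == 3) {
    checks <- character(0)
    codes <- c("IMPROVE_HABITS", flagged_items$concern)
    bmdp_label <- NULL
    group_dev <- NULL
  } else {
    checks <- c("BMDP", if (!is.null(deviations)) "food_groups")
    bmdp_label <- bmdp$label[1]
    group_dev <- deviations
    unbalanced <- identical(bmdp_label, "U")
    all_fit <- !unbalanced && (is.null(deviations) || length(group_codes) == 0)
    head_code <- if (category == 2) "ADJUST_DIET"
                 else if (all_fit) "MAINTAIN" else "MAINTAIN_QUALITY"
    codes <- c(head_code,
               if (unbalanced) "WATCH_MACRO_DISTRIBUTION",
               group_codes)
  }

  structure(list(dpa_category = category,
                 color = bd$color,
                 checks_run = checks,
                 flagged_items = flagged_items,
                 bmdp_label = bmdp_label,
                 group_deviations = group_dev,
                 advice_codes = unique(codes)),
            class = "advice_plan")
}

#' @export
print.advice_plan <- function(x, ...) {
  cat(sprintf("<advice_plan> category %d (%s)\n", x$dpa_category, x$color),
      sprintf("  checks run: %s\n",
              if (length(x$checks_run)) paste(x$checks_run, collapse = ", ") else "none"),
      sprintf("  codes: %s\n", paste(x$advice_codes, collapse = ", ")),
      sep = "")
  invisible(x)
}
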