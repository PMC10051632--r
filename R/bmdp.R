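#' Classify macronutrient balance from the fat/carbohydrate energy ratio
#'
#' The balance check divides the percent of energy from total fat by the
#' percent from available carbohydrate (F/CH). Ratios inside the closed
#' interval \[0.33, 0.77\] -- the envelope of the EFSA adequate-intake
#' ranges of 20-35%E fat and 45-60%E carbohydrate -- are labelled "B"
#' (balanced); anything outside is "U" (unbalanced).
#'
#' @param fch_ratio Fat%E / carbohydrate%E ratio(s), >= 0.
#' @param cutoffs Cut-off list carrying the `bmdp` bounds (default
#'   [default_cutoffs()], i.e. 0.33 and 0.77).
#' @return A tibble with columns `fch_ratio`, `label` ("B"/"U"),
#'   `lower_bound`, `upper_bound`.
#' @export
#' @examples
#' classify_bmdp(c(0.33, 0.5, 0.77, 1.30))$label  # "B" "B" "B" "U"
classify_bmdp <- function(fch_ratio, cutoffs = default_cutoffs()) {
  if (any(is.na(fch_ratio)) || any(fch_ratio < 0)) {
    stop_validation("fch_ratio must be >= 0")
  }
  lo <- cutoffs$bmdp$lower
  hi <- cutoffs$bmdp$upper
  tibble::tibble(
    fch_ratio = fch_ratio,
    label = ifelse(fch_ratio >= lo & fch_ratio <= hi, "B", "U"),
    lower_bound = lo,
    upper_bound = hi
  )
}

#' Derive balance bounds from percent-energy adequacy ranges
#'
#' The lower bound is the least fat share over the greatest carbohydrate
#' share and the upper bound the greatest fat share over the least
#' carbohydrate share, each truncated (not rounded) to 2 decimals so the
#' EFSA defaults of 20-35%E fat and 45-60%E carbohydrate reproduce the
#' published 0.33-0.77 interval exactly (35/45 = 0.777...).
#'
#' @param fat_range Length-2 numeric, %E range for fat (default `c(20, 35)`).
#' @param ch_range Length-2 numeric, %E range for carbohydrate (default
#'   `c(45, 60)`).
#' @return Named numeric `c(lower = ..., upper = ...)`.
#' @export
#' @examples
#' bounds_from_energy_ranges()  # c(lower = 0.33, upper = 0.77)
bounds_from_energy_ranges <- function(fat_range = c(20, 35),
                                      ch_range = c(45, 60)) {
  if (length(fat_range) != 2 || length(ch_range) != 2 ||
      any(fat_range <= 0) || any(diff(fat_range) < 0) ||
      any(diff(ch_range) < 0)) {
    stop_validation("fat_range and ch_range must be positive ordered pairs")
  }
  if (any(ch_range <= 0)) stop_validation("carbohydrate range bounds must be > 0")
  trunc2 <- function(x) floor(x * 100 + 1e-9) / 100
  c(lower = trunc2(fat_range[1] / ch_range[2]),
    upper = trunc2(fat_range[2] / ch_range[1]))
}
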