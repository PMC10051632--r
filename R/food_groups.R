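#' The twelve food groups
#'
#' The EFSA food-group partition used by common dietary software, plus
#' three extra groups, as applied here: beverages cover every drink other
#' than water and milk; miscellaneous covers agglutinated precooked
#' products, appetizers, sauces and dietetic products.
#'
#' @return Character vector of the 12 canonical group names.
#' @export
food_groups <- function() {
  c("cereals", "fats and oils", "milk and dairy products",
    "sugars, sweets and pastries", "beverages", "meat and meat products",
    "fruits and nuts", "eggs", "fish", "legumes", "vegetables",
    "miscellaneous")
}

entry_energy <- function(entries) {
  kcal <- rep(NA_real_, nrow(entries))
  if ("energy_kcal_100g" %in% names(entries)) {
    kcal <- entries$grams / 100 * entries$energy_kcal_100g
  }
  macro_cols <- c("fat_g_100g", "protein_g_100g", "carbohydrate_g_100g")
  if (anyNA(kcal) && all(macro_cols %in% names(entries))) {
    col0 <- function(col) {
      x <- if (col %in% names(entries)) entries[[col]] else rep(0, nrow(entries))
      ifelse(is.na(x), 0, x)
    }
    atw <- entries$grams / 100 *
      (9 * entries$fat_g_100g + 4 * entries$protein_g_100g +
         4 * entries$carbohydrate_g_100g + 2 * col0("fiber_g_100g") +
         7 * col0("alcohol_g_100g"))
    kcal[is.na(kcal)] <- atw[is.na(kcal)]
  }
  if (anyNA(kcal) || any(kcal < 0)) {
    stop_validation(
      "food entries need nonnegative 'energy_kcal_100g' or per-100 g macros (%s)",
      paste(macro_cols, collapse = ", "))
  }
  kcal
}

#' Food-group energy-share profile from itemised entries
#'
#' Sums the energy of each entry (grams times per-100 g energy, with
#' Atwater reconstruction when only macros are given) within its tagged
#' food group and expresses each group as a percent of total energy.
#'
#' @param entries A data frame with columns `group` (one of
#'   [food_groups()]), `grams`, and either `energy_kcal_100g` or the
#'   per-100 g macro columns `fat_g_100g`, `protein_g_100g`,
#'   `carbohydrate_g_100g` (optionally `fiber_g_100g`, `alcohol_g_100g`).
#' @return A tibble of class `food_group_profile` with one row per
#'   canonical group: `group`, `pct_energy`. Groups with no entries get 0.
#' @export
profile_from_entries <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (!all(c("group", "grams") %in% names(entries))) {
    stop_validation("food entries need 'group' and 'grams' columns")
  }
  groups <- food_groups()
  bad <- setdiff(unique(entries$group), groups)
  if (length(bad)) {
    stop_validation("unknown food group(s): %s. Valid groups: %s",
                    paste(bad, collapse = "; "), paste(groups, collapse = "; "))
  }
  check_nonneg(entries$grams, "grams")
  kcal <- entry_energy(entries)
  total <- sum(kcal)
  if (total <= 0) stop_validation("total energy of the entries is zero")
  by_group <- tapply(kcal, factor(entries$group, levels = groups), sum,
                     default = 0)
  out <- tibble::tibble(group = groups,
                        pct_energy = 100 * as.numeric(by_group) / total)
  class(out) <- c("food_group_profile", class(out))
  out
}

#' Build a reference food-group pattern by averaging menu profiles
#'
#' The reference pattern is the arithmetic per-group mean of the supplied
#' menu profiles (e.g. profiles of exemplary Mediterranean-style daily
#' menus) with a symmetric tolerance band in percent-energy points.
#'
#' @param profiles A list of `food_group_profile` objects (at least one).
#' @param tolerance Half-width of the per-group acceptance band, in %E
#'   points (default 3).
#' @return A tibble of class `reference_pattern` with columns `group`,
#'   `pct_energy`, `tolerance`.
#' @export
build_reference <- function(profiles, tolerance = 3) {
  if (length(profiles) < 1) stop_validation("need at least one menu profile")
  if (tolerance <= 0) stop_validation("tolerance must be > 0")
  groups <- food_groups()
  mat <- vapply(profiles, function(p) {
    if (!all(groups %in% p$group)) stop_validation("profile is missing groups")
    p$pct_energy[match(groups, p$group)]
  }, numeric(length(groups)))
  out <- tibble::tibble(group = groups,
                        pct_energy = rowMeans(as.matrix(mat)),
                        tolerance = tolerance)
  class(out) <- c("reference_pattern", class(out))
  out
}

#' Compare a food-group profile to a reference pattern
#'
#' Flags each group as `deficit` (observed below reference minus
#' tolerance), `excess` (above reference plus tolerance) or `fit`.
#'
#' @param profile A `food_group_profile` (from [profile_from_entries()]).
#' @param reference A `reference_pattern` (from [build_reference()] or
#'   [read_reference()]).
#' @return A tibble with columns `group`, `observed`, `reference`,
#'   `tolerance`, `status`.
#' @export
compare_to_reference <- function(profile, reference) {
  groups <- food_groups()
  if (!all(groups %in% profile$group)) {
    stop_validation("profile is missing groups: %s",
                    paste(setdiff(groups, profile$group), collapse = "; "))
  }
  if (!all(groups %in% reference$group)) {
    stop_validation("reference is missing groups: %s",
                    paste(setdiff(groups, reference$group), collapse = "; "))
  }
  obs <- profile$pct_energy[match(groups, profile$group)]
  ref <- reference$pct_energy[match(groups, reference$group)]
  tol <- reference$tolerance[match(groups, reference$group)]
  status <- ifelse(obs < ref - tol, "deficit",
                   ifelse(obs > ref + tol, "excess", "fit"))
  tibble::tibble(group = groups, observed = obs, reference = ref,
                 tolerance = tol, status = status)
}

#' Aggregate itemised food entries into a daily nutrient record
#'
#' Sums grams times per-100 g nutrient contents over all entries of a day
#' and returns the corresponding [nutrient_day()], ready for scoring.
#' Used to score whole menus.
#'
#' @param entries Food entries with per-100 g columns `carbohydrate_g_100g`,
#'   `fiber_g_100g`, `fat_g_100g`, `sfa_g_100g`, `protein_g_100g`,
#'   `sodium_mg_100g` and optionally `alcohol_g_100g`.
#' @param body_weight_kg Body weight of the consumer (kg), needed for the
#'   protein/body-weight item. Default 65, a reference adult.
#' @param lactating Lactation flag passed through to the record.
#' @return A [nutrient_day()].
#' @export
entries_to_nutrient_day <- function(entries, body_weight_kg = 65,
                                    lactating = FALSE) {
  entries <- tibble::as_tibble(entries)
  need <- c("grams", "carbohydrate_g_100g", "fiber_g_100g", "fat_g_100g",
            "sfa_g_100g", "protein_g_100g", "sodium_mg_100g")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols)) {
    stop_validation("food entries are missing columns: %s",
                    paste(missing_cols, collapse = ", "))
  }
  tot <- function(col) sum(entries$grams / 100 * entries[[col]])
  alcohol <- if ("alcohol_g_100g" %in% names(entries)) tot("alcohol_g_100g") else 0
  nutrient_day(carbohydrate_g = tot("carbohydrate_g_100g"),
               fiber_g = tot("fiber_g_100g"),
               fat_g = tot("fat_g_100g"),
               sfa_g = tot("sfa_g_100g"),
               protein_g = tot("protein_g_100g"),
               sodium_mg = tot("sodium_mg_100g"),
               alcohol_g = alcohol,
               body_weight_kg = body_weight_kg,
               lactating = lactating)
}

#' Read / write a reference pattern as YAML
#'
#' The YAML schema is a mapping `groups: {<group name>: <pct energy>}`
#' plus a scalar `tolerance` (in %E points).
#'
#' @param path YAML file path.
#' @return For `read_reference`, a `reference_pattern` tibble.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop_validation("reference file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$groups)) stop_validation("reference YAML needs a 'groups' mapping")
  groups <- food_groups()
  missing_groups <- setdiff(groups, names(raw$groups))
  if (length(missing_groups)) {
    stop_validation("reference is missing groups: %s",
                    paste(missing_groups, collapse = "; "))
  }
  tol <- if (is.null(raw$tolerance)) 3 else as.numeric(raw$tolerance)
  if (tol <= 0) stop_validation("tolerance must be > 0")
  out <- tibble::tibble(group = groups,
                        pct_energy = as.numeric(unlist(raw$groups[groups])),
                        tolerance = tol)
  class(out) <- c("reference_pattern", class(out))
  out
}

#' @rdname read_reference
#' @param reference A `reference_pattern` tibble.
#' @export
write_reference <- function(reference, path) {
  groups <- as.list(stats::setNames(reference$pct_energy, reference$group))
  yaml::write_yaml(list(groups = groups,
                        tolerance = reference$tolerance[1]), path)
  invisible(path)
}
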