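record_columns <- c("carbohydrate_g", "fiber_g", "fat_g", "sfa_g",
                    "protein_g", "sodium_mg", "body_weight_kg")
optional_columns <- c("id", "alcohol_g", "sugars_g", "energy_kcal",
                      "lactating", "bmi", "height_m", "archetype",
                      "leptin_month1", "leptin_month2", "leptin_month3")

#' Read diet records from CSV or JSON
#'
#' Reads one row per person-day (or person-average): the [nutrient_day()]
#' columns plus any optional covariates (`id`, `bmi`, `leptin_month<k>`,
#' ...). Column names are matched case-insensitively; a `mapping` can
#' rename foreign headers (e.g. from a food-composition export) to the
#' canonical names. Every row is validated and errors name the offending
#' row and field. CSV is UTF-8 and comma-separated with a header;
#' `decimal_comma = TRUE` accepts the Spanish-locale dialect (`;`
#' separator, `,` decimal mark).
#'
#' @param path File path.
#' @param format "auto" (by extension), "csv" or "json".
#' @param mapping Optional named character vector `c(canonical = "foreign")`
#'   renaming input columns.
#' @param decimal_comma CSV uses `;` separators and decimal commas.
#' @return A validated tibble of records.
#' @export
read_records <- function(path, format = c("auto", "csv", "json"),
                         mapping = NULL, decimal_comma = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file '%s' does not exist", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else if (decimal_comma) {
    tibble::as_tibble(utils::read.csv2(path, check.names = FALSE))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  names(df) <- tolower(names(df))
  if (!is.null(mapping)) {
    for (canonical in names(mapping)) {
      foreign <- tolower(mapping[[canonical]])
      if (foreign %in% names(df)) {
        names(df)[names(df) == foreign] <- tolower(canonical)
      }
    }
  }
  missing_cols <- setdiff(record_columns, names(df))
  if (length(missing_cols)) {
    stop_validation("missing required column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  if ("lactating" %in% names(df)) {
    df$lactating <- as.logical(df$lactating)
  }
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    ok <- tryCatch({
      nutrient_day(carbohydrate_g = row$carbohydrate_g, fiber_g = row$fiber_g,
                   fat_g = row$fat_g, sfa_g = row$sfa_g,
                   protein_g = row$protein_g, sodium_mg = row$sodium_mg,
                   body_weight_kg = row$body_weight_kg,
                   alcohol_g = if ("alcohol_g" %in% names(df)) row$alcohol_g else 0,
                   sugars_g = if ("sugars_g" %in% names(df)) row$sugars_g else NA_real_,
                   energy_kcal = if ("energy_kcal" %in% names(df)) row$energy_kcal else NA_real_,
                   lactating = if ("lactating" %in% names(df)) isTRUE(row$lactating) else FALSE)
      TRUE
    }, dietprofiler_validation_error = function(e) e)
    if (!isTRUE(ok)) {
      stop_validation("row %d: %s", i, conditionMessage(ok))
    }
  }
  df
}

#' Read itemised food entries from CSV or JSON
#'
#' Entries carry a food name, one of the 12 food groups, the consumed
#' grams and a per-100 g nutrient vector (see [profile_from_entries()]).
#'
#' @inheritParams read_records
#' @return A tibble of food entries.
#' @export
read_food_entries <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file '%s' does not exist", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  names(df) <- tolower(names(df))
  if (!all(c("group", "grams") %in% names(df))) {
    stop_validation("food entries need 'group' and 'grams' columns")
  }
  df
}

#' Score records and assemble the full per-subject report
#'
#' Runs the complete pipeline on a table of diet records: score breakdown
#' for everyone; the macronutrient-balance check and (when a reference
#' pattern and food-group share columns are available) the food-group
#' comparison for categories 1-2 only; and the structured advice plan.
#'
#' @param records A tibble of diet records (see [read_records()]).
#' @param cutoffs Cut-off tables.
#' @param reference Optional `reference_pattern` for the food-group
#'   comparison; used only for subjects with `fg_<group>` columns.
#' @return A list of class `dpa_report` with elements `subjects` (a list
#'   of per-subject results: id, breakdown, bmdp, deviations, advice) and
#'   `scored` (the scored tibble).
#' @export
dpa_report <- function(records, cutoffs = default_cutoffs(), reference = NULL) {
  scored <- if (nrow(tibble::as_tibble(records)) > 0) {
    score_cohort(records, cutoffs)
  } else {
    tibble::tibble()
  }
  fg_cols <- paste0("fg_", gsub("[^a-z]+", "_", food_groups()))
  has_fg <- all(fg_cols %in% names(scored))
  subjects <- lapply(seq_len(nrow(scored)), function(i) {
    r <- scored[i, ]
    bd <- as.list(r[, c("chfb_points", "sfa_points", "sodium_points",
                        "protein_points", "fiber_points", "points_a",
                        "points_b", "protein_excluded", "final_score",
                        "dpa_category", "color")])
    if (bd$dpa_category < 3) {
      bmdp <- classify_bmdp(r$fch_ratio, cutoffs)
      deviations <- if (!is.null(reference) && has_fg) {
        prof <- tibble::tibble(group = food_groups(),
                               pct_energy = as.numeric(r[, fg_cols]))
        compare_to_reference(prof, reference)
      }
    } else {
      bmdp <- NULL
      deviations <- NULL
    }
    advice <- build_plan(bd, bmdp = bmdp, deviations = deviations)
    list(id = if ("id" %in% names(r)) r$id else paste0("row", i),
         breakdown = bd,
         bmdp = if (!is.null(bmdp)) as.list(bmdp[1, ]),
         deviations = deviations,
         advice = list(checks_run = advice$checks_run,
                       advice_codes = advice$advice_codes,
                       flagged_items = advice$flagged_items))
  })
  structure(list(subjects = subjects, scored = scored), class = "dpa_report")
}

#' Write a scoring report to JSON
#'
#' Serialises a [dpa_report()] (or any list) to pretty-printed JSON with
#' stable key order, so identical inputs produce byte-identical reports.
#'
#' @param report A `dpa_report` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(subjects = lapply(report$subjects, function(s) {
    list(id = s$id,
         breakdown = s$breakdown,
         bmdp = s$bmdp,
         deviations = if (!is.null(s$deviations)) {
           lapply(seq_len(nrow(s$deviations)), function(i) as.list(s$deviations[i, ]))
         },
         advice = list(checks_run = as.list(s$advice$checks_run),
                       advice_codes = as.list(s$advice$advice_codes),
                       flagged_items = lapply(
                         seq_len(nrow(s$advice$flagged_items)),
                         function(i) as.list(s$advice$flagged_items[i, ]))))
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a JSON scoring report
#'
#' @param path Path written by [write_report()].
#' @return The report structure as a list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
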