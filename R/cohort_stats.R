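#' Per-category cohort summary (mean +/- SEM)
#'
#' Summarises a scored cohort by diet-quality category: group size and
#' mean with standard error of the mean (SEM = SD / sqrt(n)) for every
#' item's points, energy, percent-energy macronutrient shares, the
#' fat/carbohydrate energy ratio and (when present) BMI.
#'
#' @param scored A scored cohort, as returned by [score_cohort()].
#' @param vars Variables to summarise; defaults to the score, energy and
#'   anthropometry columns present in `scored`.
#' @return A tibble with one row per (category, variable): `dpa_category`,
#'   `variable`, `n`, `mean`, `sem`.
#' @export
summarize_by_dpa <- function(scored, vars = NULL) {
  if (!"dpa_category" %in% names(scored)) {
    stop_validation("cohort must be scored first (missing 'dpa_category')")
  }
  if (is.null(vars)) {
    vars <- intersect(c("chfb_points", "sfa_points", "sodium_points",
                        "protein_points", "fiber_points", "final_score",
                        "energy_kcal", "fat_pct_energy", "ch_pct_energy",
                        "protein_pct_energy", "sfa_pct_energy", "fch_ratio",
                        "bmi"), names(scored))
  }
  scored |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable",
                        values_to = "value") |>
    dplyr::group_by(.data$dpa_category, .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop")
}

# Compact letter display: groups sharing a letter are not significantly
# different. Maximal "non-significant" cliques found by subset enumeration
# (fine for the handful of categories compared here).
letter_grouping <- function(means, pmat, alpha) {
  k <- length(means)
  if (k > 12) stop("letter grouping supports at most 12 groups")
  if (k == 1) return(stats::setNames("a", names(means)))
  nsd <- pmat > alpha | is.na(pmat) # non-significant (or same group)
  diag(nsd) <- TRUE
  subsets <- list()
  for (size in k:1) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      if (all(nsd[idx, idx])) {
        covered <- any(vapply(subsets, function(s) all(idx %in% s), logical(1)))
        if (!covered) subsets <- c(subsets, list(idx))
      }
    }
  }
  # order cliques by the mean of their best-ranked member for stable letters
  ord <- order(vapply(subsets, function(s) min(rank(-means)[s]), numeric(1)))
  subsets <- subsets[ord]
  letters_out <- stats::setNames(rep("", k), names(means))
  for (j in seq_along(subsets)) {
    letters_out[subsets[[j]]] <- paste0(letters_out[subsets[[j]]], letters[j])
  }
  letters_out
}

#' Compare a variable across diet-quality groups (ANOVA + LSD letters)
#'
#' Runs the classical workflow for comparing group means: a Levene
#' pretest of variance homogeneity (alpha 0.05; on rejection the values
#' are natural-log transformed, shifted by `1 - min(x)` first if any value
#' is non-positive), one-way ANOVA, and unprotected pairwise least
#' significant difference (LSD) comparisons using the pooled ANOVA error,
#' summarised as a compact letter display: groups sharing a letter do not
#' differ at `alpha`. No multiplicity correction is applied across
#' variables.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (e.g. the diet category), same length.
#' @param alpha Significance level (default 0.05).
#' @return A list with `anova_f`, `anova_p`, `log_transformed`,
#'   `levene_p`, `pairwise` (tibble: group1, group2, diff, p) and
#'   `letters` (named character).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("excluding group(s) with n < 2: %s",
                    paste(small, collapse = ", ")))
    keep <- !(g %in% small)
    values <- values[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop_validation("need at least 2 groups with n >= 2")

  log_transformed <- FALSE
  levene_p <- NA_real_
  if (stats::var(values) > 0) {
    levene_p <- car::leveneTest(values ~ g)[["Pr(>F)"]][1]
    if (!is.na(levene_p) && levene_p < alpha) {
      offset <- if (min(values) <= 0) 1 - min(values) else 0
      values <- log(values + offset)
      log_transformed <- TRUE
    }
  }

  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    d <- means[pr[1]] - means[pr[2]]
    se <- sqrt(mse * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    p <- if (se > 0) 2 * stats::pt(-abs(d / se), df) else as.numeric(d != 0)
    tibble::tibble(group1 = pr[1], group2 = pr[2], diff = unname(d),
                   p = unname(p))
  })
  pw <- dplyr::bind_rows(pw)
  pmat <- matrix(NA_real_, nlevels(g), nlevels(g),
                 dimnames = list(levels(g), levels(g)))
  for (i in seq_len(nrow(pw))) {
    pmat[pw$group1[i], pw$group2[i]] <- pw$p[i]
    pmat[pw$group2[i], pw$group1[i]] <- pw$p[i]
  }

  list(anova_f = an["g", "F value"],
       anova_p = an["g", "Pr(>F)"],
       log_transformed = log_transformed,
       levene_p = levene_p,
       pairwise = pw,
       letters = letter_grouping(means, pmat, alpha))
}

#' Student's t-test between two diet-quality groups
#'
#' Convenience wrapper for single comparisons between two categories of a
#' scored cohort (classical two-sample t-test, pooled variance).
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector; exactly two levels after dropping `NA`s.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_pair <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (nlevels(g) != 2) stop_validation("compare_pair needs exactly 2 groups")
  stats::t.test(values ~ g, var.equal = TRUE)
}

#' BMI-milk-leptin rank correlation stratified by category and month
#'
#' For every diet-quality category and lactation month computes Spearman's
#' rank correlation between BMI and the milk leptin concentration of that
#' month, with its two-sided p-value. Strata with fewer than 3 complete
#' pairs are reported with `NA` statistics.
#'
#' @param scored A scored cohort with columns `bmi`, `dpa_category` and
#'   `leptin_month1`, `leptin_month2`, ... columns.
#' @return A tibble: `dpa_category`, `month`, `n`, `rho`, `p`.
#' @export
stratified_spearman <- function(scored) {
  lep_cols <- grep("^leptin_month[0-9]+$", names(scored), value = TRUE)
  if (!length(lep_cols)) stop_validation("no leptin_month<k> columns found")
  if (!all(c("bmi", "dpa_category") %in% names(scored))) {
    stop_validation("cohort needs 'bmi' and 'dpa_category' columns")
  }
  long <- tidyr::pivot_longer(
    scored[, c("bmi", "dpa_category", lep_cols)],
    dplyr::all_of(lep_cols),
    names_to = "month", names_pattern = "leptin_month([0-9]+)",
    names_transform = list(month = as.integer),
    values_to = "leptin")
  long |>
    dplyr::group_by(.data$dpa_category, .data$month) |>
    dplyr::group_modify(function(d, key) {
      ok <- stats::complete.cases(d$bmi, d$leptin)
      if (sum(ok) < 3) {
        return(tibble::tibble(n = sum(ok), rho = NA_real_, p = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(d$bmi[ok], d$leptin[ok],
                                             method = "spearman",
                                             exact = FALSE))
      tibble::tibble(n = sum(ok), rho = unname(ct$estimate), p = ct$p.value)
    }) |>
    dplyr::ungroup()
}
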