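#' Default scoring cut-off tables
#'
#' Returns the point cut-offs used by the diet scorer. Each of the four
#' "banded" items (carbohydrate/fiber ratio, saturated fat as % energy,
#' sodium in mg/day, fiber in g/day) is described by five ascending break
#' points: a value scores as many points as the number of breaks it strictly
#' exceeds, so values at or below the first break score 0 and values above
#' the last break score 5. The printed anchors are the first and last break
#' (e.g. sodium: 0 points at <= 2000 mg, 5 points at > 3200 mg); the
#' intermediate breaks are evenly spaced between them, which is the
#' minimal-assumption interpolation between the published end cut-offs.
#'
#' Protein is scored on the protein/body-weight ratio (g/kg/day) with a
#' bespoke non-monotone table: the EFSA population reference intake of
#' 0.83 g/kg/day scores the full 5 points, intakes below the 0.6 average
#' requirement score 0, intermediate deficits score 2, and scores decline
#' again above the optimum down to 0 beyond 1.8.
#'
#' The balanced-macronutrient bounds (fat%E / carbohydrate%E classified
#' "B" inside \[0.33, 0.77\]) live in the same table so one config file
#' controls every threshold.
#'
#' @return A list with elements `chfb`, `sfa`, `sodium`, `fiber` (each a
#'   list with a numeric `breaks` vector), `protein` (a data frame of
#'   intervals with columns `min`, `max`, `min_closed`, `max_closed`,
#'   `points`) and `bmdp` (list with `lower`, `upper`).
#' @seealso [read_cutoffs()] to load a modified table from YAML.
#' @export
#' @examples
#' ct <- default_cutoffs()
#' ct$sodium$breaks
default_cutoffs <- function() {
  protein <- data.frame(
    min        = c(0,    0.6,  0.83, 1.0,  1.2,  1.4,  1.6,  1.8),
    max        = c(0.6,  0.83, 1.0,  1.2,  1.4,  1.6,  1.8,  Inf),
    min_closed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    max_closed = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    points     = c(0L,   2L,   5L,   4L,   3L,   2L,   1L,   0L)
  )
  list(
    chfb    = list(breaks = c(10, 12, 14, 16, 18)),
    sfa     = list(breaks = c(10, 12, 14, 16, 18)),
    sodium  = list(breaks = c(2000, 2300, 2600, 2900, 3200)),
    fiber   = list(breaks = c(5, 10, 15, 20, 25)),
    protein = protein,
    bmdp    = list(lower = 0.33, upper = 0.77)
  )
}

validate_cutoffs <- function(ct) {
  for (item in c("chfb", "sfa", "sodium", "fiber")) {
    br <- ct[[item]]$breaks
    if (is.null(br) || length(br) != 5 || any(diff(br) <= 0)) {
      stop_validation("cut-offs for '%s' must be 5 strictly increasing breaks", item)
    }
  }
  pr <- ct$protein
  need <- c("min", "max", "min_closed", "max_closed", "points")
  if (!all(need %in% names(pr))) {
    stop_validation("protein cut-off table must have columns %s",
                    paste(need, collapse = ", "))
  }
  if (any(pr$points < 0 | pr$points > 5)) {
    stop_validation("protein points must be in 0..5")
  }
  # intervals must tile [0, Inf) in order
  if (pr$min[1] != 0 || !is.infinite(pr$max[nrow(pr)])) {
    stop_validation("protein intervals must cover [0, Inf)")
  }
  if (nrow(pr) > 1 && any(pr$min[-1] != pr$max[-nrow(pr)])) {
    stop_validation("protein intervals must be contiguous")
  }
  if (is.null(ct$bmdp$lower) || is.null(ct$bmdp$upper) ||
      ct$bmdp$lower < 0 || ct$bmdp$upper < ct$bmdp$lower) {
    stop_validation("bmdp bounds must satisfy 0 <= lower <= upper")
  }
  invisible(ct)
}

#' Read scoring cut-offs from a YAML file
#'
#' The file mirrors the structure of [default_cutoffs()]; any item omitted
#' from the file keeps its default. Unknown top-level keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated cut-off list.
#' @export
read_cutoffs <- function(path) {
  if (!file.exists(path)) stop_validation("cut-off file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  ct <- default_cutoffs()
  unknown <- setdiff(names(raw), names(ct))
  if (length(unknown)) {
    stop_validation("unknown cut-off keys: %s", paste(unknown, collapse = ", "))
  }
  for (item in c("chfb", "sfa", "sodium", "fiber")) {
    if (!is.null(raw[[item]]$breaks)) ct[[item]]$breaks <- as.numeric(raw[[item]]$breaks)
  }
  if (!is.null(raw$protein)) {
    pr <- do.call(rbind, lapply(raw$protein, function(row) {
      data.frame(min = as.numeric(row$min),
                 max = if (identical(row$max, ".inf") || is.null(row$max)) Inf else as.numeric(row$max),
                 min_closed = isTRUE(row$min_closed),
                 max_closed = isTRUE(row$max_closed),
                 points = as.integer(row$points))
    }))
    ct$protein <- pr
  }
  if (!is.null(raw$bmdp)) {
    if (!is.null(raw$bmdp$lower)) ct$bmdp$lower <- as.numeric(raw$bmdp$lower)
    if (!is.null(raw$bmdp$upper)) ct$bmdp$upper <- as.numeric(raw$bmdp$upper)
  }
  validate_cutoffs(ct)
}

#' Write scoring cut-offs to a YAML file
#'
#' @param cutoffs A cut-off list as returned by [default_cutoffs()].
#' @param path Destination YAML path.
#' @return `path`, invisibly.
#' @export
write_cutoffs <- function(cutoffs, path) {
  validate_cutoffs(cutoffs)
  out <- list(
    chfb = list(breaks = cutoffs$chfb$breaks),
    sfa = list(breaks = cutoffs$sfa$breaks),
    sodium = list(breaks = cutoffs$sodium$breaks),
    fiber = list(breaks = cutoffs$fiber$breaks),
    protein = lapply(seq_len(nrow(cutoffs$protein)), function(i) {
      row <- cutoffs$protein[i, ]
      list(min = row$min, max = if (is.infinite(row$max)) ".inf" else row$max,
           min_closed = row$min_closed, max_closed = row$max_closed,
           points = row$points)
    }),
    bmdp = cutoffs$bmdp
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
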