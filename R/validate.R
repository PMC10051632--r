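#' @importFrom rlang abort
NULL

# Validation failures get their own condition class so the CLI can map them
# to exit code 2 while internal errors stay at 1.
stop_validation <- function(msg, ...) {
  rlang::abort(message = sprintf(msg, ...), class = "dietprofiler_validation_error")
}

check_nonneg <- function(x, field) {
  if (any(!is.finite(x) & !is.infinite(x)) || any(is.na(x))) {
    stop_validation("field '%s' must be numeric and non-missing", field)
  }
  if (any(x < 0)) {
    stop_validation("field '%s' must be >= 0 (got %s)", field,
                    paste(signif(x[x < 0], 6), collapse = ", "))
  }
  invisible(x)
}

check_positive <- function(x, field) {
  check_nonneg(x, field)
  if (any(x <= 0)) stop_validation("field '%s' must be > 0", field)
  invisible(x)
}

check_prob_range <- function(x, field, lo = 0, hi = 100) {
  if (any(is.na(x)) || any(x < lo) || any(x > hi)) {
    stop_validation("field '%s' must lie in [%s, %s]", field, lo, hi)
  }
  invisible(x)
}
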