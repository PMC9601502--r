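# Condition helpers: every user-facing error carries a ddq_error class so
# pipelines can distinguish bad inputs from saturated wells and sparse data.

abort_invalid <- function(message, ...) {
  abort(message, class = c("ddq_error_invalid", "ddq_error"), ...)
}

abort_saturated <- function(message, ...) {
  abort(message, class = c("ddq_error_saturated", "ddq_error"), ...)
}

abort_insufficient <- function(message, ...) {
  abort(message, class = c("ddq_error_insufficient", "ddq_error"), ...)
}

abort_schema <- function(message, ...) {
  abort(message, class = c("ddq_error_schema", "ddq_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_invalid(sprintf("`%s` must be numeric and non-missing.", name))
  }
  ok_lower <- if (allow_zero_lower) x >= lower else x > lower
  if (!all(ok_lower & x <= upper)) {
    abort_invalid(sprintf("`%s` must lie in %s%g, %g].", name,
                          if (allow_zero_lower) "[" else "(", lower, upper))
  }
  invisible(x)
}

check_columns <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_schema(sprintf("%s is missing required column(s): %s.",
                         where, paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(data)
}

# Run `expr` under a fixed RNG state when `seed` is given, untouched otherwise.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
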