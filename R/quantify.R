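#' Mass ratio of adulterant to reference meat from a copy-number ratio
#'
#' The core quantification identity: for single-copy nuclear targets the
#' copy density per unit mass of each species is a protocol constant, so the
#' mass ratio of target meat to reference (beef) meat is
#' `M_T / M_B = K * Q_T / Q_B`, where `Q_T`, `Q_B` are the measured
#' copies/uL of the target and reference assays and `K` is the calibrated
#' transfer coefficient (see [estimate_k()]).
#'
#' @param q_target Target-assay concentration (copies/uL), non-negative.
#' @param q_reference Reference-assay concentration (copies/uL), strictly
#'   positive: a sample with no reference signal is not a beef-background
#'   mixture and cannot be quantified this way.
#' @param k Transfer coefficient: a positive number, or an object from
#'   [estimate_k()] / [read_k_config()].
#' @return The dimensionless mass ratio `M_T / M_B`, zero when
#'   `q_target = 0`.
#' @export
mass_ratio <- function(q_target, q_reference, k) {
  k <- as_k(k)
  check_number(q_target, "q_target", lower = 0)
  check_number(k, "k", lower = 0, allow_zero_lower = FALSE)
  if (!is.numeric(q_reference) || anyNA(q_reference)) {
    abort_invalid("`q_reference` must be numeric and non-missing.")
  }
  if (any(q_reference <= 0)) {
    abort(
      "Reference assay concentration is zero: the sample has no detectable beef background, so a target/beef mass ratio is undefined.",
      class = c("ddq_error_reference_absent", "ddq_error"))
  }
  k * q_target / q_reference
}

#' Convert a mass ratio to a mass fraction of total meat
#'
#' Under the binary-mixture assumption (the sample is target meat plus
#' reference meat and nothing else), a mass ratio `r = M_T / M_B` maps to
#' the adulterant's share of total meat mass, `100 * r / (1 + r)` percent.
#'
#' @param ratio Mass ratio `M_T / M_B`, non-negative.
#' @return Mass fraction in percent, in `[0, 100)`.
#' @seealso [mass_fraction_to_ratio()] for the inverse.
#' @export
mass_fraction <- function(ratio) {
  check_number(ratio, "ratio", lower = 0)
  100 * ratio / (1 + ratio)
}

#' @rdname mass_fraction
#' @param fraction_pct Mass fraction in percent, in `[0, 100)`.
#' @export
mass_fraction_to_ratio <- function(fraction_pct) {
  check_number(fraction_pct, "fraction_pct", lower = 0, upper = 100)
  if (any(fraction_pct >= 100)) {
    abort_invalid("A 100% fraction has no finite target/reference ratio.")
  }
  fraction_pct / (100 - fraction_pct)
}

#' Signed relative deviation of a measured value from the known value
#'
#' @param measured_pct Measured mass fraction in percent.
#' @param actual_pct Known (gravimetric or declared) mass fraction in
#'   percent, strictly positive; against a true zero the relative deviation
#'   is undefined and the absolute difference should be reported instead.
#' @param digits Decimal places for the reported value (default 2, matching
#'   assay reporting convention); use `Inf` for full precision.
#' @return `100 * (measured - actual) / actual`, in percent.
#' @export
deviation <- function(measured_pct, actual_pct, digits = 2) {
  check_number(measured_pct, "measured_pct", lower = 0)
  if (!is.numeric(actual_pct) || anyNA(actual_pct) || any(actual_pct <= 0)) {
    abort(
      "`actual_pct` must be > 0: relative deviation against a zero reference is undefined; report the absolute difference instead.",
      class = c("ddq_error_zero_reference", "ddq_error"))
  }
  out <- 100 * (measured_pct - actual_pct) / actual_pct
  if (is.finite(digits)) round(out, digits) else out
}

#' Mean absolute deviation of a set of signed deviations
#'
#' @param deviations_pct Numeric vector of signed percent deviations.
#' @inheritParams deviation
#' @return Arithmetic mean of the absolute values, in percent.
#' @export
mean_abs_deviation <- function(deviations_pct, digits = 2) {
  if (length(deviations_pct) == 0) {
    abort_insufficient("Need at least one deviation to average.")
  }
  if (!is.numeric(deviations_pct) || anyNA(deviations_pct)) {
    abort_invalid("`deviations_pct` must be numeric and non-missing.")
  }
  out <- mean(abs(deviations_pct))
  if (is.finite(digits)) round(out, digits) else out
}

#' Quantify adulterant mass fractions for a table of samples
#'
#' Applies [mass_ratio()] and [mass_fraction()] row-wise and, where a
#' declared composition is supplied, computes the signed relative deviation
#' and an adulteration flag.
#'
#' @param data A data frame with columns `q_target` and `q_reference`
#'   (copies/uL); optional `sample_id` and `declared_pct` (the label claim
#'   in percent; `NA` means the label declares no content).
#' @inheritParams mass_ratio
#' @param tolerance Adulteration tolerance in percentage points: a sample is
#'   flagged when its measured fraction exceeds the declared one by more
#'   than this (default 5).
#' @return A tibble: the input plus `mass_ratio`, `mass_fraction_pct`, and —
#'   when `declared_pct` is present — `deviation_pct` (vs a positive
#'   declared value) and logical `adulterated`.
#' @export
quantify_samples <- function(data, k, tolerance = 5) {
  check_columns(data, c("q_target", "q_reference"), "sample table")
  k <- as_k(k)
  out <- tibble::as_tibble(data)
  out$mass_ratio <- mass_ratio(out$q_target, out$q_reference, k)
  out$mass_fraction_pct <- mass_fraction(out$mass_ratio)
  if ("declared_pct" %in% names(out)) {
    pos <- !is.na(out$declared_pct) & out$declared_pct > 0
    out$deviation_pct <- NA_real_
    out$deviation_pct[pos] <-
      deviation(out$mass_fraction_pct[pos], out$declared_pct[pos])
    out$adulterated <- !is.na(out$declared_pct) &
      (out$mass_fraction_pct - out$declared_pct) > tolerance
  }
  out
}

#' Screen products against their declared composition
#'
#' Compares measured adulterant fractions with label claims and classifies
#' each product: `"consistent"` when the measurement is compatible with the
#' label, `"flagged"` when the measured fraction exceeds the declared one by
#' more than `tolerance` percentage points (including any detection against
#' a declared zero above tolerance), and `"LC"` when the label lacks a
#' defined content, in which case the measurement is reported but no
#' consistency verdict is possible.
#'
#' @param data A data frame with columns `measured_pct` and `declared_pct`
#'   (percent; `NA` declared = no defined content on the label). Identifier
#'   columns such as `sample_id` and `species` are carried through.
#' @param tolerance Percentage-point excess over the declared value that
#'   triggers a flag (default 5, a conservative allowance for assay
#'   variability).
#' @return A tibble: the input plus `excess_pct` (measured minus declared)
#'   and `status` (`"consistent"`, `"flagged"` or `"LC"`).
#' @export
screen_products <- function(data, tolerance = 5) {
  check_columns(data, c("measured_pct", "declared_pct"), "product table")
  check_number(tolerance, "tolerance", lower = 0)
  out <- tibble::as_tibble(data)
  lc <- is.na(out$declared_pct)
  out$excess_pct <- out$measured_pct - out$declared_pct
  out$status <- dplyr::case_when(
    lc ~ "LC",
    out$excess_pct > tolerance ~ "flagged",
    .default = "consistent"
  )
  out
}
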