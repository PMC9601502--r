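#' Copies per droplet from droplet counts
#'
#' In droplet digital PCR a reaction is partitioned into roughly 20,000
#' nanoliter droplets and each droplet is read as positive or negative at end
#' point. Under Poisson occupancy the fraction of negative droplets is
#' `exp(-lambda)`, so the mean copy number per droplet is recovered as
#' `lambda = -log(1 - P/N)` from `P` positive droplets out of `N` accepted.
#'
#' @param positives Number of positive droplets (`P`), one value per well.
#'   May be fractional for expected-value simulations.
#' @param accepted Number of accepted droplets (`N`), recycled against
#'   `positives`.
#' @return Numeric vector of copies per droplet (CPD), zero when `P = 0`.
#'   A saturated well (`P = N`) is an error of class `ddq_error_saturated`
#'   because the rate is unbounded there; batch wrappers should catch it and
#'   flag the well instead.
#' @seealso [cpd_to_concentration()], [estimate_concentrations()]
#' @examples
#' estimate_cpd(1000, 20000)
#' @export
estimate_cpd <- function(positives, accepted) {
  if (!is.numeric(positives) || !is.numeric(accepted) ||
      anyNA(positives) || anyNA(accepted)) {
    abort_invalid("`positives` and `accepted` must be numeric and non-missing.")
  }
  n <- pmax(length(positives), length(accepted))
  positives <- rep_len(positives, n)
  accepted <- rep_len(accepted, n)
  if (any(accepted <= 0)) {
    abort_invalid("`accepted` must be positive: a well with no accepted droplets carries no information.")
  }
  if (any(positives < 0) || any(positives > accepted)) {
    abort_invalid("`positives` must satisfy 0 <= positives <= accepted.")
  }
  if (any(positives == accepted)) {
    abort_saturated(
      "Saturated partition (all droplets positive): copies per droplet is unbounded. Dilute the sample or flag the well.")
  }
  -log1p(-positives / accepted)
}

#' Convert copies per droplet to copies per microliter
#'
#' One droplet of volume `v` nanoliters holds `v * 1e-3` microliters, so a
#' rate of `lambda` copies per droplet corresponds to `lambda / (v * 1e-3)`
#' copies per microliter of reaction. The droplet volume is an instrument
#' constant; only concentration *ratios* enter the downstream mass-fraction
#' arithmetic, so its exact value cancels there.
#'
#' @param cpd Copies per droplet, non-negative.
#' @param droplet_volume_nl Droplet volume in nanoliters; default 0.85 nL,
#'   the conventional partition volume of the instrument class that emits
#'   ~20,000 droplets per 20 uL reaction.
#' @return Copies per microliter, linear in `cpd`.
#' @export
cpd_to_concentration <- function(cpd, droplet_volume_nl = 0.85) {
  check_number(cpd, "cpd", lower = 0)
  check_number(droplet_volume_nl, "droplet_volume_nl", lower = 0,
               allow_zero_lower = FALSE)
  cpd / (droplet_volume_nl * 1e-3)
}

#' @rdname cpd_to_concentration
#' @param copies_per_ul Concentration in copies per microliter.
#' @export
concentration_to_cpd <- function(copies_per_ul, droplet_volume_nl = 0.85) {
  check_number(copies_per_ul, "copies_per_ul", lower = 0)
  check_number(droplet_volume_nl, "droplet_volume_nl", lower = 0,
               allow_zero_lower = FALSE)
  copies_per_ul * droplet_volume_nl * 1e-3
}

#' Confidence interval for the concentration of one well
#'
#' A normal-approximation binomial interval on the positive fraction `P/N`,
#' transformed through the Poisson link `-log(1 - p)` and scaled by droplet
#' volume. This is a per-well reporting aid; replicate spread remains the
#' primary uncertainty measure for assay results.
#'
#' @inheritParams estimate_cpd
#' @inheritParams cpd_to_concentration
#' @param conf Coverage probability, default 0.95.
#' @return A tibble with columns `ci_low` and `ci_high` (copies/uL),
#'   containing the point estimate; the lower bound is clamped at zero.
#' @export
concentration_interval <- function(positives, accepted,
                                   droplet_volume_nl = 0.85, conf = 0.95) {
  check_number(conf, "conf", lower = 0, upper = 1, allow_zero_lower = FALSE)
  cpd <- estimate_cpd(positives, accepted) # validates P, N
  n <- pmax(length(positives), length(accepted))
  p_hat <- rep_len(positives, n) / rep_len(accepted, n)
  acc <- rep_len(accepted, n)
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(p_hat * (1 - p_hat) / acc)
  p_lo <- pmax(p_hat - z * se, 0)
  # keep the upper bound strictly below 1 so the log link stays finite
  p_hi <- pmin(p_hat + z * se, (acc - 0.5) / acc)
  tibble::tibble(
    ci_low = cpd_to_concentration(-log1p(-p_lo), droplet_volume_nl),
    ci_high = cpd_to_concentration(-log1p(-p_hi), droplet_volume_nl)
  )
}

#' Estimate concentrations for a table of wells
#'
#' Batch front end to the Poisson estimator: takes a tidy table of droplet
#' counts (one row per well) and appends copies per droplet, copies per
#' microliter and a confidence interval. Saturated wells (`P = N`) and wells
#' failing the accepted-droplet QC are flagged, not dropped and not fatal.
#'
#' @param data A data frame with numeric columns `positives` and `accepted`;
#'   all other columns (sample, well and assay identifiers) are carried
#'   through unchanged.
#' @inheritParams concentration_interval
#' @param qc_min_droplets Minimum accepted droplets for a well to pass QC
#'   (default 10,000).
#' @return A tibble: the input plus `cpd`, `copies_per_ul`, `ci_low`,
#'   `ci_high`, `saturated` and `qc_pass`. Saturated wells carry `NA`
#'   estimates.
#' @examples
#' wells <- tibble::tibble(well_id = c("A01", "A02"),
#'                         positives = c(0, 1000), accepted = 20000)
#' estimate_concentrations(wells)
#' @export
estimate_concentrations <- function(data, droplet_volume_nl = 0.85,
                                    conf = 0.95, qc_min_droplets = 10000) {
  check_columns(data, c("positives", "accepted"), "droplet table")
  data <- tibble::as_tibble(data)
  if (!is.numeric(data$positives) || !is.numeric(data$accepted)) {
    abort_schema("`positives` and `accepted` must be numeric columns.")
  }
  saturated <- data$positives == data$accepted & data$accepted > 0
  out <- data
  out$cpd <- NA_real_
  out$copies_per_ul <- NA_real_
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  ok <- !saturated
  if (any(ok)) {
    cpd <- estimate_cpd(data$positives[ok], data$accepted[ok])
    ci <- concentration_interval(data$positives[ok], data$accepted[ok],
                                 droplet_volume_nl, conf)
    out$cpd[ok] <- cpd
    out$copies_per_ul[ok] <- cpd_to_concentration(cpd, droplet_volume_nl)
    out$ci_low[ok] <- ci$ci_low
    out$ci_high[ok] <- ci$ci_high
  }
  out$saturated <- saturated
  out$qc_pass <- data$accepted >= qc_min_droplets
  out
}
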