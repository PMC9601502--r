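#' Transfer coefficient for a single calibration mixture
#'
#' For a gravimetric binary mixture with known adulterant mass fraction `w`
#' (percent w/w), the transfer coefficient follows from the quantification
#' identity `M_T/M_B = K * Q_T/Q_B` rearranged as
#' `K = (w / (100 - w)) * mean(Q_B) / mean(Q_T)`. Replicates are aggregated
#' by the arithmetic mean of copies/uL *before* taking the ratio (ratio of
#' means, not mean of ratios), and the result is rounded to `digits`
#' decimals — the convention under which replicate tables reproduce their
#' printed per-mixture K values.
#'
#' @param mass_fraction_pct True adulterant mass fraction of the mixture in
#'   percent, strictly inside (0, 100).
#' @param target_conc Replicate copies/uL of the adulterant (target) assay.
#' @param reference_conc Replicate copies/uL of the beef (reference) assay.
#' @param digits Rounding applied to the reported K (default 2); `Inf`
#'   disables rounding.
#' @return A single positive K value.
#' @seealso [estimate_k()] for pooling several mixtures.
#' @examples
#' k_for_mixture(10, c(29.7, 31, 30.3, 31, 32.2, 31.7),
#'               c(332, 350, 345, 344, 355, 361))
#' @export
k_for_mixture <- function(mass_fraction_pct, target_conc, reference_conc,
                          digits = 2) {
  check_number(mass_fraction_pct, "mass_fraction_pct", lower = 0, upper = 100,
               allow_zero_lower = FALSE)
  if (mass_fraction_pct >= 100) {
    abort_invalid("`mass_fraction_pct` must be strictly below 100 for a binary mixture.")
  }
  if (length(target_conc) == 0 || length(reference_conc) == 0) {
    abort_insufficient("Both assays need at least one replicate concentration.")
  }
  check_number(target_conc, "target_conc", lower = 0, allow_zero_lower = FALSE)
  check_number(reference_conc, "reference_conc", lower = 0,
               allow_zero_lower = FALSE)
  k <- (mass_fraction_pct / (100 - mass_fraction_pct)) *
    mean(reference_conc) / mean(target_conc)
  if (is.finite(digits)) round(k, digits) else k
}

#' Estimate a pooled transfer coefficient from a calibration series
#'
#' Pools per-mixture K values over a series of gravimetric mixtures (e.g.
#' 10/30/50/70/90% w/w) into a single species-pair constant. Per-mixture K
#' values are rounded to `digits` decimals *before* the pooled mean and RSD
#' are computed; unrounded values are retained alongside. A stable K across
#' the series is what licenses using one constant for unknown samples.
#'
#' @param data A data frame with one row per replicate measurement and
#'   columns `mass_fraction_pct` (true adulterant percent of the mixture),
#'   `assay` (`"target"` or `"reference"`) and `copies_per_ul`. An optional
#'   `mixture` column labels mixtures; by default each distinct
#'   `mass_fraction_pct` is one mixture.
#' @param species_pair Length-2 character vector naming the pair, e.g.
#'   `c(target = "pork", reference = "beef")`; metadata only.
#' @inheritParams k_for_mixture
#' @return An object of class `transfer_coefficient` with components
#'   `per_mixture` (tibble: mixture, mass fraction, replicate counts, mean
#'   concentrations, `k_raw`, `k`), `k_mean` (mean of the rounded per-mixture
#'   values), `k` (the working constant, `k_mean` rounded to `digits`),
#'   `k_rsd_pct` (sample RSD of the rounded values, in percent) and
#'   `species_pair`. Has [tidy()], [glance()], [autoplot()] and `print`
#'   methods.
#' @examples
#' cal <- ddpcr_example("calibration")
#' estimate_k(dplyr::filter(cal, species == "pork"),
#'            species_pair = c(target = "pork", reference = "beef"))
#' @export
estimate_k <- function(data,
                       species_pair = c(target = "target", reference = "beef"),
                       digits = 2) {
  check_columns(data, c("mass_fraction_pct", "assay", "copies_per_ul"),
                "calibration table")
  if (!all(data$assay %in% c("target", "reference"))) {
    abort_schema("`assay` must contain only \"target\" and \"reference\".")
  }
  data <- tibble::as_tibble(data)
  if (!"mixture" %in% names(data)) {
    data$mixture <- paste0(format(data$mass_fraction_pct, trim = TRUE), "%")
  }

  per_mixture <- data |>
    dplyr::summarise(
      q_mean = mean(.data$copies_per_ul),
      n = dplyr::n(),
      .by = c("mixture", "mass_fraction_pct", "assay")
    ) |>
    tidyr::pivot_wider(names_from = "assay",
                       values_from = c("q_mean", "n")) |>
    dplyr::arrange(.data$mass_fraction_pct)
  if (!all(c("q_mean_target", "q_mean_reference") %in% names(per_mixture)) ||
      anyNA(per_mixture$q_mean_target) || anyNA(per_mixture$q_mean_reference)) {
    abort_schema("Every mixture needs replicates for both the target and the reference assay.")
  }
  if (nrow(per_mixture) < 2) {
    abort_insufficient("Need at least two calibration mixtures to pool K and compute an RSD.")
  }

  per_mixture <- per_mixture |>
    dplyr::mutate(
      k_raw = purrr::pmap_dbl(
        list(.data$mass_fraction_pct, .data$q_mean_target,
             .data$q_mean_reference),
        function(w, qt, qr) {
          k_for_mixture(w, qt, qr, digits = Inf)
        }),
      k = if (is.finite(digits)) round(.data$k_raw, digits) else .data$k_raw
    )

  k_mean <- mean(per_mixture$k)
  structure(
    list(
      species_pair = species_pair,
      per_mixture = per_mixture,
      k_mean = k_mean,
      k = if (is.finite(digits)) round(k_mean, digits) else k_mean,
      k_mean_raw = mean(per_mixture$k_raw),
      k_rsd_pct = 100 * sd(per_mixture$k) / k_mean,
      digits = digits
    ),
    class = "transfer_coefficient"
  )
}

#' Extract a numeric transfer coefficient
#'
#' Accepts a bare number, a [estimate_k()] result or a configuration read by
#' [read_k_config()], and returns the working K constant.
#'
#' @param k A number, `transfer_coefficient` or `k_config` object.
#' @return A single positive numeric K.
#' @export
as_k <- function(k) {
  if (inherits(k, "transfer_coefficient") || inherits(k, "k_config")) {
    k <- k$k
  }
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k <= 0) {
    abort_invalid("`k` must be a single positive number (or an object carrying one).")
  }
  as.numeric(k)
}

#' @export
print.transfer_coefficient <- function(x, ...) {
  cat(sprintf("Transfer coefficient: %s / %s\n",
              x$species_pair[["target"]], x$species_pair[["reference"]]))
  cat(sprintf("  K = %.*f (mean of %d per-mixture values, RSD %.2f%%)\n",
              max(x$digits, 2, na.rm = TRUE), x$k,
              nrow(x$per_mixture), x$k_rsd_pct))
  print(x$per_mixture, ...)
  invisible(x)
}

#' @describeIn estimate_k Per-mixture K values as a tibble.
#' @param x A `transfer_coefficient` object.
#' @param ... Unused.
#' @method tidy transfer_coefficient
#' @export
tidy.transfer_coefficient <- function(x, ...) {
  x$per_mixture
}

#' @describeIn estimate_k One-row summary: `k`, `k_mean`, `k_rsd_pct`,
#'   number of mixtures and the pair labels.
#' @method glance transfer_coefficient
#' @export
glance.transfer_coefficient <- function(x, ...) {
  tibble::tibble(
    target = x$species_pair[["target"]],
    reference = x$species_pair[["reference"]],
    k = x$k,
    k_mean = x$k_mean,
    k_mean_raw = x$k_mean_raw,
    k_rsd_pct = x$k_rsd_pct,
    n_mixtures = nrow(x$per_mixture)
  )
}

#' @describeIn estimate_k Per-mixture K values against the mixture mass
#'   fraction, with the pooled constant as a horizontal line.
#' @param object A `transfer_coefficient` object.
#' @method autoplot transfer_coefficient
#' @export
autoplot.transfer_coefficient <- function(object, ...) {
  ggplot2::ggplot(object$per_mixture,
                  ggplot2::aes(x = .data$mass_fraction_pct, y = .data$k)) +
    ggplot2::geom_hline(yintercept = object$k, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Adulterant mass fraction of calibration mixture (% w/w)",
      y = "Transfer coefficient K",
      title = sprintf("%s/%s: K = %.2f (RSD %.2f%%)",
                      object$species_pair[["target"]],
                      object$species_pair[["reference"]],
                      object$k, object$k_rsd_pct)
    ) +
    ggplot2::theme_minimal()
}

#' Verify a calibrated transfer coefficient on mixtures of known composition
#'
#' Quantifies check mixtures with the calibrated K and compares the results
#' with the true gravimetric fractions. `data` may carry either measured
#' mass fractions directly (`measured_pct`) or replicate concentrations
#' (`assay` + `copies_per_ul` per `actual_pct`, as for [estimate_k()]), in
#' which case the measured fraction is computed through [mass_ratio()] and
#' [mass_fraction()] on the replicate-mean concentrations.
#'
#' @param data A data frame with column `actual_pct` plus either
#'   `measured_pct` or (`assay`, `copies_per_ul`).
#' @inheritParams mass_ratio
#' @return A tibble of class `k_verification` with columns `actual_pct`,
#'   `measured_pct` and `deviation_pct` (signed relative deviation in
#'   percent); [glance()] gives the min/max/mean absolute deviation summary.
#' @export
verify_k <- function(data, k) {
  check_columns(data, "actual_pct", "verification table")
  k <- as_k(k)
  if ("measured_pct" %in% names(data)) {
    out <- tibble::as_tibble(data)
  } else {
    check_columns(data, c("assay", "copies_per_ul"), "verification table")
    out <- tibble::as_tibble(data) |>
      dplyr::summarise(q = mean(.data$copies_per_ul),
                       .by = c("actual_pct", "assay")) |>
      tidyr::pivot_wider(names_from = "assay", values_from = "q") |>
      dplyr::mutate(
        measured_pct = mass_fraction(
          mass_ratio(.data$target, .data$reference, k))) |>
      dplyr::select("actual_pct", "measured_pct")
  }
  out$deviation_pct <- deviation(out$measured_pct, out$actual_pct)
  structure(dplyr::arrange(out, .data$actual_pct),
            k = k, class = c("k_verification", class(out)))
}

#' @describeIn verify_k Deviation summary: min, max and mean of the absolute
#'   deviations, plus the K used.
#' @param x A `k_verification` tibble.
#' @param ... Unused.
#' @method glance k_verification
#' @export
glance.k_verification <- function(x, ...) {
  dev <- abs(x$deviation_pct)
  tibble::tibble(
    k = attr(x, "k"),
    n_mixtures = nrow(x),
    min_abs_deviation_pct = min(dev),
    max_abs_deviation_pct = max(dev),
    mean_abs_deviation_pct = mean_abs_deviation(x$deviation_pct)
  )
}
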