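#' Simulation configuration for binary meat mixtures
#'
#' Fixes the generative model used by every simulator in the package. A
#' mixture with adulterant mass fraction `w` (percent) contributes
#' `w/100 * c_target` copies/uL to the target assay and
#' `(1 - w/100) * c_reference` copies/uL to the reference assay, both scaled
#' by a common `degradation_factor` (thermal copy loss) and jittered by
#' multiplicative lognormal replicate noise (pipetting/extraction error,
#' whose spread scales with magnitude as replicate tables show).
#' Concentration becomes copies per droplet through the droplet volume, and
#' each well's positive count is Binomial(`n`, `1 - exp(-lambda)`).
#'
#' The default anchors (`c_target = 300` copies/uL per unit mass fraction,
#' `k_true = 1.19`) give a pork-like series: a 10% mixture yields about 30
#' target and 320 reference copies/uL, the magnitude seen in real
#' calibration runs. A chicken-like series uses
#' `sim_config(c_target = 2300, k_true = 0.38)`.
#'
#' @param c_target Copies/uL contributed per unit mass fraction of target
#'   meat (latent copy density `C_T`).
#' @param k_true True transfer coefficient `C_B / C_T`; used to derive
#'   `c_reference` when that is not given.
#' @param c_reference Copies/uL per unit mass fraction of reference meat
#'   (latent `C_B`); defaults to `k_true * c_target`.
#' @param droplets_per_well Accepted droplets per well (default 20,000).
#' @param droplet_volume_nl Droplet volume in nanoliters (default 0.85).
#' @param replicate_cv Coefficient of variation of the lognormal replicate
#'   noise (default 0.05, i.e. 5%); 0 disables noise.
#' @param degradation_factor Multiplicative copy retention in (0, 1]
#'   applied equally to both channels (default 1 = untreated);
#'   `degradation_factor_reference` may override the reference channel to
#'   emulate differential thermal loss.
#' @param degradation_factor_reference Optional channel-specific retention
#'   for the reference assay; defaults to `degradation_factor`.
#' @param sampling `"binomial"` draws the positive count stochastically;
#'   `"expected"` sets it to its (fractional) expectation, turning the
#'   pipeline into a deterministic oracle.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(c_target = 300, k_true = 1.19,
                       c_reference = k_true * c_target,
                       droplets_per_well = 20000,
                       droplet_volume_nl = 0.85,
                       replicate_cv = 0.05,
                       degradation_factor = 1,
                       degradation_factor_reference = degradation_factor,
                       sampling = c("binomial", "expected")) {
  sampling <- match.arg(sampling)
  check_number(c_target, "c_target", lower = 0, allow_zero_lower = FALSE)
  check_number(c_reference, "c_reference", lower = 0, allow_zero_lower = FALSE)
  check_number(droplets_per_well, "droplets_per_well", lower = 0,
               allow_zero_lower = FALSE)
  check_number(droplet_volume_nl, "droplet_volume_nl", lower = 0,
               allow_zero_lower = FALSE)
  check_number(replicate_cv, "replicate_cv", lower = 0)
  check_number(degradation_factor, "degradation_factor", lower = 0, upper = 1,
               allow_zero_lower = FALSE)
  check_number(degradation_factor_reference, "degradation_factor_reference",
               lower = 0, upper = 1, allow_zero_lower = FALSE)
  structure(
    list(
      c_target = c_target,
      c_reference = c_reference,
      k_true = c_reference / c_target,
      droplets_per_well = droplets_per_well,
      droplet_volume_nl = droplet_volume_nl,
      replicate_cv = replicate_cv,
      degradation_factor = degradation_factor,
      degradation_factor_reference = degradation_factor_reference,
      sampling = sampling
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ddPCR simulation config\n")
  cat(sprintf("  C_T = %g, C_B = %g copies/uL per unit mass fraction (K = %.4g)\n",
              x$c_target, x$c_reference, x$k_true))
  cat(sprintf("  %g droplets/well of %g nL, replicate CV %g%%, retention %g/%g, %s sampling\n",
              x$droplets_per_well, x$droplet_volume_nl, 100 * x$replicate_cv,
              x$degradation_factor, x$degradation_factor_reference, x$sampling))
  invisible(x)
}

# Multiplicative lognormal noise with unit mean and the configured CV.
replicate_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one droplet partition at a known rate
#'
#' Draws the positive-droplet count of a well whose true copies-per-droplet
#' rate is `lambda`: each of `n_droplets` droplets is occupied with
#' probability `1 - exp(-lambda)` independently, so
#' `positives ~ Binomial(n_droplets, 1 - exp(-lambda))`. With
#' `sampling = "expected"` the count is set to its (possibly fractional)
#' expectation, which makes [estimate_cpd()] recover `lambda` exactly.
#'
#' @param lambda True copies per droplet, non-negative; vectorized (one well
#'   per element).
#' @param n_droplets Accepted droplets per well.
#' @param seed Optional integer seed for a reproducible draw; `NULL` uses
#'   the current RNG stream.
#' @param sampling `"binomial"` (default) or `"expected"`.
#' @return A tibble with one row per well: `lambda_true`, `positives`,
#'   `accepted`.
#' @export
simulate_partition <- function(lambda, n_droplets = 20000, seed = NULL,
                               sampling = c("binomial", "expected")) {
  sampling <- match.arg(sampling)
  check_number(lambda, "lambda", lower = 0)
  check_number(n_droplets, "n_droplets", lower = 0, allow_zero_lower = FALSE)
  p_occ <- -expm1(-lambda)
  positives <- with_optional_seed(seed, {
    if (sampling == "binomial") {
      rbinom(length(lambda), size = n_droplets, prob = p_occ)
    } else {
      n_droplets * p_occ
    }
  })
  tibble::tibble(
    lambda_true = lambda,
    positives = as.numeric(positives),
    accepted = rep_len(as.numeric(n_droplets), length(lambda))
  )
}

# Expected copies/uL of one channel before partition sampling.
channel_concentration <- function(w_pct, config, assay) {
  if (assay == "target") {
    (w_pct / 100) * config$c_target * config$degradation_factor
  } else {
    (1 - w_pct / 100) * config$c_reference * config$degradation_factor_reference
  }
}

#' Simulate one assay well of a binary mixture
#'
#' @param w_pct True adulterant mass fraction in percent, in `[0, 100]`.
#' @param config A [sim_config()] object.
#' @param assay `"target"` (adulterant channel) or `"reference"` (beef
#'   channel).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `mass_fraction_pct`, `assay`, `conc_true`
#'   (the noise-jittered copies/uL the well was generated at),
#'   `lambda_true`, `positives`, `accepted`.
#' @export
simulate_mixture_well <- function(w_pct, config = sim_config(),
                                  assay = c("target", "reference"),
                                  seed = NULL) {
  assay <- match.arg(assay)
  check_number(w_pct, "w_pct", lower = 0, upper = 100)
  stopifnot(inherits(config, "sim_config"))
  with_optional_seed(seed, {
    conc <- channel_concentration(w_pct, config, assay) *
      replicate_noise(1, config$replicate_cv)
    lambda <- concentration_to_cpd(conc, config$droplet_volume_nl)
    part <- simulate_partition(lambda, config$droplets_per_well,
                               sampling = config$sampling)
    tibble::tibble(
      mass_fraction_pct = w_pct,
      assay = assay,
      conc_true = conc,
      lambda_true = part$lambda_true,
      positives = part$positives,
      accepted = part$accepted
    )
  })
}

#' Simulate a calibration series of gravimetric mixtures
#'
#' Generates the full two-channel replicate design used for transfer
#' coefficient estimation: for each mixture level and replicate, one target
#' and one reference well are simulated and run through the Poisson
#' estimator. The output feeds [estimate_k()] directly.
#'
#' @param levels_pct True adulterant mass fractions in percent, each inside
#'   (0, 100); default the 10/30/50/70/90 calibration design.
#' @param replicates Wells per level and channel (default 6).
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed covering the whole series.
#' @return A tibble with one row per well: `mixture`, `mass_fraction_pct`,
#'   `replicate`, `assay`, `lambda_true`, `positives`, `accepted`, `cpd`,
#'   `copies_per_ul`.
#' @examples
#' sim <- simulate_calibration_series(seed = 1)
#' estimate_k(sim, species_pair = c(target = "pork", reference = "beef"))
#' @export
simulate_calibration_series <- function(levels_pct = c(10, 30, 50, 70, 90),
                                        replicates = 6,
                                        config = sim_config(),
                                        seed = NULL) {
  check_number(levels_pct, "levels_pct", lower = 0, upper = 100,
               allow_zero_lower = FALSE)
  if (any(levels_pct >= 100)) {
    abort_invalid("Calibration levels must be strictly inside (0, 100)%.")
  }
  if (replicates < 2) {
    abort_insufficient("Calibration needs at least two replicates per level.")
  }
  stopifnot(inherits(config, "sim_config"))
  with_optional_seed(seed, {
    design <- tidyr::expand_grid(
      mass_fraction_pct = levels_pct,
      replicate = seq_len(replicates),
      assay = c("target", "reference")
    )
    wells <- purrr::pmap(design, function(mass_fraction_pct, replicate, assay) {
      simulate_mixture_well(mass_fraction_pct, config, assay)
    })
    out <- dplyr::bind_cols(
      design[c("mass_fraction_pct", "replicate", "assay")],
      dplyr::bind_rows(wells)[c("lambda_true", "positives", "accepted")]
    )
    out$mixture <- paste0(format(out$mass_fraction_pct, trim = TRUE), "%")
    out$cpd <- estimate_cpd(out$positives, out$accepted)
    out$copies_per_ul <- cpd_to_concentration(out$cpd, config$droplet_volume_nl)
    dplyr::relocate(out, "mixture")
  })
}

#' Simulate a sensitivity dilution series
#'
#' Generates replicate wells at trace mass fractions down to and below the
#' detection limit, where the expected number of target copies per well
#' drops under one and stochastic non-detects appear. Detection follows the
#' positivity rule: at least one positive droplet in the target channel of a
#' well passing the accepted-droplet QC. Detected replicates are quantified
#' with the supplied working `k`; non-detects measure 0.
#'
#' @param levels_pct True mass fractions in percent, `>= 0` (0 is allowed
#'   and yields no target signal).
#' @param replicates Replicates per level (default 3).
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed.
#' @param k Working transfer coefficient used to quantify detected
#'   replicates; defaults to the configured truth rounded to 2 decimals.
#' @param qc_min_droplets Accepted-droplet QC threshold (default 10,000).
#' @return A tibble with one row per replicate: `actual_pct`, `replicate`,
#'   `target_positives`, `detected`, `q_target`, `q_reference`,
#'   `measured_pct`. Summarise per level with [summarise_dilution_series()].
#' @export
simulate_dilution_series <- function(levels_pct = c(0.01, 0.05, 0.1, 0.2,
                                                    0.5, 0.8, 1, 5, 10),
                                     replicates = 3,
                                     config = sim_config(),
                                     seed = NULL,
                                     k = round(config$k_true, 2),
                                     qc_min_droplets = 10000) {
  check_number(levels_pct, "levels_pct", lower = 0, upper = 100)
  if (replicates < 1) abort_insufficient("Need at least one replicate per level.")
  stopifnot(inherits(config, "sim_config"))
  k <- as_k(k)
  with_optional_seed(seed, {
    design <- tidyr::expand_grid(actual_pct = levels_pct,
                                 replicate = seq_len(replicates))
    rows <- purrr::pmap(design, function(actual_pct, replicate) {
      tgt <- simulate_mixture_well(actual_pct, config, "target")
      ref <- simulate_mixture_well(actual_pct, config, "reference")
      detected <- tgt$positives >= 1 & tgt$accepted >= qc_min_droplets
      q_target <- cpd_to_concentration(
        estimate_cpd(tgt$positives, tgt$accepted), config$droplet_volume_nl)
      q_reference <- cpd_to_concentration(
        estimate_cpd(ref$positives, ref$accepted), config$droplet_volume_nl)
      measured <- if (detected && q_reference > 0) {
        mass_fraction(mass_ratio(q_target, q_reference, k))
      } else {
        0
      }
      tibble::tibble(target_positives = tgt$positives, detected = detected,
                     q_target = q_target, q_reference = q_reference,
                     measured_pct = measured)
    })
    dplyr::bind_cols(design, dplyr::bind_rows(rows))
  })
}

#' Summarise a replicate-level dilution series per level
#'
#' Aggregates the output of [simulate_dilution_series()] (or any table with
#' the same replicate-level columns) into the per-level form consumed by
#' [determine_lod()] and [determine_loq()].
#'
#' @param data A data frame with columns `actual_pct`, `detected` and
#'   `measured_pct`, one row per replicate.
#' @return A tibble per level: `actual_pct`, `detections`,
#'   `total_replicates`, `detection_rate_pct`, `mean_measured`,
#'   `sd_measured`, `deviation_pct` (`NA` at a true zero level).
#' @export
summarise_dilution_series <- function(data) {
  check_columns(data, c("actual_pct", "detected", "measured_pct"),
                "dilution series")
  tibble::as_tibble(data) |>
    dplyr::summarise(
      detections = sum(.data$detected),
      total_replicates = dplyr::n(),
      mean_measured = mean(.data$measured_pct),
      sd_measured = sd(.data$measured_pct),
      .by = "actual_pct"
    ) |>
    dplyr::mutate(
      detection_rate_pct = detection_rate(.data$detections,
                                          .data$total_replicates),
      deviation_pct = ifelse(
        .data$actual_pct > 0,
        100 * (.data$mean_measured - .data$actual_pct) / .data$actual_pct,
        NA_real_)
    ) |>
    dplyr::arrange(.data$actual_pct)
}
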