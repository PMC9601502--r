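#' Relative standard deviation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation — the
#' precision measure used throughout assay validation (repeatability,
#' reproducibility, limit of quantification).
#'
#' @param values At least two numeric measurements with non-zero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2) {
    abort_insufficient("RSD needs at least two values.")
  }
  if (!is.numeric(values) || anyNA(values)) {
    abort_invalid("`values` must be numeric and non-missing.")
  }
  m <- mean(values)
  if (m == 0) {
    abort_insufficient("RSD is undefined for measurements with zero mean.")
  }
  100 * sd(values) / m
}

#' Detection rate of a dilution level
#'
#' @param detections Replicates with a positive qualitative result.
#' @param total_replicates Total replicates tested, positive.
#' @return Percent of replicates detected.
#' @export
detection_rate <- function(detections, total_replicates) {
  if (!is.numeric(detections) || !is.numeric(total_replicates) ||
      anyNA(detections) || anyNA(total_replicates)) {
    abort_invalid("`detections` and `total_replicates` must be numeric and non-missing.")
  }
  if (any(total_replicates <= 0)) {
    abort_invalid("`total_replicates` must be positive.")
  }
  if (any(detections < 0) || any(detections > total_replicates)) {
    abort_invalid("`detections` must satisfy 0 <= detections <= total_replicates.")
  }
  100 * detections / total_replicates
}

# Per-level detection rate from whichever columns the series provides.
level_detection_rate <- function(data) {
  if ("detection_rate_pct" %in% names(data)) {
    data$detection_rate_pct
  } else {
    check_columns(data, c("detections", "total_replicates"), "dilution series")
    detection_rate(data$detections, data$total_replicates)
  }
}

# Smallest level whose tail (itself and every higher level) all pass; NA if
# none. `pass` is aligned with `levels` sorted ascending.
lowest_stable_level <- function(levels, pass) {
  ord <- order(levels)
  levels <- levels[ord]
  pass <- pass[ord]
  tail_ok <- rev(cumprod(rev(as.numeric(pass)))) == 1
  if (!any(tail_ok)) NA_real_ else levels[which(tail_ok)[1]]
}

#' Limit of detection of a dilution series
#'
#' The LOD is the lowest adulterant mass fraction at which *all* replicates
#' give a positive qualitative result, with the stability requirement that
#' every higher tested level is also fully detected (a non-monotone series
#' cannot yield a spuriously low LOD).
#'
#' @param data A data frame with one row per dilution level: `actual_pct`
#'   plus either `detection_rate_pct` or (`detections`, `total_replicates`).
#' @return The LOD in percent w/w, or `NA` (with a warning) when no level
#'   is fully detected.
#' @examples
#' determine_lod(dplyr::filter(ddpcr_example("dilution"), species == "pork"))
#' @export
determine_lod <- function(data) {
  check_columns(data, "actual_pct", "dilution series")
  if (nrow(data) < 1) abort_insufficient("Dilution series is empty.")
  rate <- level_detection_rate(data)
  lod <- lowest_stable_level(data$actual_pct, rate >= 100 - 1e-9)
  if (is.na(lod)) {
    warn("No dilution level was detected in all replicates; LOD is undefined.",
         class = "ddq_warning_undefined_limit")
  }
  lod
}

#' Limit of quantification of a dilution series
#'
#' The LOQ is the lowest adulterant mass fraction that is stably *and*
#' reliably quantified: 100% detection rate, replicate RSD at most
#' `max_rsd_pct`, and absolute relative bias at most `max_bias_pct`, with
#' every higher tested level also passing. Precision (RSD) and trueness
#' (bias) are both required — near the detection limit a series can be
#' precise yet biased high by a factor of two, which no analyst would call
#' quantifiable.
#'
#' Per-level RSD is taken from, in order of preference: a `measured` list
#' column of replicate values, an `rsd_pct` column, or
#' `100 * sd_measured / mean_measured`. Per-level bias comes from a
#' `deviation_pct` column or `100 * (mean_measured - actual) / actual`.
#'
#' @inheritParams determine_lod
#' @param max_rsd_pct Precision acceptance threshold in percent (default 25).
#' @param max_bias_pct Trueness acceptance threshold in percent (default 25).
#' @return The LOQ in percent w/w, or `NA` (with a warning) when no level
#'   qualifies. The per-level pass table is attached as attribute `"levels"`.
#' @examples
#' determine_loq(dplyr::filter(ddpcr_example("dilution"), species == "pork"))
#' @export
determine_loq <- function(data, max_rsd_pct = 25, max_bias_pct = 25) {
  check_columns(data, "actual_pct", "dilution series")
  if (nrow(data) < 1) abort_insufficient("Dilution series is empty.")
  rate <- level_detection_rate(data)

  level_rsd <- if ("measured" %in% names(data)) {
    purrr::map_dbl(data$measured, function(v) {
      if (length(v) < 2 || mean(v) == 0) NA_real_ else rsd(v)
    })
  } else if ("rsd_pct" %in% names(data)) {
    data$rsd_pct
  } else {
    check_columns(data, c("mean_measured", "sd_measured"), "dilution series")
    ifelse(data$mean_measured > 0,
           100 * data$sd_measured / data$mean_measured, NA_real_)
  }

  bias <- if ("deviation_pct" %in% names(data)) {
    data$deviation_pct
  } else {
    level_mean <- if ("mean_measured" %in% names(data)) {
      data$mean_measured
    } else {
      check_columns(data, "measured", "dilution series")
      purrr::map_dbl(data$measured, mean)
    }
    100 * (level_mean - data$actual_pct) / data$actual_pct
  }

  pass <- rate >= 100 - 1e-9 &
    !is.na(level_rsd) & level_rsd <= max_rsd_pct &
    !is.na(bias) & abs(bias) <= max_bias_pct
  loq <- lowest_stable_level(data$actual_pct, pass)
  if (is.na(loq)) {
    warn("No dilution level met the precision and trueness criteria; LOQ is undefined.",
         class = "ddq_warning_undefined_limit")
  }
  structure(loq, levels = tibble::tibble(
    actual_pct = data$actual_pct,
    detection_rate_pct = rate,
    rsd_pct = level_rsd,
    bias_pct = bias,
    pass = pass
  ))
}

#' Repeatability and reproducibility of replicate measurements
#'
#' Repeatability is the within-run RSD (replicates measured together);
#' reproducibility is the RSD of run means across independent runs (other
#' day, other operator). Both are judged against the same acceptance
#' threshold.
#'
#' @param data A data frame with one row per replicate measurement and
#'   columns `level_pct` (true mass fraction), `run_id` and `value`
#'   (measured mass fraction in percent).
#' @param max_rsd_pct Acceptance threshold in percent (default 25).
#' @return A list with tibbles `repeatability` (per level and run: n, mean,
#'   `rsd_pct`, `pass`) and `reproducibility` (per level: number of runs,
#'   RSD of run means, `pass`).
#' @export
repeatability_reproducibility <- function(data, max_rsd_pct = 25) {
  check_columns(data, c("level_pct", "run_id", "value"), "replication table")
  data <- tibble::as_tibble(data)

  rep_tbl <- data |>
    dplyr::summarise(n = dplyr::n(),
                     mean_value = mean(.data$value),
                     .by = c("level_pct", "run_id"))
  if (any(rep_tbl$n < 2)) {
    abort_insufficient("Every (level, run) group needs at least two replicates for repeatability.")
  }
  rep_tbl <- data |>
    dplyr::summarise(n = dplyr::n(),
                     mean_value = mean(.data$value),
                     rsd_pct = rsd(.data$value),
                     .by = c("level_pct", "run_id")) |>
    dplyr::mutate(pass = .data$rsd_pct <= max_rsd_pct)

  if (any(table(rep_tbl$level_pct) < 2)) {
    abort_insufficient("Reproducibility needs at least two independent runs per level.")
  }
  repro_tbl <- rep_tbl |>
    dplyr::summarise(n_runs = dplyr::n(),
                     rsd_pct = rsd(.data$mean_value),
                     .by = "level_pct") |>
    dplyr::mutate(pass = .data$rsd_pct <= max_rsd_pct)

  list(repeatability = rep_tbl, reproducibility = repro_tbl)
}

#' Linearity of measured against actual mass fractions
#'
#' Ordinary least-squares fit of measured on actual mass fraction over the
#' assay's dynamic range. A slope near 1, intercept near 0 and r-squared
#' near 1 indicate the copy-ratio quantification is linear in the
#' gravimetric truth.
#'
#' @param data A data frame with columns `actual_pct` and `measured_pct`
#'   (replicate-level rows are fine; the fit uses all rows).
#' @return An object of class `linearity_fit` wrapping the `lm` fit, with
#'   [tidy()], [glance()], [autoplot()] and `print` methods.
#' @export
fit_linearity <- function(data) {
  check_columns(data, c("actual_pct", "measured_pct"), "linearity table")
  if (length(unique(data$actual_pct)) < 3) {
    abort_insufficient("Linearity needs at least three distinct actual levels.")
  }
  if (sd(data$actual_pct) == 0) {
    abort(
      "All actual levels are identical; the fit is singular.",
      class = c("ddq_error_singular_fit", "ddq_error"))
  }
  model <- lm(measured_pct ~ actual_pct, data = data)
  structure(
    list(
      model = model,
      n = nrow(data),
      range_pct = range(data$actual_pct)
    ),
    class = "linearity_fit"
  )
}

#' @export
print.linearity_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Linearity over %g-%g%% (n = %d): measured = %.4f * actual + %.4f, r^2 = %.4f\n",
    x$range_pct[1], x$range_pct[2], x$n,
    g$slope, g$intercept, g$r_squared))
  invisible(x)
}

#' @describeIn fit_linearity Coefficient table (term, estimate, std.error,
#'   statistic, p.value).
#' @param x A `linearity_fit` object.
#' @param ... Unused.
#' @method tidy linearity_fit
#' @export
tidy.linearity_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' @describeIn fit_linearity One-row fit summary: slope, intercept,
#'   r-squared, n and the dynamic-range endpoints.
#' @method glance linearity_fit
#' @export
glance.linearity_fit <- function(x, ...) {
  cf <- coef(x$model)
  mf <- x$model$model
  # squared Pearson correlation of measured with actual; equals the OLS
  # R^2 for a simple regression and stays quiet on an exact fit
  r2 <- stats::cor(mf$measured_pct, mf$actual_pct)^2
  tibble::tibble(
    slope = unname(cf["actual_pct"]),
    intercept = unname(cf["(Intercept)"]),
    r_squared = r2,
    n = x$n,
    range_low_pct = x$range_pct[1],
    range_high_pct = x$range_pct[2]
  )
}

#' @describeIn fit_linearity Scatter of measured vs actual with the fitted
#'   line and the identity line.
#' @param object A `linearity_fit` object.
#' @method autoplot linearity_fit
#' @export
autoplot.linearity_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$model$model,
                  ggplot2::aes(x = .data$actual_pct, y = .data$measured_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Actual mass fraction (% w/w)",
      y = "Measured mass fraction (% w/w)",
      title = sprintf("Linearity: slope %.3f, r² = %.4f", g$slope,
                      g$r_squared)
    ) +
    ggplot2::theme_minimal()
}
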