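#' Read a droplet-count or concentration table
#'
#' Reads a CSV of per-well ddPCR results. Two layouts are accepted: raw
#' droplet counts (columns `positives` and `accepted`) — the preferred
#' input — or pre-computed concentrations (column `copies_per_ul`), for
#' data published only at the concentration level. Identifier columns
#' (`sample_id`, `well_id`, `assay_id`, ...) are carried through. Rows
#' failing the accepted-droplet QC are flagged via `qc_pass`, never
#' silently dropped; structural problems (missing columns, non-numeric
#' cells, count inversions, duplicate wells) are schema errors naming the
#' offending rows.
#'
#' @param path Path to a CSV file.
#' @param qc_min_droplets Minimum accepted droplets for QC (default 10,000;
#'   only applied when counts are present).
#' @return A tibble, one row per well.
#' @export
read_droplet_table <- function(path, qc_min_droplets = 10000) {
  if (!file.exists(path)) {
    abort_schema(sprintf("File not found: %s", path))
  }
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_schema(sprintf("Cannot parse %s as CSV: %s",
                                             path, conditionMessage(e)))
  )
  if (nrow(data) == 0) {
    abort_schema(sprintf("%s contains no data rows.", path))
  }
  has_counts <- all(c("positives", "accepted") %in% names(data))
  has_conc <- "copies_per_ul" %in% names(data)
  if (!has_counts && !has_conc) {
    abort_schema(sprintf(
      "%s must provide either `positives` + `accepted` or `copies_per_ul`.",
      path))
  }
  numeric_cols <- intersect(c("positives", "accepted", "copies_per_ul"),
                            names(data))
  for (col in numeric_cols) {
    if (!is.numeric(data[[col]])) {
      abort_schema(sprintf("Column `%s` in %s is not numeric.", col, path))
    }
    bad <- which(is.na(data[[col]]) | data[[col]] < 0)
    if (length(bad) > 0) {
      abort_schema(sprintf("Column `%s` has missing or negative values at row(s) %s.",
                           col, paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (has_counts) {
    bad <- which(data$positives > data$accepted)
    if (length(bad) > 0) {
      abort_schema(sprintf("`positives` exceeds `accepted` at row(s) %s.",
                           paste(head(bad, 5), collapse = ", ")))
    }
    data$qc_pass <- data$accepted >= qc_min_droplets
  }
  # replicate rows legitimately share sample and assay labels; only a
  # physical well identifier must be unique within them
  id_cols <- intersect(c("sample_id", "well_id", "assay_id"), names(data))
  if ("well_id" %in% id_cols) {
    key <- do.call(paste, c(data[id_cols], sep = "\r"))
    dup <- which(duplicated(key))
    if (length(dup) > 0) {
      abort_schema(sprintf("Duplicate well identifier(s) at row(s) %s.",
                           paste(head(dup, 5), collapse = ", ")))
    }
  }
  tibble::as_tibble(data)
}

#' Write and read a transfer-coefficient configuration
#'
#' Serializes a calibrated [estimate_k()] result to YAML so the constant can
#' be reused by later quantification runs (and by the command-line
#' interface) with full provenance: the species pair, working K, pooled
#' statistics and per-mixture values.
#'
#' @param coefficient A `transfer_coefficient` object.
#' @param path Output/input YAML path.
#' @return `write_k_config()` returns `path` invisibly; `read_k_config()`
#'   returns a `k_config` object usable wherever a `k` argument is expected.
#' @export
write_k_config <- function(coefficient, path) {
  stopifnot(inherits(coefficient, "transfer_coefficient"))
  cfg <- list(
    species_pair = as.list(coefficient$species_pair),
    k = coefficient$k,
    k_mean = coefficient$k_mean,
    k_rsd_pct = coefficient$k_rsd_pct,
    digits = coefficient$digits,
    per_mixture = purrr::transpose(as.list(
      coefficient$per_mixture[c("mixture", "mass_fraction_pct", "k_raw", "k")])),
    generator = paste0("ddpcrquant ",
                       as.character(utils::packageVersion("ddpcrquant"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_k_config
#' @export
read_k_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No transfer-coefficient configuration at %s: run the calibration step first.", path),
          class = c("ddq_error_missing_calibration", "ddq_error"))
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$k) || !is.numeric(cfg$k) || cfg$k <= 0) {
    abort_schema(sprintf("%s does not contain a positive `k` value.", path))
  }
  structure(cfg, class = "k_config")
}

#' Write a quantification report
#'
#' Serializes quantification results together with the analysis settings
#' that produced them — the K constant, droplet volume, QC threshold and
#' adulteration tolerance — so every report is auditable on its own.
#' Percentages are rounded to 2 decimals at this boundary only; upstream
#' tibbles keep full precision.
#'
#' @param results A tibble of per-sample results (e.g. from
#'   [quantify_samples()] or [screen_products()]).
#' @param path Output JSON path.
#' @param k The transfer coefficient used (number or object).
#' @param droplet_volume_nl,qc_min_droplets,tolerance Settings to embed.
#' @return `path`, invisibly.
#' @export
write_quant_report <- function(results, path, k,
                               droplet_volume_nl = 0.85,
                               qc_min_droplets = 10000,
                               tolerance = 5) {
  rounded <- dplyr::mutate(
    tibble::as_tibble(results),
    dplyr::across(dplyr::where(is.numeric), function(x) round(x, 2)))
  payload <- list(
    settings = list(
      k = as_k(k),
      droplet_volume_nl = droplet_volume_nl,
      qc_min_droplets = qc_min_droplets,
      adulteration_tolerance_pct = tolerance,
      generator = paste0("ddpcrquant ",
                         as.character(utils::packageVersion("ddpcrquant")))
    ),
    results = rounded
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Bundled reference datasets
#'
#' Small plain-text datasets shipped with the package: replicate ddPCR
#' measurements of gravimetric pork/beef and chicken/beef mixtures from a
#' published assay of porcine and chicken derivatives in beef, used in
#' examples and tests.
#'
#' * `"calibration"` — replicate copies/uL of the adulterant (`target`) and
#'   beef (`reference`) assays for 10/30/50/70/90% w/w mixtures, six
#'   replicates each, both species.
#' * `"verification"` — measured mass fractions (mean, SD and reported
#'   signed deviation) of independent 20/40/60/80% check mixtures.
#' * `"dilution"` — sensitivity series 0.01–10% w/w: per-level measured
#'   mean and SD, reported deviation, detections out of three replicates.
#' * `"thermal"` — 10% and 50% mixtures steamed at 100 C for 5/10/20 min:
#'   measured mean, SD and deviation.
#' * `"products"` — sixteen commercial beef products: declared vs measured
#'   pork and chicken percentages (`NA` declared = label lacking defined
#'   content).
#'
#' @param name Dataset name, one of the above.
#' @return A tibble.
#' @examples
#' ddpcr_example("calibration")
#' @export
ddpcr_example <- function(name = c("calibration", "verification", "dilution",
                                   "thermal", "products")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "ddpcrquant", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
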