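test_that("rsd uses the sample standard deviation over the mean", {
  expect_equal(rsd(c(1.25, 1.12, 1.11, 1.24, 1.23)), 5.79, tolerance = 5e-3)
  expect_equal(rsd(c(0.36, 0.39, 0.35, 0.41, 0.38)), 6.32, tolerance = 5e-3)
  expect_identical(rsd(c(2, 2, 2)), 0)
  expect_error(rsd(1), class = "ddq_error_insufficient")
  expect_error(rsd(c(-1, 1)), class = "ddq_error_insufficient")
})

test_that("rsd is scale invariant", {
  withr::with_seed(31, {
    x <- runif(10, 1, 100)
    for (c in c(0.001, 1, 42)) {
      expect_equal(rsd(c * x), rsd(x), tolerance = 1e-10)
    }
  })
})

test_that("detection_rate converts counts to percent", {
  expect_identical(detection_rate(0, 3), 0)
  expect_equal(detection_rate(1, 3), 100 / 3)
  expect_identical(detection_rate(3, 3), 100)
  expect_error(detection_rate(4, 3), class = "ddq_error_invalid")
  expect_error(detection_rate(0, 0), class = "ddq_error_invalid")
})

test_that("determine_lod finds the lowest stably detected level", {
  expect_equal(determine_lod(example_species("dilution", "pork")), 0.1)
  expect_equal(determine_lod(example_species("dilution", "chicken")), 0.1)

  all_hit <- tibble::tibble(actual_pct = c(0.5, 1, 5),
                            detection_rate_pct = 100)
  expect_equal(determine_lod(all_hit), 0.5)

  none <- tibble::tibble(actual_pct = c(0.5, 1), detection_rate_pct = c(50, 80))
  expect_warning(lod <- determine_lod(none),
                 class = "ddq_warning_undefined_limit")
  expect_true(is.na(lod))
})

test_that("a non-monotone series cannot yield a spuriously low LOD", {
  dippy <- tibble::tibble(
    actual_pct = c(0.1, 0.2, 0.5, 1),
    detection_rate_pct = c(100, 66.7, 100, 100) # 0.2% level drops out
  )
  expect_equal(determine_lod(dippy), 0.5)
})

test_that("determine_loq applies precision and trueness jointly", {
  loq_p <- determine_loq(example_species("dilution", "pork"))
  loq_c <- determine_loq(example_species("dilution", "chicken"))
  expect_equal(as.numeric(loq_p), 1)
  expect_equal(as.numeric(loq_c), 1)
  lv <- attr(loq_p, "levels")
  # fully detected but biased high: quantification starts above those levels
  expect_false(lv$pass[lv$actual_pct == 0.2]) # RSD fine, bias 58%
  expect_true(all(lv$pass[lv$actual_pct >= 1]))
})

test_that("determine_loq skips an unstable level and keeps the passing tail", {
  series <- tibble::tibble(
    actual_pct = c(0.5, 1, 5, 10),
    detection_rate_pct = 100,
    rsd_pct = c(30, 10, 8, 5),
    deviation_pct = c(5, 10, 4, 2)
  )
  expect_equal(as.numeric(determine_loq(series)), 1)
  # replicate list-columns work too
  reps <- tibble::tibble(
    actual_pct = c(1, 5),
    detection_rate_pct = 100,
    measured = list(c(1.1, 1.0, 0.95), c(5.2, 4.9, 5.1))
  )
  expect_equal(as.numeric(determine_loq(reps)), 1)
})

test_that("LOD does not exceed LOQ when both are defined", {
  for (sp in c("pork", "chicken")) {
    d <- example_species("dilution", sp)
    expect_lte(determine_lod(d), as.numeric(determine_loq(d)))
  }
  cfg <- sim_config(replicate_cv = 0.05)
  sim <- simulate_dilution_series(replicates = 12, config = cfg, seed = 7) |>
    summarise_dilution_series()
  lod <- determine_lod(sim)
  loq <- suppressWarnings(as.numeric(determine_loq(sim)))
  if (!is.na(lod) && !is.na(loq)) expect_lte(lod, loq)
})

test_that("repeatability and reproducibility split within- and between-run spread", {
  runs <- tidyr::expand_grid(level_pct = c(10, 50), run_id = c("d1", "d2"),
                             rep = 1:3) |>
    dplyr::mutate(value = level_pct) # identical values everywhere
  rr <- repeatability_reproducibility(runs)
  expect_equal(rr$repeatability$rsd_pct, rep(0, 4))
  expect_equal(rr$reproducibility$rsd_pct, rep(0, 2))
  expect_true(all(rr$repeatability$pass))

  expect_error(
    repeatability_reproducibility(
      tibble::tibble(level_pct = 10, run_id = "d1", value = 10)),
    class = "ddq_error_insufficient")
})

test_that("repeatability RSD recovers injected replicate noise", {
  # 2% multiplicative noise at level 50%: the mean within-run RSD over many
  # runs approaches 2% (slightly below, by the small-sample sd bias)
  cv <- 0.02
  withr::with_seed(33, {
    sims <- purrr::map_dfr(1:100, function(run) {
      tibble::tibble(level_pct = 50, run_id = paste0("r", run),
                     value = 50 * rlnorm(6, -log(1 + cv^2) / 2,
                                         sqrt(log(1 + cv^2))))
    })
  })
  rr <- repeatability_reproducibility(sims)
  expect_equal(mean(rr$repeatability$rsd_pct), 2, tolerance = 0.15)
  expect_true(all(rr$repeatability$rsd_pct < 25))
})

test_that("a replicate group breaching the threshold is flagged failing", {
  runs <- dplyr::bind_rows(
    tibble::tibble(level_pct = 10, run_id = "a", value = c(2, 10, 20)),
    tibble::tibble(level_pct = 10, run_id = "b", value = c(9.9, 10, 10.1))
  )
  rr <- repeatability_reproducibility(runs)
  expect_equal(rr$repeatability$pass, c(FALSE, TRUE))
})

test_that("fit_linearity recovers a perfect line and rejects degenerate input", {
  perfect <- tibble::tibble(actual_pct = c(1, 5, 10, 50, 90),
                            measured_pct = c(1, 5, 10, 50, 90))
  fit <- fit_linearity(perfect)
  g <- glance(fit)
  expect_equal(g$slope, 1, tolerance = 1e-12)
  expect_equal(g$intercept, 0, tolerance = 1e-10)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)
  expect_equal(suppressWarnings(tidy(fit))$term, c("(Intercept)", "actual_pct"))

  expect_error(
    fit_linearity(tibble::tibble(actual_pct = c(1, 5), measured_pct = c(1, 5))),
    class = "ddq_error_insufficient")
})
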