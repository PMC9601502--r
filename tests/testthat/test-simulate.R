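test_that("simulate_partition follows binomial occupancy and fixed seeds", {
  expect_equal(simulate_partition(0, 20000, seed = 1)$positives, 0)
  a <- simulate_partition(c(0.05, 0.5), 20000, seed = 99)
  b <- simulate_partition(c(0.05, 0.5), 20000, seed = 99)
  expect_identical(a, b)

  # occupancy fraction near 1 - exp(-1) at lambda = 1, within 3 binomial SDs
  part <- simulate_partition(1, 20000, seed = 5)
  p <- -expm1(-1)
  expect_lt(abs(part$positives / 20000 - p), 3 * sqrt(p * (1 - p) / 20000))
  expect_error(simulate_partition(-1, 20000), class = "ddq_error_invalid")
})

test_that("expected-value sampling makes the estimator exact", {
  lambda <- c(0.01, 0.3, 1.5)
  part <- simulate_partition(lambda, 20000, sampling = "expected")
  expect_equal(estimate_cpd(part$positives, part$accepted), lambda,
               tolerance = 1e-12)
})

test_that("the Poisson estimator is consistent at standard droplet counts", {
  for (lambda in c(0.01, 0.1, 1.0)) {
    withr::with_seed(1000 + round(1000 * lambda), {
      part <- simulate_partition(rep(lambda, 500), 20000)
      est <- estimate_cpd(part$positives, part$accepted)
    })
    expect_equal(mean(est), lambda, tolerance = 0.02)
  }
})

test_that("sim_config validates and derives the implied K", {
  cfg <- sim_config(c_target = 300, k_true = 1.19)
  expect_equal(cfg$c_reference, 357)
  expect_equal(cfg$k_true, 1.19)
  cfg2 <- sim_config(c_target = 100, c_reference = 38)
  expect_equal(cfg2$k_true, 0.38)
  expect_error(sim_config(replicate_cv = -0.1), class = "ddq_error_invalid")
  expect_error(sim_config(degradation_factor = 0), class = "ddq_error_invalid")
  expect_error(sim_config(degradation_factor = 1.2), class = "ddq_error_invalid")
})

test_that("simulated wells hit the expected concentration magnitudes", {
  # pork-like anchor: a 10% mixture should read ~30 copies/uL in the target
  # channel and a few hundred in the reference channel
  cfg <- sim_config()
  wells <- withr::with_seed(12, {
    purrr::map_dfr(1:50, function(i) {
      dplyr::bind_rows(simulate_mixture_well(10, cfg, "target"),
                       simulate_mixture_well(10, cfg, "reference"))
    })
  })
  conc <- wells |>
    dplyr::mutate(copies_per_ul = cpd_to_concentration(
      estimate_cpd(positives, accepted), cfg$droplet_volume_nl)) |>
    dplyr::summarise(m = mean(copies_per_ul), .by = assay)
  expect_equal(conc$m[conc$assay == "target"], 30, tolerance = 0.1)
  expect_equal(conc$m[conc$assay == "reference"], 321.3, tolerance = 0.1)
  expect_error(simulate_mixture_well(101, cfg), class = "ddq_error_invalid")
})

test_that("a zero-fraction sample never fires the target channel", {
  w <- simulate_mixture_well(0, sim_config(), "target", seed = 3)
  expect_equal(w$positives, 0)
  expect_equal(w$lambda_true, 0)
})

test_that("noiseless simulation is a deterministic end-to-end oracle", {
  cfg <- noiseless_config(k_true = 1.19)
  sim <- simulate_calibration_series(config = cfg)
  fit <- estimate_k(sim, pork_pair, digits = Inf)
  expect_equal(fit$k_mean, 1.19, tolerance = 1e-12)
  expect_equal(tidy(fit)$k_raw, rep(1.19, 5), tolerance = 1e-12)

  # quantify the simulated wells back: exact recovery of the mass fraction
  conc <- sim |>
    dplyr::summarise(q = mean(copies_per_ul),
                     .by = c(mass_fraction_pct, assay)) |>
    tidyr::pivot_wider(names_from = assay, values_from = q)
  measured <- mass_fraction(mass_ratio(conc$target, conc$reference, 1.19))
  expect_equal(measured, conc$mass_fraction_pct, tolerance = 1e-12)
})

test_that("calibration parameter recovery at default noise", {
  for (k_true in c(0.38, 1.19)) {
    cfg <- sim_config(c_target = if (k_true < 1) 2300 else 300,
                      k_true = k_true)
    fits <- purrr::map_dbl(1:5, function(i) {
      sim <- simulate_calibration_series(config = cfg, seed = 5000 + i)
      estimate_k(sim)$k_mean
    })
    expect_true(all(abs(fits - k_true) / k_true < 0.05))
  }
})

test_that("simulation is reproducible and respects the seed contract", {
  s1 <- simulate_calibration_series(config = sim_config(), seed = 77)
  s2 <- simulate_calibration_series(config = sim_config(), seed = 77)
  expect_identical(s1, s2)
  s3 <- simulate_calibration_series(config = sim_config(), seed = 78)
  expect_false(identical(s1$positives, s3$positives))
})

test_that("trace levels produce Poisson-limited stochastic non-detects", {
  # pick the level whose expected target copies per well is 0.2:
  # detection probability ~ 1 - exp(-0.2) = 18.1%
  cfg <- sim_config(replicate_cv = 0)
  copies_per_well <- function(w) {
    (w / 100) * cfg$c_target * cfg$droplet_volume_nl * 1e-3 *
      cfg$droplets_per_well
  }
  w <- 0.2 / copies_per_well(1) # solve for 0.2 copies/well
  sim <- simulate_dilution_series(levels_pct = w, replicates = 600,
                                  config = cfg, seed = 41)
  rate <- mean(sim$detected)
  expect_equal(rate, -expm1(-0.2), tolerance = 0.25)
  # a true-zero level is never detected (no noise floor is modelled)
  zero <- simulate_dilution_series(levels_pct = 0, replicates = 20,
                                   config = cfg, seed = 42)
  expect_equal(sum(zero$detected), 0)
})

test_that("LOD improves (or holds) with more droplets per well", {
  levels <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2)
  lods <- purrr::map_dbl(c(5000, 20000, 80000), function(n) {
    cfg <- sim_config(droplets_per_well = n)
    sim <- simulate_dilution_series(levels, replicates = 30, config = cfg,
                                    seed = 91, qc_min_droplets = 1000)
    suppressWarnings(determine_lod(summarise_dilution_series(sim)))
  })
  expect_true(all(diff(lods) <= 0))
})

test_that("degradation scales channel rates and can be made differential", {
  cfg <- noiseless_config(degradation_factor = 0.5)
  full <- simulate_mixture_well(50, noiseless_config(), "target")
  half <- simulate_mixture_well(50, cfg, "target")
  expect_equal(half$lambda_true, full$lambda_true / 2, tolerance = 1e-12)

  # equal loss in both channels cancels in the ratio: quantification survives
  sim <- simulate_calibration_series(config = cfg)
  expect_equal(estimate_k(sim, digits = Inf)$k_mean, 1.19, tolerance = 1e-12)

  # preferential loss of target copies inflates the apparent K
  diff_cfg <- sim_config(replicate_cv = 0, sampling = "expected",
                         degradation_factor = 0.5,
                         degradation_factor_reference = 1)
  sim_d <- simulate_calibration_series(config = diff_cfg)
  expect_gt(estimate_k(sim_d, digits = Inf)$k_mean, 1.19)
})
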