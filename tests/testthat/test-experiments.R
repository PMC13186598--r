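canonical_spec <- covariance_spec(25, 5, 2.5, 2.5, 0)
canonical_params <- shared_error_params(30, 0.65, 12, 4, tau_I = 2, tau_E = 4)

test_that("subtractive sweep tracks the analytic slope across the grid", {
  sw <- run_subtractive_sweep(canonical_spec, rho_grid = c(-0.6, 0, 0.6),
                              n = 25, iterations = 500, seed = 10)
  expect_s3_class(sw, "sweep_result")
  expect_named(sw, c("rho", "expected_slope", "mean_slope", "sd_slope",
                     "mc_se_slope", "rejection_rate", "mc_se_rejection"))
  expect_equal(sw$expected_slope, sw$rho - 1)
  expect_true(all(sw$rejection_rate >= 0 & sw$rejection_rate <= 1))
  # 3.5 MC SEs: per-condition 3-SE bound, Bonferroni-widened for the
  # maximum over the grid
  expect_true(all(abs(sw$mean_slope - sw$expected_slope) <=
                    3.5 * sw$mc_se_slope))
})

test_that("per-condition results are keyed on rho, not grid order", {
  a <- run_subtractive_sweep(canonical_spec, rho_grid = c(0.2, -0.4), n = 25,
                             iterations = 100, seed = 5)
  b <- run_subtractive_sweep(canonical_spec, rho_grid = c(-0.4, 0.2), n = 25,
                             iterations = 100, seed = 5)
  expect_equal(dplyr::arrange(tibble::as_tibble(a), rho),
               dplyr::arrange(tibble::as_tibble(b), rho))
})

test_that("extending iterations leaves the earlier substreams unchanged", {
  make_xy <- function(s) {
    ae <- slopebench:::sample_bivariate_core(canonical_spec, 25, s)
    list(x = ae$y, y = ae$x - ae$y)
  }
  short <- slopebench:::sweep_condition(make_xy, 40, -1, 0.05, 9, 123)
  long <- slopebench:::sweep_condition(make_xy, 80, -1, 0.05, 9, 123)
  expect_identical(long$slopes[1:40], short$slopes)
  expect_identical(long$rejects[1:40], short$rejects)
})

test_that("independent sweep compresses slopes by the SD ratio", {
  spec <- covariance_spec(10, 5, 2.5, 2.5, 0)
  sw <- run_independent_sweep(spec, rho_grid = c(-0.6, 0, 0.9),
                              sd_ratio = 0.5, n = 25, iterations = 500,
                              seed = 11)
  expect_equal(sw$expected_slope, sw$rho * 0.5)
  expect_true(all(abs(sw$mean_slope - sw$expected_slope) <=
                    3.5 * sw$mc_se_slope))
  # conditions are keyed on (rho, ratio): another ratio gives other draws
  sw2 <- run_independent_sweep(spec, rho_grid = c(0), sd_ratio = 2,
                               n = 25, iterations = 500, seed = 11)
  expect_false(isTRUE(all.equal(
    sw$mean_slope[sw$rho == 0], sw2$mean_slope
  )))
})

test_that("rejection rate grows with distance from the null correlation", {
  sw <- run_subtractive_sweep(canonical_spec, rho_grid = c(0, 0.3, 0.6),
                              n = 25, iterations = 1000, seed = 12)
  expect_lt(sw$rejection_rate[1], sw$rejection_rate[2])
  expect_lt(sw$rejection_rate[2], sw$rejection_rate[3])
})

test_that("shared-error study recovers the model's population slopes", {
  study <- run_shared_error_study(canonical_params, population_n = 1000,
                                  n_sub = 25, iterations = 1000, seed = 13)
  expect_s3_class(study, "bootstrap_slopes")
  expect_identical(nrow(study), 1000L)
  pop <- attr(study, "population_slopes")
  analytic <- shared_error_expected_slopes(canonical_params)
  # finite-population estimates sit within sampling error of the algebra
  expect_lt(abs(pop["slope_I_on_E"] - analytic["slope_I_on_E"]), 0.06)
  expect_lt(abs(pop["slope_E_on_A"] - analytic["slope_E_on_A"]), 0.06)
  expect_lt(abs(pop["slope_I_on_A"] - analytic["slope_I_on_A"]), 0.06)
  gl <- glance(study)
  expect_named(gl, c("relationship", "population_slope", "expected_slope",
                     "boot_mean", "boot_se", "boot_q25", "boot_median",
                     "boot_q75"))
  expect_true(all(gl$boot_q25 <= gl$boot_median &
                    gl$boot_median <= gl$boot_q75))
})

test_that("noiseless shared-error study yields the exact -p_i tradeoff", {
  p0 <- shared_error_params(30, 0.65, 12, 4)
  study <- run_shared_error_study(p0, population_n = 500, n_sub = 25,
                                  iterations = 50, seed = 14)
  pop <- attr(study, "population_slopes")
  expect_equal(unname(pop["slope_I_on_E"]), -0.65)
  # every bootstrap resample sees the same deterministic relation
  expect_equal(study$slope_I_on_E, rep(-0.65, 50))
})

test_that("loose-additivity study matches the attenuation prediction", {
  spec <- covariance_spec(10, 10, 2.5, 2.5, -0.5)
  study <- run_loose_additivity_study(spec, noise_grid = c(0, 1.5, 3),
                                      n_sub = 25, iterations = 500,
                                      population_n = 1000, seed = 15)
  expect_s3_class(study, "loose_additivity_result")
  expect_named(study, c("noise_sd", "predicted_slope", "mean_slope",
                        "median_slope", "boot_se", "q25", "q75"))
  # no noise: the composite is the total, every slope is exactly 1
  expect_identical(study$median_slope[1], 1)
  expect_identical(study$boot_se[1], 0)
  draws <- attr(study, "draws")
  expect_identical(nrow(draws), 1500L)
  expect_true(all(draws$slope[draws$noise_sd == 0] == 1))
  # attenuation: predictions decrease and medians follow within 3 boot SE
  expect_true(all(diff(study$predicted_slope) < 0))
  off0 <- abs(study$median_slope[-1] - study$predicted_slope[-1])
  expect_true(all(off0 <= 3 * study$boot_se[-1]))
})

test_that("residual diagnostics return exact zeros on additive data", {
  tr <- make_independent_triad(covariance_spec(10, 5, 2, 3, -0.4), 200, 16)
  d <- residual_diagnostics(tr)
  expect_identical(
    unname(unlist(d)),
    c(0, 0, 0, 0, 0)
  )
})

test_that("residual diagnostics detect non-additive fingerprints", {
  tr <- make_independent_triad(covariance_spec(10, 5, 2, 3, 0), 2000, 17)
  gated <- tibble::tibble(
    implicit = tr$implicit, explicit = tr$explicit,
    total = tr$implicit + tr$explicit -
      0.02 * tr$implicit * tr$explicit
  )
  expect_lt(residual_diagnostics(gated)$corr_with_product, 0)
  set.seed(18)
  noisy <- tibble::tibble(
    implicit = tr$implicit, explicit = tr$explicit,
    total = tr$implicit + tr$explicit + rnorm(2000)
  )
  d <- residual_diagnostics(noisy)
  expect_lt(abs(d$mean_residual), 3 / sqrt(2000))
  expect_error(residual_diagnostics(gated[1:2, ]),
               class = "slopebench_sample_size_error")
})

test_that("experiment drivers validate their arguments", {
  expect_error(run_subtractive_sweep(canonical_spec, rho_grid = c(0, 1)),
               class = "slopebench_argument_error")
  expect_error(run_independent_sweep(canonical_spec, sd_ratio = -1,
                                     iterations = 10),
               class = "slopebench_domain_error")
  expect_error(run_shared_error_study(canonical_params, population_n = 10,
                                      n_sub = 25, iterations = 5),
               class = "slopebench_argument_error")
  expect_error(run_loose_additivity_study(canonical_spec,
                                          noise_grid = c(-1, 0)),
               class = "slopebench_argument_error")
})
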