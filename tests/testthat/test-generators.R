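aimreport_spec_AE <- covariance_spec(25, 5, 2.5, 2.5, 0)

test_that("identical seeds give bit-identical samples; different seeds differ", {
  spec <- covariance_spec(25, 5, 2.5, 2.5, 0.3)
  a <- sample_bivariate(spec, 1000, seed = 11)
  b <- sample_bivariate(spec, 1000, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, sample_bivariate(spec, 1000, seed = 12)))
  expect_identical(make_subtractive_triad(spec, 50, 3),
                   make_subtractive_triad(spec, 50, 3))
  p <- shared_error_params(30, 0.65, 12, 4, 2, 4)
  expect_identical(make_shared_error_population(p, 50, 3),
                   make_shared_error_population(p, 50, 3))
})

test_that("perfect correlation is an exact linear construction", {
  spec <- covariance_spec(25, 5, 2, 2, 1)
  xy <- sample_bivariate(spec, 100, seed = 4)
  expect_equal(xy$y - 5, xy$x - 25)
  spec_neg <- covariance_spec(0, 0, 1.5, 3, -1)
  xy2 <- sample_bivariate(spec_neg, 100, seed = 4)
  expect_equal(cor(xy2$x, xy2$y), -1)
})

test_that("sample moments recover the specification at large n", {
  spec <- covariance_spec(25, 5, 2.5, 2.5, 0.5)
  xy <- sample_bivariate(spec, 1e6, seed = 21)
  expect_lt(abs(cor(xy$x, xy$y) - 0.5), 0.005)
  expect_lt(abs(mean(xy$x) - 25) / 25, 0.01)
  expect_lt(abs(mean(xy$y) - 5) / 5, 0.01)
  expect_lt(abs(sd(xy$x) - 2.5) / 2.5, 0.01)
  expect_lt(abs(sd(xy$y) - 2.5) / 2.5, 0.01)
})

test_that("additivity holds exactly, by construction, in every generator", {
  spec <- covariance_spec(25, 5, 2.5, 2.5, 0.4)
  p <- shared_error_params(30, 0.65, 12, 4, 2, 4)
  triads <- c(
    list(
      make_subtractive_triad(spec, 200, 1),
      make_independent_triad(spec, 200, 1),
      make_shared_error_population(p, 200, 1)
    ),
    make_iso_A_scenarios()
  )
  for (tr in triads) {
    expect_identical(tr$total, tr$implicit + tr$explicit)
  }
})

test_that("subtractive triads have the derived component's moments", {
  tr <- make_subtractive_triad(aimreport_spec_AE, 1e6, seed = 8)
  expect_identical(triad_provenance(tr), "subtractive")
  # E[I] = mu_A - mu_E = 20 by linearity
  expect_lt(abs(mean(tr$implicit) - 20), 0.01)
  expect_lt(abs(cor(tr$total, tr$explicit)), 0.005)
})

test_that("independent triads reproduce the compressed-slope example", {
  # sd ratio 0.5 with correlation -0.6 gives an I-on-E slope of -0.3
  spec <- covariance_spec(10, 5, 1.25, 2.5, -0.6)
  tr <- make_independent_triad(spec, 1e6, seed = 9)
  expect_identical(triad_provenance(tr), "independent")
  expect_lt(abs(fit_slope(tr$explicit, tr$implicit)$slope - (-0.3)), 0.01)
  spec0 <- covariance_spec(10, 5, 1.25, 2.5, 0)
  tr0 <- make_independent_triad(spec0, 1e6, seed = 9)
  f0 <- fit_slope(tr0$explicit, tr0$implicit)
  expect_lt(abs(f0$slope), 3 * f0$se_slope)
})

test_that("shared-error populations follow the residual-error relation", {
  p <- shared_error_params(30, 0.65, 12, 4, tau_I = 2, tau_E = 4)
  # noiseless: implicit is exactly p_i * (r - explicit)
  p0 <- shared_error_params(30, 0.65, 12, 4)
  tr0 <- make_shared_error_population(p0, 500, seed = 2)
  expect_equal(tr0$implicit, 0.65 * (30 - tr0$explicit))
  tr <- make_shared_error_population(p, 1e6, seed = 2)
  expect_identical(triad_provenance(tr), "shared_error")
  # E[I_obs] = p_i (r - mu_E) = 11.7
  expect_lt(abs(mean(tr$implicit) - 11.7), 0.05)
  expect_lt(abs(fit_slope(tr$explicit, tr$implicit)$slope - (-0.325)), 0.01)
})

test_that("iso-A scenarios pin the three correlations under exact additivity", {
  scen <- make_iso_A_scenarios()
  expect_named(scen, c("constant_total", "scaled_components",
                       "shifting_tradeoff"))
  cors <- purrr::map_dbl(scen, ~ cor(.x$implicit, .x$explicit))
  expect_equal(unname(cors), c(-1, 1, -1))
  expect_true(all(purrr::map_int(scen, nrow) == 3L))
  # constant_total sits on a single iso-A contour
  expect_identical(unique(scen$constant_total$total), 20)
})

test_that("derived seeds are deterministic, keyed, and 32-bit safe", {
  expect_identical(derive_seed(7, 3, 41), derive_seed(7, 3, 41))
  expect_false(derive_seed(7, 3, 41) == derive_seed(7, 3, 42))
  expect_false(derive_seed(7, 3, 41) == derive_seed(7, 4, 41))
  expect_false(derive_seed(7, 3, 41) == derive_seed(8, 3, 41))
  big <- purrr::map_int(1:200, ~ derive_seed(2^30 + .x, 2^26, 10000))
  expect_true(all(big >= 0 & big < 2^31))
})

test_that("triad CSV dump has the documented schema and round-trips", {
  tr <- make_independent_triad(covariance_spec(10, 5, 2, 2, 0.2), 20, 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_triad_csv(tr, path)
  expect_match(readLines(path, n = 1), "^# units:")
  back <- read_result_csv(path)
  expect_named(back, c("implicit_deg", "explicit_deg", "total_deg",
                       "provenance", "seed"))
  expect_equal(back$implicit_deg, tr$implicit)
  expect_identical(unique(back$provenance), "independent")
})

test_that("generators reject undersized or malformed requests", {
  spec <- covariance_spec(0, 0, 1, 1, 0)
  expect_error(sample_bivariate(spec, 1, 1),
               class = "slopebench_argument_error")
  expect_error(make_subtractive_triad(spec, 1.5, 1),
               class = "slopebench_argument_error")
  expect_error(make_independent_triad("not a spec", 10, 1))
})
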