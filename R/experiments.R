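# One sweep condition: `iterations` seeded datasets, an OLS fit each,
# benchmark decision by CI exclusion. `make_xy(seed)` returns list(x, y)
# with x the predictor. Iteration seeds come from derive_seed(master, key,
# iter), so results per condition are independent of grid order and the
# first k iterations are unchanged when `iterations` grows.
sweep_condition <- function(make_xy, iterations, benchmark, alpha,
                            master, key) {
  slopes <- numeric(iterations)
  rejects <- logical(iterations)
  for (it in seq_len(iterations)) {
    d <- make_xy(derive_seed(master, key, it))
    f <- ols_core(d$x, d$y, alpha)
    slopes[it] <- f$slope
    rejects[it] <- benchmark < f$ci_low || benchmark > f$ci_high
  }
  list(slopes = slopes, rejects = rejects)
}

new_sweep_result <- function(rows, n, iterations, benchmark, alpha, seed,
                             kind) {
  out <- rows
  attr(out, "n") <- n
  attr(out, "iterations") <- iterations
  attr(out, "benchmark") <- benchmark
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "kind") <- kind
  class(out) <- c("sweep_result", class(out))
  out
}

summarise_condition <- function(sim, iterations) {
  p <- mean(sim$rejects)
  tibble::tibble(
    mean_slope = mean(sim$slopes),
    sd_slope = stats::sd(sim$slopes),
    mc_se_slope = stats::sd(sim$slopes) / sqrt(iterations),
    rejection_rate = p,
    mc_se_rejection = sqrt(p * (1 - p) / iterations)
  )
}

#' Monte Carlo sweep of the subtractive slope test over a correlation grid
#'
#' For each correlation `rho` in the grid, simulates `iterations` datasets
#' of `n` participants by sampling (A, E) from the bivariate normal built
#' from `spec_base` with that `rho`, derives `I = A - E`, fits the OLS
#' slope of I on E with a `(1 - alpha)` CI, and records the mean and SD of
#' the slopes together with the fraction of datasets whose CI excludes
#' `benchmark`. The analytic expectation `rho * sd_A / sd_E - 1` is
#' tabulated alongside, and per-condition Monte Carlo standard errors are
#' emitted so downstream tolerances can be principled.
#'
#' @param spec_base A [covariance_spec()] over (A, E); its `rho` is
#'   ignored and replaced by each grid value.
#' @param rho_grid Correlations to sweep; each strictly inside (-1, 1).
#' @param n Participants per simulated dataset.
#' @param iterations Datasets per grid point.
#' @param benchmark Benchmark slope tested by CI exclusion (default -1).
#' @param alpha Two-sided significance level (default 0.05).
#' @param seed Master seed; conditions and iterations derive substreams
#'   via [derive_seed()].
#'
#' @return A `sweep_result` tibble with one row per grid point: `rho`,
#'   `expected_slope`, `mean_slope`, `sd_slope`, `mc_se_slope`,
#'   `rejection_rate`, `mc_se_rejection`.
#' @examples
#' spec <- covariance_spec(25, 5, 2.5, 2.5, 0)
#' run_subtractive_sweep(spec, rho_grid = c(-0.5, 0, 0.5), n = 25,
#'                       iterations = 200, seed = 1)
#' @export
run_subtractive_sweep <- function(spec_base,
                                  rho_grid = seq(-0.9, 0.9, by = 0.1),
                                  n = 25, iterations = 10000,
                                  benchmark = -1, alpha = 0.05, seed = 1) {
  stopifnot(inherits(spec_base, "covariance_spec"))
  check_grid(rho_grid)
  check_n(iterations, min = 1L)
  rows <- purrr::map_dfr(rho_grid, function(rho) {
    spec <- covariance_spec(spec_base$mean_x, spec_base$mean_y,
                            spec_base$sd_x, spec_base$sd_y, rho)
    sim <- sweep_condition(
      function(s) {
        ae <- sample_bivariate_core(spec, n, s)
        list(x = ae$y, y = ae$x - ae$y) # I = A - E regressed on E
      },
      iterations, benchmark, alpha, seed, condition_key(rho)
    )
    dplyr::bind_cols(
      tibble::tibble(
        rho = rho,
        expected_slope = expected_slope_subtractive(rho, spec$sd_x, spec$sd_y)
      ),
      summarise_condition(sim, iterations)
    )
  })
  new_sweep_result(rows, n, iterations, benchmark, alpha, seed,
                   kind = "subtractive")
}

check_grid <- function(rho_grid) {
  if (!is.numeric(rho_grid) || length(rho_grid) < 1L ||
      any(abs(rho_grid) >= 1)) {
    rlang::abort("`rho_grid` values must lie strictly inside (-1, 1).",
                 class = "slopebench_argument_error")
  }
  invisible(NULL)
}

#' Monte Carlo sweep of the slope test under independent measurement
#'
#' As [run_subtractive_sweep()], but implicit and explicit learning are
#' sampled directly from a bivariate normal (additivity enforced by
#' construction, `A = I + E`) and the fitted regression is I on E with
#' default benchmark 0. The implicit SD at every condition is
#' `sd_ratio * sd_E`, so one call reproduces one variance-ratio column of
#' the independent-measurement analysis; sweep `sd_ratio` over
#' `c(0.5, 1, 2)` for the full design.
#'
#' @param spec_base A [covariance_spec()] over (I, E); `sd_y` is the
#'   explicit SD, `sd_x` and `rho` are overridden per condition.
#' @param rho_grid Correlations to sweep.
#' @param sd_ratio Implicit-to-explicit SD ratio `sigma_I / sigma_E` (> 0).
#' @param n,iterations,benchmark,alpha,seed As in
#'   [run_subtractive_sweep()]; `benchmark` defaults to 0.
#'
#' @return A `sweep_result` tibble; `expected_slope` is
#'   `rho * sd_ratio`, and an `sd_ratio` column records the condition.
#' @examples
#' spec <- covariance_spec(10, 12, 2.5, 2.5, 0)
#' run_independent_sweep(spec, rho_grid = c(-0.6, 0), sd_ratio = 0.5,
#'                       n = 25, iterations = 200, seed = 1)
#' @export
run_independent_sweep <- function(spec_base,
                                  rho_grid = seq(-0.9, 0.9, by = 0.1),
                                  sd_ratio = 1, n = 25, iterations = 10000,
                                  benchmark = 0, alpha = 0.05, seed = 1) {
  stopifnot(inherits(spec_base, "covariance_spec"))
  check_grid(rho_grid)
  check_n(iterations, min = 1L)
  if (!is.numeric(sd_ratio) || length(sd_ratio) != 1L || sd_ratio <= 0) {
    rlang::abort("`sd_ratio` must be a single positive number.",
                 class = "slopebench_domain_error")
  }
  sigma_E <- spec_base$sd_y
  sigma_I <- sd_ratio * sigma_E
  rows <- purrr::map_dfr(rho_grid, function(rho) {
    spec <- covariance_spec(spec_base$mean_x, spec_base$mean_y,
                            sigma_I, sigma_E, rho)
    sim <- sweep_condition(
      function(s) {
        ie <- sample_bivariate_core(spec, n, s)
        list(x = ie$y, y = ie$x) # I regressed on E
      },
      iterations, benchmark, alpha, seed,
      derive_seed(seed, condition_key(rho), condition_key(sd_ratio))
    )
    dplyr::bind_cols(
      tibble::tibble(
        rho = rho, sd_ratio = sd_ratio,
        expected_slope = expected_slope_independent(rho, sigma_I, sigma_E)
      ),
      summarise_condition(sim, iterations)
    )
  })
  new_sweep_result(rows, n, iterations, benchmark, alpha, seed,
                   kind = "independent")
}

#' Bootstrap slope study of the shared-error model
#'
#' Generates one shared-error population of `population_n` participants,
#' computes the three population regression slopes (I on E, E on A, I on
#' A, with A the sum of the noisy component measures), then bootstraps
#' `iterations` resamples of `n_sub` participants (with replacement) and
#' refits all three slopes in each resample.
#'
#' @param params A [shared_error_params()] object.
#' @param population_n Simulated population size (>= 2).
#' @param n_sub Bootstrap sample size (<= `population_n`).
#' @param iterations Number of bootstrap resamples.
#' @param seed Master seed.
#'
#' @return A `bootstrap_slopes` tibble with one row per resample and
#'   columns `iteration`, `slope_I_on_E`, `slope_E_on_A`, `slope_I_on_A`.
#'   Attributes carry the population slopes (`population_slopes`, a named
#'   vector), the population itself (`population`), `n_sub` and `seed`;
#'   see [glance.bootstrap_slopes()].
#' @examples
#' p <- shared_error_params(30, 0.65, 12, 4, tau_I = 2, tau_E = 4)
#' study <- run_shared_error_study(p, population_n = 1000, n_sub = 25,
#'                                 iterations = 500, seed = 1)
#' glance(study)
#' @export
run_shared_error_study <- function(params, population_n = 1000, n_sub = 25,
                                   iterations = 10000, seed = 1) {
  stopifnot(inherits(params, "shared_error_params"))
  check_n(population_n, min = 2L)
  check_n(n_sub, min = 3L)
  check_n(iterations, min = 1L)
  if (n_sub > population_n) {
    rlang::abort("`n_sub` must not exceed `population_n`.",
                 class = "slopebench_argument_error")
  }
  pop <- make_shared_error_population(params, population_n,
                                      derive_seed(seed, 1))
  pop_slopes <- triad_slopes(pop$implicit, pop$explicit, pop$total)
  draws <- matrix(NA_real_, nrow = iterations, ncol = 3L)
  for (it in seq_len(iterations)) {
    set.seed(derive_seed(seed, 2, it))
    idx <- sample.int(population_n, n_sub, replace = TRUE)
    draws[it, ] <- triad_slopes(pop$implicit[idx], pop$explicit[idx],
                                pop$total[idx])
  }
  out <- tibble::tibble(
    iteration = seq_len(iterations),
    slope_I_on_E = draws[, 1], slope_E_on_A = draws[, 2],
    slope_I_on_A = draws[, 3]
  )
  attr(out, "population_slopes") <- pop_slopes
  attr(out, "population") <- pop
  attr(out, "params") <- params
  attr(out, "n_sub") <- n_sub
  attr(out, "iterations") <- iterations
  attr(out, "seed") <- seed
  class(out) <- c("bootstrap_slopes", class(out))
  out
}

triad_slopes <- function(implicit, explicit, total) {
  c(
    slope_I_on_E = ols_core(explicit, implicit, 0.05)$slope,
    slope_E_on_A = ols_core(total, explicit, 0.05)$slope,
    slope_I_on_A = ols_core(total, implicit, 0.05)$slope
  )
}

#' Population and bootstrap summary of a shared-error study
#'
#' @param x A [run_shared_error_study()] result.
#' @param ... Unused.
#' @return A tibble with one row per relationship: population slope,
#'   analytic expectation, bootstrap mean/SE and quartiles.
#' @method glance bootstrap_slopes
#' @export
glance.bootstrap_slopes <- function(x, ...) {
  pop <- attr(x, "population_slopes")
  expected <- shared_error_expected_slopes(attr(x, "params"))
  rel <- names(pop)
  purrr::map_dfr(rel, function(r) {
    d <- x[[r]]
    tibble::tibble(
      relationship = r,
      population_slope = unname(pop[r]),
      expected_slope = unname(expected[r]),
      boot_mean = mean(d), boot_se = stats::sd(d),
      boot_q25 = unname(stats::quantile(d, 0.25)),
      boot_median = unname(stats::quantile(d, 0.5)),
      boot_q75 = unname(stats::quantile(d, 0.75))
    )
  })
}

#' @export
print.bootstrap_slopes <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_slopes> %d resamples of n = %d from a population of %d\n",
    attr(x, "iterations"), attr(x, "n_sub"), nrow(attr(x, "population"))
  ))
  print(glance(x))
  invisible(x)
}

#' Attenuation of the loose-additivity slope under measurement noise
#'
#' The loose-additivity check regresses total adaptation A on the sum of
#' the measured components. This study generates one additive population
#' of true (I, E) pairs from `spec_IE` (total = I + E exactly), then, for
#' each noise SD in `noise_grid`, adds independent Gaussian observation
#' noise to both components and bootstraps `iterations` resamples of
#' `n_sub`, refitting A on (`I_obs + E_obs`) each time. The closed-form
#' attenuation prediction from [attenuation_expected_slope()] is tabulated
#' alongside the bootstrap distribution.
#'
#' @param spec_IE A [covariance_spec()] over the true (I, E) components.
#' @param noise_grid Noise SDs (degrees, >= 0) applied to both components.
#' @param n_sub Bootstrap sample size.
#' @param iterations Bootstrap resamples per noise level.
#' @param population_n Size of the underlying true population.
#' @param seed Master seed.
#'
#' @return A `loose_additivity_result` tibble, one row per noise level:
#'   `noise_sd`, `predicted_slope`, `mean_slope`, `median_slope`,
#'   `boot_se`, `q25`, `q75`. The full draws are in `attr(, "draws")`
#'   (columns `noise_sd`, `iteration`, `slope`).
#' @examples
#' spec <- covariance_spec(10, 10, 2.5, 2.5, -0.5)
#' run_loose_additivity_study(spec, noise_grid = c(0, 2), n_sub = 25,
#'                            iterations = 200, seed = 1)
#' @export
run_loose_additivity_study <- function(spec_IE,
                                       noise_grid = seq(0, 5, by = 0.5),
                                       n_sub = 25, iterations = 10000,
                                       population_n = 1000, seed = 1) {
  stopifnot(inherits(spec_IE, "covariance_spec"))
  if (!is.numeric(noise_grid) || any(noise_grid < 0)) {
    rlang::abort("`noise_grid` must be non-negative noise SDs in degrees.",
                 class = "slopebench_argument_error")
  }
  check_n(n_sub, min = 3L)
  check_n(iterations, min = 1L)
  check_n(population_n, min = 2L)
  base <- make_independent_triad(spec_IE, population_n, derive_seed(seed, 1))
  a_true <- base$total # = implicit + explicit exactly
  draws_list <- vector("list", length(noise_grid))
  rows <- purrr::map_dfr(seq_along(noise_grid), function(g) {
    sig <- noise_grid[g]
    key <- condition_key(sig)
    set.seed(derive_seed(seed, 2, key))
    composite <- if (sig > 0) {
      (base$implicit + stats::rnorm(population_n, 0, sig)) +
        (base$explicit + stats::rnorm(population_n, 0, sig))
    } else {
      base$implicit + base$explicit
    }
    slopes <- numeric(iterations)
    for (it in seq_len(iterations)) {
      set.seed(derive_seed(seed, 3, key, it))
      idx <- sample.int(population_n, n_sub, replace = TRUE)
      slopes[it] <- ols_core(composite[idx], a_true[idx], 0.05)$slope
    }
    draws_list[[g]] <<- tibble::tibble(
      noise_sd = sig, iteration = seq_len(iterations), slope = slopes
    )
    tibble::tibble(
      noise_sd = sig,
      predicted_slope = attenuation_expected_slope(
        spec_IE$sd_x, spec_IE$sd_y, spec_IE$rho, sig, sig
      ),
      mean_slope = mean(slopes),
      median_slope = stats::median(slopes),
      boot_se = stats::sd(slopes),
      q25 = unname(stats::quantile(slopes, 0.25)),
      q75 = unname(stats::quantile(slopes, 0.75))
    )
  })
  attr(rows, "draws") <- dplyr::bind_rows(draws_list)
  attr(rows, "spec") <- spec_IE
  attr(rows, "n_sub") <- n_sub
  attr(rows, "iterations") <- iterations
  attr(rows, "seed") <- seed
  class(rows) <- c("loose_additivity_result", class(rows))
  rows
}

#' Residual fingerprints of the additive combination rule
#'
#' Computes the residual `epsilon = total - implicit - explicit` and its
#' mean plus correlations with the implicit measure, the explicit measure,
#' their product and their sum. Under exact additivity the residual is
#' identically zero (mean and all correlations reported as 0); a
#' multiplicative gating term leaves a residual that covaries with the
#' product, and a saturating output rule leaves residuals that grow more
#' negative with the sum.
#'
#' @param sample A triad tibble (or any data frame with numeric columns
#'   `implicit`, `explicit`, `total`), n >= 3.
#' @return A one-row tibble: `mean_residual` (degrees), `corr_with_I`,
#'   `corr_with_E`, `corr_with_product`, `corr_with_sum`.
#' @examples
#' residual_diagnostics(make_iso_A_scenarios()$constant_total)
#' @export
residual_diagnostics <- function(sample) {
  stopifnot(is.data.frame(sample),
            all(c("implicit", "explicit", "total") %in% names(sample)))
  if (nrow(sample) < 3L) {
    rlang::abort("need at least 3 individuals for residual diagnostics.",
                 class = "slopebench_sample_size_error")
  }
  # recompute the sum before subtracting so additive data give exact zeros
  eps <- sample$total - (sample$implicit + sample$explicit)
  safe_cor <- function(u) {
    if (stats::sd(eps) == 0 || stats::sd(u) == 0) 0 else stats::cor(eps, u)
  }
  tibble::tibble(
    mean_residual = mean(eps),
    corr_with_I = safe_cor(sample$implicit),
    corr_with_E = safe_cor(sample$explicit),
    corr_with_product = safe_cor(sample$implicit * sample$explicit),
    corr_with_sum = safe_cor(sample$implicit + sample$explicit)
  )
}
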