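#' Expected I-on-E slope under subtractive measurement
#'
#' When implicit recalibration is derived by subtraction (I = A - E), the
#' population OLS slope of I on E is fixed by the covariance structure of
#' total adaptation A and the measured component E:
#' \deqn{\beta = \rho_{A,E}\,\sigma_A/\sigma_E - 1.}
#' The classic -1 benchmark is recovered only when A and E are uncorrelated;
#' additivity itself (which holds by construction under subtraction) places
#' no constraint on the slope.
#'
#' @param rho Correlation between total adaptation and the explicit measure.
#' @param sigma_A SD of total adaptation, degrees (> 0).
#' @param sigma_E SD of the explicit measure, degrees (> 0).
#'
#' @return The expected OLS slope (dimensionless).
#' @examples
#' expected_slope_subtractive(rho = 0, sigma_A = 2.5, sigma_E = 2.5)  # -1
#' expected_slope_subtractive(rho = 0.4, sigma_A = 5, sigma_E = 2.5)  # -0.2
#' @seealso [expected_slope_independent()], [run_subtractive_sweep()]
#' @export
expected_slope_subtractive <- function(rho, sigma_A, sigma_E) {
  check_slope_moments(rho, sigma_A, sigma_E)
  rho * sigma_A / sigma_E - 1
}

#' Expected I-on-E slope under independent measurement
#'
#' When implicit and explicit learning are measured independently, the
#' population OLS slope of I on E is
#' \deqn{\beta = \rho_{I,E}\,\sigma_I/\sigma_E,}
#' i.e. the correlation scaled by the SD ratio. Additivity does not
#' constrain either factor, so no slope value confirms or refutes it.
#'
#' @param rho Correlation between the implicit and explicit measures.
#' @param sigma_I SD of the implicit measure, degrees (> 0).
#' @param sigma_E SD of the explicit measure, degrees (> 0).
#'
#' @return The expected OLS slope (dimensionless).
#' @examples
#' expected_slope_independent(rho = -0.6, sigma_I = 1, sigma_E = 2)  # -0.3
#' @seealso [expected_slope_subtractive()], [run_independent_sweep()]
#' @export
expected_slope_independent <- function(rho, sigma_I, sigma_E) {
  check_slope_moments(rho, sigma_I, sigma_E)
  rho * sigma_I / sigma_E
}

check_slope_moments <- function(rho, sd1, sd2) {
  stopifnot(is.numeric(rho), is.numeric(sd1), is.numeric(sd2))
  if (any(sd1 <= 0) || any(sd2 <= 0)) {
    rlang::abort("standard deviations must be strictly positive.",
                 class = "slopebench_domain_error")
  }
  if (any(abs(rho) > 1)) {
    rlang::abort("`rho` must lie in [-1, 1].",
                 class = "slopebench_domain_error")
  }
  invisible(NULL)
}

#' Population slopes implied by the shared-error model
#'
#' Closed-form large-population OLS slopes among the observed (noisy)
#' measures generated by the shared-error model: implicit-on-explicit,
#' explicit-on-total and implicit-on-total, where the observed total is the
#' sum of the two noisy component measures (`A_obs = I_obs + E_obs`).
#'
#' Writing `v = sigma_E^2` and `a = 1 - p_i`, covariance algebra on
#' `E ~ N(mu_E, v)`, `I = p_i (r - E)` plus independent measurement noise
#' with variances `tau_I^2`, `tau_E^2` gives
#' \deqn{\beta_{I\sim E} = -p_i v / (v + \tau_E^2)}
#' \deqn{\beta_{E\sim A} = (a v + \tau_E^2) / (a^2 v + \tau_I^2 + \tau_E^2)}
#' \deqn{\beta_{I\sim A} = (-p_i a v + \tau_I^2) / (a^2 v + \tau_I^2 + \tau_E^2)}
#' These expressions are validated against large-sample simulation in the
#' package test suite.
#'
#' @param params A [shared_error_params()] object.
#'
#' @return A named numeric vector with elements `slope_I_on_E`,
#'   `slope_E_on_A`, `slope_I_on_A`.
#' @examples
#' p <- shared_error_params(r = 30, p_i = 0.65, mu_E = 12, sigma_E = 4,
#'                          tau_I = 2, tau_E = 4)
#' shared_error_expected_slopes(p)  # approx (-0.325, 0.984, 0.016)
#' @export
shared_error_expected_slopes <- function(params) {
  stopifnot(inherits(params, "shared_error_params"))
  v <- params$sigma_E^2
  a <- 1 - params$p_i
  vI <- params$tau_I^2
  vE <- params$tau_E^2
  denom_A <- a^2 * v + vI + vE
  if (denom_A <= 0) {
    rlang::abort(
      "degenerate model: observed total has zero variance (p_i = 1 with no noise).",
      class = "slopebench_domain_error"
    )
  }
  c(
    slope_I_on_E = -params$p_i * v / (v + vE),
    slope_E_on_A = (a * v + vE) / denom_A,
    slope_I_on_A = (-params$p_i * a * v + vI) / denom_A
  )
}

#' Expected attenuation of the loose-additivity slope
#'
#' The "loose additivity" check regresses total adaptation A on the sum of
#' the measured components. When the component measures carry independent
#' Gaussian noise, the composite predictor `I_obs + E_obs` is noisy and the
#' slope is diluted below 1 by the predictor's reliability:
#' \deqn{\beta = V / (V + \tau_I^2 + \tau_E^2), \quad
#'       V = \sigma_I^2 + \sigma_E^2 + 2\rho\,\sigma_I\sigma_E,}
#' where V is the true variance of I + E. Slopes below 1 are therefore
#' expected under exact additivity whenever measurement is imperfect.
#'
#' @param sigma_I,sigma_E True component SDs, degrees (> 0).
#' @param rho Correlation between the true components.
#' @param tau_I,tau_E Measurement-noise SDs, degrees (>= 0).
#'
#' @return The expected OLS slope of A on (I_obs + E_obs), in `[0, 1]`.
#' @examples
#' attenuation_expected_slope(2.5, 2.5, rho = -0.5, tau_I = 2, tau_E = 2)
#' @seealso [run_loose_additivity_study()]
#' @export
attenuation_expected_slope <- function(sigma_I, sigma_E, rho, tau_I, tau_E) {
  check_slope_moments(rho, sigma_I, sigma_E)
  stopifnot(is.numeric(tau_I), is.numeric(tau_E))
  if (any(tau_I < 0) || any(tau_E < 0)) {
    rlang::abort("noise SDs must be non-negative.",
                 class = "slopebench_domain_error")
  }
  v_true <- sigma_I^2 + sigma_E^2 + 2 * rho * sigma_I * sigma_E
  denom <- v_true + tau_I^2 + tau_E^2
  if (any(denom <= 0)) {
    rlang::abort("predictor variance is zero: composite and noise both degenerate.",
                 class = "slopebench_domain_error")
  }
  v_true / denom
}
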