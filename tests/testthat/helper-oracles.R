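# Independent oracles the implementation is checked against.

# Textbook OLS via stats::lm with t-based confint: the reference the
# closed-form engine must reproduce.
lm_oracle <- function(x, y, alpha = 0.05) {
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, level = 1 - alpha)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    se_slope = unname(summary(fit)$coefficients[2, 2]),
    ci_low = ci[2, 1], ci_high = ci[2, 2]
  )
}

# Two-pass covariance-ratio slope, independent of the package's algebra.
cov_ratio_oracle <- function(x, y) {
  stats::cov(x, y) / stats::var(x)
}

# Large-sample simulated slopes for the shared-error model: the oracle
# behind the closed forms in shared_error_expected_slopes().
simulate_shared_error_slopes <- function(params, n = 1e6, seed = 1) {
  pop <- make_shared_error_population(params, n, seed)
  fits <- list(
    I_on_E = fit_slope(pop$explicit, pop$implicit),
    E_on_A = fit_slope(pop$total, pop$explicit),
    I_on_A = fit_slope(pop$total, pop$implicit)
  )
  list(
    slopes = vapply(fits, `[[`, numeric(1), "slope"),
    ses = vapply(fits, `[[`, numeric(1), "se_slope")
  )
}

random_shared_error_params <- function() {
  shared_error_params(
    r = stats::runif(1, 10, 45),
    p_i = stats::runif(1, 0.05, 0.95),
    mu_E = stats::runif(1, 0, 20),
    sigma_E = stats::runif(1, 1, 6),
    tau_I = stats::runif(1, 0, 4),
    tau_E = stats::runif(1, 0, 5)
  )
}
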