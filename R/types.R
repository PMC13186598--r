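#' Bivariate moment specification for two learning measures
#'
#' A `covariance_spec` fixes the first and second moments of a bivariate
#' normal population over two learning measures (degrees of hand angle):
#' means, standard deviations and the correlation `rho`. Which two measures
#' the axes stand for depends on the consumer: the subtractive generator
#' reads `(x, y)` as (total adaptation A, explicit strategy E); the
#' independent-measurement generator reads them as (implicit I, explicit E).
#'
#' @param mean_x,mean_y Population means, degrees.
#' @param sd_x,sd_y Population standard deviations, degrees; must be > 0.
#' @param rho Pearson correlation between the two measures, in `[-1, 1]`.
#'
#' @return An object of class `"covariance_spec"`: a named list with the
#'   five moments.
#' @examples
#' # moments approximating a typical aim-report study arm
#' covariance_spec(mean_x = 25, mean_y = 5, sd_x = 2.5, sd_y = 2.5, rho = 0)
#' @export
covariance_spec <- function(mean_x, mean_y, sd_x, sd_y, rho) {
  stopifnot(
    is.numeric(mean_x), length(mean_x) == 1L, is.finite(mean_x),
    is.numeric(mean_y), length(mean_y) == 1L, is.finite(mean_y),
    is.numeric(sd_x), length(sd_x) == 1L, is.finite(sd_x),
    is.numeric(sd_y), length(sd_y) == 1L, is.finite(sd_y),
    is.numeric(rho), length(rho) == 1L, is.finite(rho)
  )
  if (sd_x <= 0 || sd_y <= 0) {
    rlang::abort("`sd_x` and `sd_y` must be strictly positive (degrees).",
                 class = "slopebench_domain_error")
  }
  if (abs(rho) > 1) {
    rlang::abort("`rho` must lie in [-1, 1].",
                 class = "slopebench_domain_error")
  }
  structure(
    list(mean_x = mean_x, mean_y = mean_y, sd_x = sd_x, sd_y = sd_y,
         rho = rho),
    class = "covariance_spec"
  )
}

#' @export
print.covariance_spec <- function(x, ...) {
  cat(sprintf(
    "<covariance_spec> mean = (%g, %g) deg, sd = (%g, %g) deg, rho = %g\n",
    x$mean_x, x$mean_y, x$sd_x, x$sd_y, x$rho
  ))
  invisible(x)
}

#' Parameters of the shared-error generative model
#'
#' In the shared-error model the explicit strategy E is drawn from a normal
#' distribution and the implicit system recalibrates in proportion to the
#' residual rotation left uncompensated by strategy: `I = p_i * (r - E)`.
#' Measurement adds independent Gaussian noise to each component; the
#' observed total is the sum of the two noisy measures.
#'
#' @param r Rotation magnitude, degrees.
#' @param p_i Implicit steady-state capacity, dimensionless in `[0, 1]`.
#' @param mu_E Mean explicit strategy, degrees.
#' @param sigma_E SD of explicit strategy, degrees; must be > 0.
#' @param tau_I Measurement-noise SD added to implicit, degrees; >= 0.
#' @param tau_E Measurement-noise SD added to explicit, degrees; >= 0.
#'
#' @return An object of class `"shared_error_params"`.
#' @examples
#' shared_error_params(r = 30, p_i = 0.65, mu_E = 12, sigma_E = 4,
#'                     tau_I = 2, tau_E = 4)
#' @export
shared_error_params <- function(r, p_i, mu_E, sigma_E, tau_I = 0, tau_E = 0) {
  stopifnot(
    is.numeric(r), length(r) == 1L, is.finite(r),
    is.numeric(p_i), length(p_i) == 1L, is.finite(p_i),
    is.numeric(mu_E), length(mu_E) == 1L, is.finite(mu_E),
    is.numeric(sigma_E), length(sigma_E) == 1L, is.finite(sigma_E),
    is.numeric(tau_I), length(tau_I) == 1L, is.finite(tau_I),
    is.numeric(tau_E), length(tau_E) == 1L, is.finite(tau_E)
  )
  if (p_i < 0 || p_i > 1) {
    rlang::abort("`p_i` must lie in [0, 1].",
                 class = "slopebench_domain_error")
  }
  if (sigma_E <= 0) {
    rlang::abort("`sigma_E` must be strictly positive (degrees).",
                 class = "slopebench_domain_error")
  }
  if (tau_I < 0 || tau_E < 0) {
    rlang::abort("noise SDs `tau_I`, `tau_E` must be non-negative.",
                 class = "slopebench_domain_error")
  }
  structure(
    list(r = r, p_i = p_i, mu_E = mu_E, sigma_E = sigma_E,
         tau_I = tau_I, tau_E = tau_E),
    class = "shared_error_params"
  )
}

#' @export
print.shared_error_params <- function(x, ...) {
  cat(sprintf(
    paste0("<shared_error_params> r = %g deg, p_i = %g, ",
           "E ~ N(%g, %g) deg, noise SD (I, E) = (%g, %g) deg\n"),
    x$r, x$p_i, x$mu_E, x$sigma_E, x$tau_I, x$tau_E
  ))
  invisible(x)
}
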