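# Bare-metal OLS used inside the Monte Carlo loops: slope as the
# covariance-to-variance ratio, t-based CI with n - 2 df. Returns a plain
# list; fit_slope() wraps it in the user-facing class.
ols_core <- function(x, y, alpha) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx * dx)
  slope <- sum(dx * (y - my)) / sxx
  intercept <- my - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  half <- stats::qt(1 - alpha / 2, df) * se
  list(slope = slope, intercept = intercept, se_slope = se,
       se_intercept = sqrt(rss / df * (1 / n + mx^2 / sxx)),
       ci_low = slope - half, ci_high = slope + half,
       sigma = sqrt(rss / df), n = n, df = df)
}

#' Fit an OLS slope with a t-based confidence interval
#'
#' Ordinary least squares of `y` on `x`. The slope is the ratio of the
#' sample covariance of `x` and `y` to the sample variance of `x`; the
#' two-sided `(1 - alpha)` confidence interval uses the t distribution
#' with `n - 2` degrees of freedom. Exactly collinear data give a
#' zero-width interval collapsed onto the point estimate.
#'
#' @param x Predictor, degrees; must have positive variance.
#' @param y Outcome, degrees; same length as `x`.
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#'
#' @return An object of class `"slope_fit"`: a list with elements `slope`,
#'   `intercept`, `se_slope`, `ci_low`, `ci_high`, `n`, `alpha`.
#' @examples
#' fit <- fit_slope(c(0, 1, 2, 3), c(1, 2, 2, 4))
#' fit$slope  # 0.9
#' tidy(fit)
#' @export
fit_slope <- function(x, y, alpha = 0.05) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have the same length.",
                 class = "slopebench_argument_error")
  }
  if (length(x) < 3L) {
    rlang::abort("need at least 3 observations for a finite slope CI.",
                 class = "slopebench_sample_size_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be a single value in (0, 1).",
                 class = "slopebench_argument_error")
  }
  if (stats::var(x) == 0) {
    rlang::abort("predictor `x` is constant: slope undefined.",
                 class = "slopebench_degenerate_predictor_error")
  }
  out <- ols_core(x, y, alpha)
  out$alpha <- alpha
  structure(out, class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> slope = %.4f [%.4f, %.4f] (%.0f%% CI), intercept = %.4f deg, n = %d\n",
    x$slope, x$ci_low, x$ci_high, 100 * (1 - x$alpha), x$intercept, x$n
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a slope fit into one row per coefficient
#'
#' @param x A [fit_slope()] result.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  half_int <- stats::qt(1 - x$alpha / 2, x$df) * x$se_intercept
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope),
    conf.low = c(x$intercept - half_int, x$ci_low),
    conf.high = c(x$intercept + half_int, x$ci_high)
  )
}

#' One-row summary of a slope fit
#'
#' @param x A [fit_slope()] result.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `se_slope`, `ci_low`, `ci_high`,
#'   `intercept`, `sigma`, `n`, `alpha`.
#' @method glance slope_fit
#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, se_slope = x$se_slope,
    ci_low = x$ci_low, ci_high = x$ci_high,
    intercept = x$intercept, sigma = x$sigma,
    n = x$n, alpha = x$alpha
  )
}

#' Does a slope fit reject a benchmark value?
#'
#' The benchmark test used throughout the sweep experiments: a benchmark
#' slope is rejected when it falls outside the fit's confidence interval.
#' A benchmark exactly on a CI boundary is \emph{not} rejected; for exact
#' collinear fits (zero-width CI) rejection is strict inequality against
#' the point estimate.
#'
#' @param fit A [fit_slope()] result.
#' @param benchmark Benchmark slope value (e.g. -1 for the subtractive
#'   tradeoff benchmark, 0 under independent measurement).
#' @return `TRUE` if the benchmark lies outside the CI.
#' @examples
#' fit <- fit_slope(rnorm(20), rnorm(20))
#' benchmark_reject(fit, -1)
#' @export
benchmark_reject <- function(fit, benchmark) {
  stopifnot(inherits(fit, "slope_fit"), is.numeric(benchmark),
            length(benchmark) == 1L)
  benchmark < fit$ci_low || benchmark > fit$ci_high
}
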