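#' Derive a reproducible sub-seed from a master seed
#'
#' Experiments derive one independent RNG substream per condition and
#' iteration by mixing the master seed with integer keys through a
#' Lehmer-style multiplicative congruential step modulo 2^31 - 1.
#' Conditions are keyed on their parameter values (not grid position), so
#' per-condition results do not depend on grid order, and extending
#' `iterations` leaves earlier iterations' draws unchanged.
#'
#' @param master Master seed (integer-valued).
#' @param ... Non-negative integer keys (condition key, iteration index, ...).
#' @return An integer seed in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(42, 3, 17)
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- as.numeric(master) %% m
  for (k in c(...)) {
    # s < 2^31 and 48271 * 2^31 + k < 2^53: exact in double arithmetic
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(s)
}

# Integer key for a real-valued condition parameter (resolution 1e-6).
condition_key <- function(value) {
  as.numeric(round((value + 100) * 1e6))
}

# Fast internal sampler: plain list, no tibble overhead. Factorizes the
# 2x2 covariance as x = sd_x z1, y = sd_y (rho z1 + sqrt(1-rho^2) z2);
# |rho| = 1 is an exact linear map of a single draw.
sample_bivariate_core <- function(spec, n, seed) {
  set.seed(seed)
  z1 <- stats::rnorm(n)
  x <- spec$mean_x + spec$sd_x * z1
  if (abs(spec$rho) == 1) {
    y <- spec$mean_y + spec$sd_y * sign(spec$rho) * z1
  } else {
    z2 <- stats::rnorm(n)
    y <- spec$mean_y +
      spec$sd_y * (spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)
  }
  list(x = x, y = y)
}

#' Sample paired measures from a bivariate normal population
#'
#' Draws `n` pairs whose population law is bivariate normal with the
#' moments in `spec`. Sampling uses a 2x2 factorization of the covariance
#' matrix; perfectly correlated specs (`|rho| = 1`) are handled as an exact
#' linear map of a single standard-normal draw rather than a near-singular
#' factorization. Identical `(spec, n, seed)` give bit-identical output.
#'
#' @param spec A [covariance_spec()].
#' @param n Number of pairs (>= 2).
#' @param seed Integer seed; the function calls [set.seed()].
#'
#' @return A tibble with numeric columns `x` and `y` (degrees).
#' @examples
#' sample_bivariate(covariance_spec(25, 5, 2.5, 2.5, 0), n = 5, seed = 1)
#' @export
sample_bivariate <- function(spec, n, seed) {
  stopifnot(inherits(spec, "covariance_spec"))
  check_n(n, min = 2L)
  xy <- sample_bivariate_core(spec, n, seed)
  tibble::tibble(x = xy$x, y = xy$y)
}

check_n <- function(n, min) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < min ||
      n != round(n)) {
    rlang::abort(sprintf("`n` must be a whole number >= %d.", min),
                 class = "slopebench_argument_error")
  }
  invisible(NULL)
}

new_triad <- function(implicit, explicit, total, provenance, seed) {
  out <- tibble::tibble(
    implicit = implicit, explicit = explicit, total = total
  )
  attr(out, "provenance") <- provenance
  attr(out, "seed") <- seed
  class(out) <- c("triad_sample", class(out))
  out
}

#' @export
print.triad_sample <- function(x, ...) {
  cat(sprintf("<triad_sample> provenance = %s, seed = %s, n = %d (degrees)\n",
              attr(x, "provenance"), format(attr(x, "seed")), nrow(x)))
  NextMethod()
}

#' Provenance tag of a triad sample
#'
#' @param x A triad tibble from one of the generators.
#' @return `"subtractive"`, `"independent"` or `"shared_error"`.
#' @export
triad_provenance <- function(x) attr(x, "provenance")

#' Generate a subtractive-logic population (I derived as A - E)
#'
#' Samples total adaptation A and explicit strategy E from the bivariate
#' normal in `spec_AE` (`x` = A, `y` = E) and derives the implicit measure
#' by subtraction, `I = A - E` — the construction used by aim-report
#' studies. Additivity `total = implicit + explicit` holds as an algebraic
#' identity in the output.
#'
#' @param spec_AE A [covariance_spec()] over (A, E): `x` is total
#'   adaptation, `y` is explicit strategy.
#' @param n Number of simulated participants (>= 2).
#' @param seed Integer seed.
#'
#' @return A `triad_sample` tibble with columns `implicit`, `explicit`,
#'   `total` (degrees) and provenance `"subtractive"`.
#' @examples
#' make_subtractive_triad(covariance_spec(25, 5, 2.5, 2.5, 0.5), 25, seed = 1)
#' @export
make_subtractive_triad <- function(spec_AE, n, seed) {
  stopifnot(inherits(spec_AE, "covariance_spec"))
  check_n(n, min = 2L)
  ae <- sample_bivariate_core(spec_AE, n, seed)
  implicit <- ae$x - ae$y
  # store the total as the recomposed sum so the additive identity holds
  # bit-exactly; it differs from the sampled A by at most one ulp
  new_triad(
    implicit = implicit, explicit = ae$y, total = implicit + ae$y,
    provenance = "subtractive", seed = seed
  )
}

#' Generate an independently measured additive population
#'
#' Samples implicit and explicit learning from the bivariate normal in
#' `spec_IE` (`x` = I, `y` = E) and enforces additivity by constructing the
#' total as their sum: `total = implicit + explicit` exactly. The total is
#' derived, never sampled.
#'
#' @param spec_IE A [covariance_spec()] over (I, E): `x` is implicit,
#'   `y` is explicit.
#' @param n Number of simulated participants (>= 2).
#' @param seed Integer seed.
#'
#' @return A `triad_sample` tibble with provenance `"independent"`.
#' @examples
#' make_independent_triad(covariance_spec(10, 12, 2, 4, -0.6), 25, seed = 1)
#' @export
make_independent_triad <- function(spec_IE, n, seed) {
  stopifnot(inherits(spec_IE, "covariance_spec"))
  check_n(n, min = 2L)
  ie <- sample_bivariate_core(spec_IE, n, seed)
  new_triad(
    implicit = ie$x, explicit = ie$y, total = ie$x + ie$y,
    provenance = "independent", seed = seed
  )
}

# Core shared-error draw used by both the public generator and the
# experiment drivers.
shared_error_core <- function(params, n, seed) {
  set.seed(seed)
  e_true <- stats::rnorm(n, params$mu_E, params$sigma_E)
  i_true <- params$p_i * (params$r - e_true)
  i_obs <- if (params$tau_I > 0) i_true + stats::rnorm(n, 0, params$tau_I) else i_true
  e_obs <- if (params$tau_E > 0) e_true + stats::rnorm(n, 0, params$tau_E) else e_true
  list(implicit = i_obs, explicit = e_obs)
}

#' Generate a shared-error model population
#'
#' Simulates a steady-state population in which the explicit strategy is
#' drawn as `E ~ N(mu_E, sigma_E)` and the implicit system recalibrates in
#' proportion to the residual error the strategy leaves uncorrected,
#' `I = p_i * (r - E)`. Independent Gaussian measurement noise (SDs
#' `tau_I`, `tau_E`) is added to each component; the observed total is the
#' sum of the noisy measures, so `total = implicit + explicit` holds
#' exactly in the output even though both measures are noisy.
#'
#' @param params A [shared_error_params()] object.
#' @param n Number of simulated participants (>= 2).
#' @param seed Integer seed.
#'
#' @return A `triad_sample` tibble with provenance `"shared_error"`.
#' @examples
#' p <- shared_error_params(r = 30, p_i = 0.65, mu_E = 12, sigma_E = 4,
#'                          tau_I = 2, tau_E = 4)
#' make_shared_error_population(p, n = 1000, seed = 1)
#' @export
make_shared_error_population <- function(params, n, seed) {
  stopifnot(inherits(params, "shared_error_params"))
  check_n(n, min = 2L)
  obs <- shared_error_core(params, n, seed)
  new_triad(
    implicit = obs$implicit, explicit = obs$explicit,
    total = obs$implicit + obs$explicit,
    provenance = "shared_error", seed = seed
  )
}

#' Three-person demonstrations that covariance is independent of additivity
#'
#' Returns three tiny populations, each satisfying `total = implicit +
#' explicit` exactly for every individual, whose implicit-explicit
#' correlations are nonetheless -1, +1 and -1:
#' \describe{
#'   \item{constant_total}{total adaptation fixed, proportions vary: all
#'     points sit on one iso-A contour, correlation -1.}
#'   \item{scaled_components}{total varies, proportions fixed: both
#'     components grow together, correlation +1.}
#'   \item{shifting_tradeoff}{total varies and the mix shifts: points span
#'     several iso-A contours yet correlate at -1.}
#' }
#' Bar heights are illustrative integers; the contract is the additive
#' identity and the three correlations.
#'
#' @return A named list of three `triad_sample` tibbles (3 rows each).
#' @examples
#' purrr::map_dbl(make_iso_A_scenarios(), ~ cor(.x$implicit, .x$explicit))
#' @export
make_iso_A_scenarios <- function() {
  list(
    constant_total = new_triad(
      implicit = c(15, 12, 9), explicit = c(5, 8, 11),
      total = c(20, 20, 20), provenance = "independent", seed = NA_integer_
    ),
    scaled_components = new_triad(
      implicit = c(9, 12, 15), explicit = c(6, 8, 10),
      total = c(15, 20, 25), provenance = "independent", seed = NA_integer_
    ),
    shifting_tradeoff = new_triad(
      implicit = c(12, 8, 4), explicit = c(4, 6, 8),
      total = c(16, 14, 12), provenance = "independent", seed = NA_integer_
    )
  )
}

#' Write a triad sample to CSV
#'
#' Columns are `implicit_deg`, `explicit_deg`, `total_deg`, `provenance`,
#' `seed`; a `#` comment line records the units. Read back with
#' `readr::read_csv(path, comment = "#")`.
#'
#' @param triad A `triad_sample` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_triad_csv <- function(triad, path) {
  stopifnot(inherits(triad, "triad_sample"))
  out <- tibble::tibble(
    implicit_deg = triad$implicit,
    explicit_deg = triad$explicit,
    total_deg = triad$total,
    provenance = triad_provenance(triad),
    seed = attr(triad, "seed")
  )
  writeLines("# units: implicit_deg, explicit_deg, total_deg in degrees of hand angle",
             path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
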