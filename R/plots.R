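#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Shared look: expected-slope overlays in orange, benchmarks dashed black,
# mirroring the conventions of the figures the experiments emulate.

sweep_panels <- function(df, benchmark, alpha) {
  has_ratio <- "sd_ratio" %in% names(df) && dplyr::n_distinct(df$sd_ratio) > 1
  p_slope <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rho))
  if (is.finite(benchmark)) {
    p_slope <- p_slope +
      ggplot2::geom_hline(yintercept = benchmark, linetype = "dashed")
  }
  p_slope <- p_slope +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_slope),
                       colour = "darkorange", linewidth = 1) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$mean_slope,
      ymin = .data$mean_slope - .data$sd_slope,
      ymax = .data$mean_slope + .data$sd_slope
    ), size = 0.3) +
    ggplot2::labs(x = expression(rho), y = "slope",
                  subtitle = "mean simulated slope (± SD) vs analytic expectation") +
    ggplot2::theme_minimal()
  p_rej <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rho,
                                            y = .data$rejection_rate)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = expression(rho), y = "rejection rate",
                  subtitle = "benchmark rejection rate") +
    ggplot2::theme_minimal()
  if (has_ratio) {
    fac <- ggplot2::facet_wrap(ggplot2::vars(.data$sd_ratio),
                               labeller = ggplot2::label_both)
    p_slope <- p_slope + fac
    p_rej <- p_rej + fac
  }
  patchwork::wrap_plots(p_slope, p_rej, ncol = 1)
}

#' Plot a sweep result
#'
#' Two stacked panels: mean simulated slope against the analytic expected
#' slope (orange) with the benchmark as a dashed line, and the benchmark
#' rejection rate with the nominal level dashed.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A patchwork of two ggplots.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  sweep_panels(tibble::as_tibble(object), attr(object, "benchmark"),
               attr(object, "alpha"))
}

bootstrap_hist <- function(long, pop_df) {
  ggplot2::ggplot(long, ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(data = pop_df,
                        ggplot2::aes(xintercept = .data$population_slope),
                        colour = "darkorange", linewidth = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$relationship), scales = "free_x") +
    ggplot2::labs(x = "bootstrap slope", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap slope distributions from a shared-error study
#'
#' Histograms of the three bootstrap slope distributions with the
#' population slopes marked in orange.
#'
#' @param object A `bootstrap_slopes` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bootstrap_slopes
#' @export
autoplot.bootstrap_slopes <- function(object, ...) {
  pop <- attr(object, "population_slopes")
  long <- tidyr::pivot_longer(tibble::as_tibble(object), cols = -"iteration",
                              names_to = "relationship", values_to = "slope")
  pop_df <- tibble::tibble(relationship = names(pop),
                           population_slope = unname(pop))
  bootstrap_hist(long, pop_df)
}

attenuation_plot <- function(draws, pred_df) {
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$noise_sd,
                                      y = .data$slope,
                                      group = .data$noise_sd)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.1, fill = "grey85") +
    ggplot2::geom_line(data = pred_df,
                       ggplot2::aes(y = .data$predicted_slope, group = 1),
                       colour = "darkorange", linewidth = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "measurement-noise SD (deg)",
                  y = "slope of A on (I_obs + E_obs)") +
    ggplot2::theme_minimal()
}

#' Plot a loose-additivity attenuation study
#'
#' Boxplots of the bootstrap slope distributions per noise level with the
#' closed-form attenuation prediction overlaid in orange and the identity
#' slope dashed.
#'
#' @param object A `loose_additivity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loose_additivity_result
#' @export
autoplot.loose_additivity_result <- function(object, ...) {
  attenuation_plot(attr(object, "draws"),
                   tibble::as_tibble(object)[, c("noise_sd", "predicted_slope")])
}

#' Plot the iso-A demonstration scenarios
#'
#' Implicit against explicit for the three tiny populations of
#' [make_iso_A_scenarios()], with dashed iso-A contours (I + E constant)
#' through each individual.
#'
#' @return A ggplot.
#' @export
plot_iso_A_scenarios <- function() {
  scen <- make_iso_A_scenarios()
  df <- purrr::imap_dfr(scen, ~ dplyr::mutate(tibble::as_tibble(.x),
                                              scenario = .y))
  df$scenario <- factor(df$scenario, levels = names(scen))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$explicit, y = .data$implicit)) +
    ggplot2::geom_abline(ggplot2::aes(intercept = .data$total, slope = -1),
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
    ggplot2::labs(x = "explicit (deg)", y = "implicit (deg)") +
    ggplot2::theme_minimal()
}

#' Render figure files from result CSVs
#'
#' Reads each CSV written by the experiment writers, infers its kind from
#' the column schema and writes a PNG figure next to it (or into
#' `out_dir`): sweep CSVs become slope/rejection panels, shared-error CSVs
#' become bootstrap histograms with population-slope markers, and
#' loose-additivity CSVs become boxplot distributions with the predicted
#' attenuation curve.
#'
#' @param paths Character vector of result CSV paths.
#' @param out_dir Output directory; default alongside each CSV.
#' @param style Plot style; only `"default"` is defined.
#' @return Paths of the written image files, invisibly.
#' @export
render_figures <- function(paths, out_dir = NULL, style = "default") {
  style <- match.arg(style)
  written <- purrr::map_chr(paths, function(path) {
    df <- read_result_csv(path)
    p <- figure_for_csv(df, path)
    dir <- if (is.null(out_dir)) dirname(path) else out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out <- file.path(dir, paste0(tools::file_path_sans_ext(basename(path)),
                                 ".png"))
    ggplot2::ggsave(out, p, width = 7, height = 6, dpi = 150)
    out
  })
  invisible(written)
}

figure_for_csv <- function(df, path) {
  cols <- names(df)
  if (all(c("rho", "statistic", "value") %in% cols)) {
    id_cols <- intersect(c("rho", "sd_ratio"), cols)
    wide <- tidyr::pivot_wider(df, id_cols = dplyr::all_of(id_cols),
                               names_from = "statistic",
                               values_from = "value")
    return(sweep_panels(wide, benchmark = NA_real_, alpha = 0.05))
  }
  if (all(c("relationship", "iteration", "slope") %in% cols)) {
    pop_df <- dplyr::distinct(df, .data$relationship, .data$population_slope)
    return(bootstrap_hist(df, pop_df))
  }
  if (all(c("noise_sd", "predicted_slope", "slope") %in% cols)) {
    pred_df <- dplyr::distinct(df, .data$noise_sd, .data$predicted_slope)
    return(attenuation_plot(df, pred_df))
  }
  rlang::abort(sprintf("cannot infer figure type from columns of %s", path),
               class = "slopebench_io_error")
}
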