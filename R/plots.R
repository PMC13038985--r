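#' Plot longitudinal microstructure profiles
#'
#' Porosity and volume-weighted mean canal diameter versus longitudinal
#' position, one line per sampling depth, direction-averaged.
#'
#' @param object A `bone_profiles` object from [assemble_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bone_profiles
#' @export
autoplot.bone_profiles <- function(object, ...) {
  df <- object$longitudinal |>
    tidyr::pivot_longer(c("porosity", "mean_diameter"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         porosity = "porosity (fraction)",
                                         mean_diameter = "canal diameter (um)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position / 1000, y = .data$value,
                                   colour = factor(.data$depth))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "position from distal end (mm)", y = NULL,
                  colour = "depth (um)") +
    ggplot2::theme_minimal()
}

#' Plot cortical thickness along the bone
#'
#' @param profiles A `bone_profiles` object.
#' @return A ggplot object.
#' @export
plot_cortical_thickness <- function(profiles) {
  ggplot2::ggplot(profiles$thickness,
                  ggplot2::aes(x = .data$position / 1000,
                               y = .data$thickness_mm,
                               colour = .data$direction)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_line(data = profiles$thickness_mean, colour = "black",
                       linewidth = 1) +
    ggplot2::labs(x = "position from distal end (mm)",
                  y = "cortical thickness (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stress-strain curve with its bilinear fit
#'
#' @param curve A tibble with `strain`, `stress`.
#' @param fit A [fit_bilinear()] result.
#' @return A ggplot object.
#' @export
plot_bilinear_fit <- function(curve, fit) {
  b <- fit$breakpoint_strain
  pre <- curve[curve$strain <= max(curve$strain[which.max(curve$stress)]), ]
  grid <- tibble(strain = seq(0, max(pre$strain), length.out = 200))
  grid$stress <- fit$intercept + ifelse(grid$strain <= b,
                                        fit$modulus1 * grid$strain,
                                        fit$modulus1 * b +
                                          fit$modulus2 * (grid$strain - b))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$strain, y = .data$stress)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_vline(xintercept = b, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "strain", y = "stress (MPa)") +
    ggplot2::theme_minimal()
}

#' Scatter plots of microstructure against modulus
#'
#' Mirrors the study's correlation panels: porosity and canal diameter against
#' modulus 1 and modulus 2, with the Pearson r annotated.
#'
#' @param object A `study_report` from [summarize_study()].
#' @param paired The paired table the report was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, paired, ...) {
  df <- paired |>
    tidyr::pivot_longer(dplyr::any_of(c("porosity", "mean_diameter")),
                        names_to = "structure_var",
                        values_to = "structure_value") |>
    tidyr::pivot_longer(dplyr::any_of(c("modulus1", "modulus2")),
                        names_to = "modulus_var", values_to = "modulus_value")
  ann <- object$correlations |>
    dplyr::filter(.data$scope == "pooled") |>
    dplyr::mutate(structure_var = .data$var_x, modulus_var = .data$var_y,
                  label = sprintf("r = %.3f, p = %.3g", .data$r, .data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$structure_value,
                                   y = .data$modulus_value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$label),
                       x = -Inf, y = -Inf, hjust = -0.05, vjust = -0.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_grid(modulus_var ~ structure_var, scales = "free") +
    ggplot2::labs(x = "microstructure", y = "modulus (MPa)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
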