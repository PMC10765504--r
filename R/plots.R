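#' Plot growth curves with fitted logistics
#'
#' Observed abundance per bottle on a log10 axis, with the fitted logistic
#' trajectory and the stationary onset (`2 t_mid`, dashed) overlaid when
#' `fits` is supplied.
#'
#' @param series An incubation series tibble.
#' @param fits Optional [fit_growth()] result (with its `fit` list-column).
#' @param analyte Abundance analyte; default `"PA"`.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(series, fits = NULL, analyte = "PA") {
  dat <- series |>
    filter(.data$analyte == !!analyte, .data$qc_flag == "ok")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_days, y = .data$value,
                                         colour = .data$treatment,
                                         shape = .data$bottle)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (d)", y = paste0(analyte, " (", dat$unit[1], ")"),
                  colour = "Treatment", shape = "Bottle") +
    ggplot2::theme_minimal()
  if (!is.null(fits) && "fit" %in% names(fits)) {
    grid <- purrr::pmap(list(fits$treatment, fits$bottle, fits$fit),
                        function(tr, bo, f) {
                          t <- seq(min(f$times), max(f$times), length.out = 100)
                          tibble(treatment = tr, bottle = bo, time_days = t,
                                 value = f$K /
                                   (1 + (f$K - f$N0) / f$N0 * exp(-f$r * t)))
                        }) |> bind_rows()
    p <- p +
      ggplot2::geom_line(data = grid, alpha = 0.7) +
      ggplot2::geom_vline(
        data = distinct(fits, .data$treatment, .data$t_stationary),
        ggplot2::aes(xintercept = .data$t_stationary,
                     colour = .data$treatment),
        linetype = "dashed", show.legend = FALSE)
  }
  p
}

#' @export
autoplot.growth_fit <- function(object, ...) {
  obs <- tibble(time_days = object$times, value = object$abundances)
  t <- seq(min(object$times), max(object$times), length.out = 200)
  line <- tibble(time_days = t,
                 value = object$K / (1 + (object$K - object$N0) / object$N0 *
                                       exp(-object$r * t)))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_days, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$t_stationary,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (d)", y = "Abundance (cells L-1)") +
    ggplot2::theme_minimal()
}

#' Plot an analyte time series by treatment
#'
#' @param series An incubation series tibble.
#' @param analyte Analyte to plot; default `"DOC"`.
#' @return A ggplot object.
#' @export
plot_analyte <- function(series, analyte = "DOC") {
  dat <- filter(series, .data$analyte == !!analyte)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_days, y = .data$value,
                                    colour = .data$treatment,
                                    shape = .data$qc_flag,
                                    group = interaction(.data$treatment,
                                                        .data$bottle))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = filter(dat, .data$qc_flag == "ok")) +
    ggplot2::labs(x = "Time (d)", y = paste0(analyte, " (", dat$unit[1], ")"),
                  colour = "Treatment", shape = "QC") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of compound-class peak-area fractions
#'
#' @param fractions The `class_fractions` tibble from the metabolome stage
#'   (columns `sample_id`, `class`, `fraction`).
#' @return A ggplot object.
#' @export
plot_class_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Peak-area fraction", fill = "Class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Stacked bar chart of family-level relative abundances
#'
#' @param fractions Long tibble from [aggregate_taxa()] (`sample_id`,
#'   `group`, `fraction`).
#' @return A ggplot object.
#' @export
plot_community <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                               fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of ASVs", fill = "Family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
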