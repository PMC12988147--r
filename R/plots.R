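#' Plot a fitted lifespan trajectory
#'
#' @param object A `trajectory_fit`.
#' @param ... Unused.
#' @return A ggplot of the fitted curve over age.
#' @method autoplot trajectory_fit
#' @export
autoplot.trajectory_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$fitted)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = "Age (years)",
                  y = object$metric %||% "value",
                  title = object$modality) +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap derivative band and detected inflection age
#'
#' @param object An `inflection_result`.
#' @param ... Unused.
#' @return A ggplot of the derivative CI over age with the inflection age
#'   marked.
#' @method autoplot inflection_result
#' @export
autoplot.inflection_result <- function(object, ...) {
  ci <- attr(object, "ci")
  fit <- attr(object, "fit")
  d <- dplyr::mutate(ci, deriv = fit$deriv)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$deriv), colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Age (years)", y = "First derivative") +
    ggplot2::theme_minimal()
  if (!is.na(object$inflection_age[1])) {
    p <- p + ggplot2::geom_vline(xintercept = object$inflection_age[1],
                                 colour = "#d95f02", linetype = 3)
  }
  p
}

#' Plot true versus predicted age
#'
#' @param object An `age_prediction_run`.
#' @param corrected Plot bias-corrected predictions if available.
#' @param ... Unused.
#' @return A ggplot scatter with the identity line.
#' @method autoplot age_prediction_run
#' @export
autoplot.age_prediction_run <- function(object, corrected = FALSE, ...) {
  d <- object$predictions
  ycol <- if (corrected && "corrected" %in% names(d)) "corrected" else "predicted"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true, y = .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Chronological age (years)",
                  y = paste0(ycol, " age (years)")) +
    ggplot2::theme_minimal()
}

#' Plot VIP scores of a PLS model
#'
#' @param object A `pls_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart with the VIP = 1 significance line.
#' @method autoplot pls_fit
#' @export
autoplot.pls_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$predictor, .data$VIP),
                                  y = .data$VIP,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d95f02",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "VIP") +
    ggplot2::theme_minimal()
}

#' VIP significance grid across outcomes
#'
#' @param grid Tibble from [cognition_models()].
#' @return A ggplot tile grid (outcome x predictor), significant cells
#'   filled.
#' @export
plot_vip_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$predictor, y = .data$outcome,
                                     fill = .data$VIP)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_point(data = dplyr::filter(grid, .data$significant),
                        shape = 8, size = 1.5) +
    ggplot2::scale_fill_gradient(low = "grey90", high = "#d95f02") +
    ggplot2::labs(x = NULL, y = NULL, fill = "VIP") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
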