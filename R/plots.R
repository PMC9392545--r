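#' Plot a beta profile along the virtual line
#'
#' Group-mean beta per ROI index and condition with a standard-error
#' ribbon; vertical dashed lines mark the two anchor ROIs.
#'
#' @param profile Profile tibble ([roi_profile()]).
#' @param anchors ROI indices of the two peaks (default 16 and 36).
#' @param conditions Conditions to show (default: all).
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, anchors = c(16, 36), conditions = NULL) {
  if (!is.null(conditions)) {
    profile <- dplyr::filter(profile, .data$condition %in% conditions)
  }
  summ <- profile |>
    dplyr::group_by(.data$roi, .data$condition) |>
    dplyr::summarise(mean = mean(.data$beta),
                     se = stats::sd(.data$beta) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$roi, .data$mean,
                                     colour = .data$condition,
                                     fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = anchors, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "ROI index (1-based along the virtual line)",
                  y = "beta (response units)",
                  colour = "condition", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot selectivity along the virtual line
#'
#' @param sel Selectivity tibble ([selectivity()]).
#' @param anchors Anchor ROI indices.
#' @return A ggplot object.
#' @export
plot_selectivity <- function(sel, anchors = c(16, 36)) {
  summ <- sel |>
    dplyr::mutate(pair = paste(.data$preferred, "-", .data$nonpreferred)) |>
    dplyr::group_by(.data$roi, .data$pair) |>
    dplyr::summarise(mean = mean(.data$selectivity), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$roi, .data$mean,
                                     colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = anchors, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "ROI index", y = "selectivity (response units)",
                  colour = "pair") +
    ggplot2::theme_minimal()
}

#' Plot classification accuracy along the virtual line
#'
#' @param accuracy Accuracy tibble ([accuracy_table()]).
#' @param chance Chance line (default 0.5).
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy, chance = 0.5) {
  summ <- accuracy |>
    dplyr::group_by(.data$roi, .data$condition, .data$category) |>
    dplyr::summarise(mean = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$roi, .data$mean,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = chance, linetype = "dotted") +
    ggplot2::facet_wrap(~ .data$category) +
    ggplot2::labs(x = "ROI index", y = "classification accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.report_bundle <- function(object, ...) {
  plot_profile(object$profile)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
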