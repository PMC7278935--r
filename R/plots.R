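#' Plot a conversion profile
#'
#' Bar chart of the per-product elongation conversions; not-detected
#' products are shown as empty slots on the axis.
#'
#' @param profile a `conversion_profile` tibble.
#' @return a ggplot object.
#' @export
plot_conversion_profile <- function(profile) {
  d <- profile |>
    mutate(product = factor(.data$product, levels = .data$product))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$product, y = .data$conversion)) +
    ggplot2::geom_col(fill = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Conversion (%)",
                  title = sprintf("Elongation of %s", d$substrate[1])) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot grouped saturated fatty-acid profiles
#'
#' @param profiles tibble with columns `fatty_acid`, `percent` and a
#'   grouping column `construct` (replicates are averaged).
#' @return a ggplot object.
#' @export
plot_sfa_profiles <- function(profiles) {
  d <- profiles |>
    group_by(.data$construct, .data$fatty_acid) |>
    summarise(percent = mean(.data$percent), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fatty_acid, y = .data$percent,
                                  fill = .data$construct)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of total SFA ≥ C24", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot of a qPCR standard curve
#'
#' @param object a `standard_curve` fit.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.standard_curve <- function(object, ...) {
  d <- object$model$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_copies, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::labs(x = "log10(copies)", y = "Ct",
                  subtitle = sprintf("slope %.2f, E = %.2f, r² = %.3f",
                                     object$slope, object$efficiency,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}
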