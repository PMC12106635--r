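#' Plots for angle histograms, tract profiles and region summaries
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an angle histogram
#'
#' @param object an `angle_histogram`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.angle_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "median"),
                        linetype = "dashed") +
    ggplot2::labs(x = "angular deviation (deg)", y = "voxels",
                  subtitle = sprintf("median %.1f deg, mode %.0f deg",
                                     attr(object, "median"),
                                     attr(object, "mode"))) +
    ggplot2::xlim(0, 90) +
    ggplot2::theme_minimal()
}

#' Plot an along-tract profile
#'
#' Segment means with the across-streamline min-max ribbon.
#'
#' @param object a `tract_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tract_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$segment, y = .data$mean_angle)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_angle,
                                      ymax = .data$max_angle),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::ylim(0, 90) +
    ggplot2::labs(x = "segment (1..100 along tract)",
                  y = "vessel-fiber angle (deg)",
                  title = attr(object, "bundle")) +
    ggplot2::theme_minimal()
}

#' Plot a region summary
#'
#' Dominant vs nearest mean angle per atlas label.
#'
#' @param regions tibble from [region_summary()].
#' @return a ggplot.
#' @export
plot_region_summary <- function(regions) {
  long <- tidyr::pivot_longer(regions,
                              cols = c("mean_dominant", "mean_nearest"),
                              names_to = "measure", names_prefix = "mean_",
                              values_to = "mean_angle")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label_name,
                                     y = .data$mean_angle,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 90) +
    ggplot2::labs(x = NULL, y = "mean angle (deg)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
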