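#' Organ class colour palette
#'
#' @return Named vector of colours keyed by organ class name.
#' @export
organ_palette <- function() {
  c(background = "grey85", stem = "#8B5A2B", leaf = "#2E8B57",
    flower = "#D02090", pot = "grey40", tag = "gold")
}

#' Plot a 2D projection of a labeled point cloud
#'
#' @param cloud A point-cloud tibble.
#' @param colour Column to colour by (`"label"`, `"pred"`, or any numeric
#'   column such as `"curvature"`); `NULL` for a plain silhouette.
#' @param axes Which two coordinates to plot (default x-z, the side view).
#' @param size Point size.
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud, colour = if ("label" %in% names(cloud)) "label" else NULL,
                       axes = c("x", "z"), size = 0.3) {
  cloud <- validate_point_cloud(cloud)
  stopifnot(length(axes) == 2, all(axes %in% c("x", "y", "z")))
  p <- ggplot2::ggplot(cloud, ggplot2::aes(
    x = .data[[axes[1]]], y = .data[[axes[2]]]
  ))
  if (!is.null(colour) && colour %in% names(cloud)) {
    vals <- cloud[[colour]]
    if (colour %in% c("label", "pred")) {
      cloud$.organ <- factor(organ_name(vals), levels = names(organ_palette()))
      p <- ggplot2::ggplot(cloud, ggplot2::aes(
        x = .data[[axes[1]]], y = .data[[axes[2]]], colour = .data$.organ
      )) +
        ggplot2::scale_colour_manual(values = organ_palette(), name = "organ")
    } else {
      p <- p + ggplot2::aes(colour = .data[[colour]])
    }
  }
  p +
    ggplot2::geom_point(size = size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(axes[1], "(mm)"), y = paste(axes[2], "(mm)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.segmentation_report <- function(object, ...) {
  object$metrics |>
    tidyr::pivot_longer(c("precision", "recall", "iou"),
                        names_to = "metric", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$value,
                                 fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = organ_palette()[c("leaf", "stem")]) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shootseg_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(
    x = .data$method, y = .data$mean,
    ymin = pmax(.data$mean - .data$sd, 0),
    ymax = pmin(.data$mean + .data$sd, 1),
    fill = .data$class
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_manual(values = organ_palette()[c("leaf", "stem")]) +
    ggplot2::labs(y = "mean across test models", x = NULL) +
    ggplot2::theme_minimal()
}
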