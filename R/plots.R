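#' Plot a line profile with its delineability levels
#'
#' @param object A `cm_line_profile`.
#' @param background Optional background level to draw; computed via
#'   [estimate_background()] when `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_line_profile <- function(object, background = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$intensity)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1, color = "steelblue") +
    ggplot2::labs(x = "Position along line [mm]", y = "Signal intensity") +
    ggplot2::theme_minimal()
  if (isTRUE(background)) {
    bg <- estimate_background(object)
    h <- bg + 0.5 * (max(object$intensity) - bg)
    p <- p +
      ggplot2::geom_hline(yintercept = bg, linetype = "dashed", color = "firebrick") +
      ggplot2::geom_hline(yintercept = h, linetype = "dashed", color = "seagreen")
  }
  p
}

#' Plot a relaxation map
#'
#' @param object A `cm_relaxation_map`.
#' @param limits Color scale limits in ms (default `c(0, 100)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_relaxation_map <- function(object, limits = c(0, 100), ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                           col = seq_len(ncol(object$values)))
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, na.value = "grey15",
                                  name = sprintf("%s [ms]", object$family)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a phantom's tissue labels
#'
#' @param object A `cm_tissue_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_tissue_model <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$labels)),
                           col = seq_len(ncol(object$labels)))
  df$tissue <- factor(TISSUE_LEVELS[as.vector(object$labels)], levels = TISSUE_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "Tissue") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Boxplots of study delineability metrics by sequence and defect size
#'
#' @param study A [run_study()] result.
#' @return A ggplot object.
#' @export
plot_delineability <- function(study) {
  d <- dplyr::filter(study$study_table, .data$stage == "delineability")
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$value, fill = .data$sequence)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Nominal defect diameter", y = "[mm]", fill = "Sequence") +
    ggplot2::theme_minimal()
}

#' Boxplots of study bone-texture features by sequence
#'
#' @param study A [run_study()] result.
#' @return A ggplot object.
#' @export
plot_texture <- function(study) {
  d <- dplyr::filter(study$study_table, .data$stage == "texture",
                     .data$metric != "bin_occupancy")
  ggplot2::ggplot(d, ggplot2::aes(.data$sequence, .data$value, fill = .data$sequence)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Pre/post regional relaxation times of a study
#'
#' @param study A [run_study()] result.
#' @return A ggplot object.
#' @export
plot_regional <- function(study) {
  d <- dplyr::filter(study$study_table, .data$stage == "regional")
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$value, fill = .data$timepoint)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Region", y = "Relaxation time [ms]", fill = NULL) +
    ggplot2::theme_minimal()
}
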