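# ggplot2 display methods. Images are rendered with geom_raster on a tidy
# pixel table; channels are merged to RGB in channel order (up to three).

pixel_tibble <- function(m, value = "value") {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  names(df)[3] <- value
  df
}

#' Display a projected image as an RGB composite
#'
#' Channels are normalised to their own maxima and mapped to red, green and
#' blue in channel order.
#'
#' @param object A [projected_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.projected_image <- function(object, ...) {
  d <- dim(object$pixels)
  rgb_ch <- function(k) {
    if (k > d[1]) return(matrix(0, d[2], d[3]))
    m <- object$pixels[k, , ]
    if (max(m) > 0) m / max(m) else m
  }
  df <- pixel_tibble(rgb_ch(1), "r")
  df$g <- as.vector(rgb_ch(2))
  df$b <- as.vector(rgb_ch(3))
  df$fill <- grDevices::rgb(df$r, df$g, df$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste(object$channel_names, collapse = " / ")
    ) +
    ggplot2::theme_void()
}

#' Display a region label map
#'
#' @param object A [region_label_map()].
#' @param ... Unused.
#' @return A ggplot with the fixed palette background/core/outgrowth.
#' @exportS3Method ggplot2::autoplot
autoplot.region_label_map <- function(object, ...) {
  df <- pixel_tibble(object$labels)
  df$region <- factor(REGION_NAMES[df$value + 1L], levels = REGION_NAMES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(background = "grey15",
                                          core = "#4477AA",
                                          outgrowth = "#EE6677")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' Plot detected cells over the searched channel
#'
#' @param img A [projected_image()].
#' @param detections A `cell_detections` tibble from
#'   [detect_cells_outside_core()].
#' @return A ggplot.
#' @export
plot_detections <- function(img, detections) {
  ch <- attr(detections, "channel")
  m <- channel_matrix(img, ch)
  df <- pixel_tibble(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(
      data = tibble::as_tibble(detections),
      ggplot2::aes(x = .data$col, y = .data$row),
      colour = "red", shape = 1, size = 3, inherit.aes = FALSE
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = ch,
                  title = paste0(attr(detections, "count"),
                                 " cell(s) outside the core")) +
    ggplot2::theme_void()
}

#' Plot per-condition means with SEM error bars
#'
#' @param object A `cohort_result` from [run_pipeline()].
#' @param metrics Metric names to show; defaults to the outgrowth/core
#'   ratio and the cell count.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_result <- function(object,
                                   metrics = c("outgrowth_core_ratio",
                                               "cells_outside_core"),
                                   ...) {
  df <- dplyr::filter(object$summary, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "#4477AA", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "condition mean ± SEM") +
    ggplot2::theme_minimal()
}
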