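# ggplot2 displays for the main result types.

mask_outline_df <- function(mask) {
  m <- as_logical_matrix(mask)
  edge <- m & !(mask_erode(m, EBImage::makeBrush(3, "box")))
  idx <- which(edge)
  rc <- arrayInd(idx, dim(m))
  tibble(row = rc[, 1], col = rc[, 2])
}

#' Plot a spike detection over its source image
#'
#' Renders the RGB image (when available in the intermediates or supplied)
#' with the final spike regions outlined.
#'
#' @param object A `spike_detection`.
#' @param image Optional `H x W x 3` array to draw under the outlines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_detection <- function(object, image = NULL, ...) {
  h <- nrow(object$final_mask); w <- ncol(object$final_mask)
  p <- ggplot2::ggplot() +
    ggplot2::coord_fixed(xlim = c(0.5, w + 0.5), ylim = c(h + 0.5, 0.5),
                         expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d spike region(s), %d px",
                                  nrow(object$regions),
                                  object$total_spike_area))
  if (!is.null(image)) {
    p <- p + ggplot2::annotation_raster(grDevices::as.raster(clamp01(image)),
                                        xmin = 0.5, xmax = w + 0.5,
                                        ymin = -(h + 0.5), ymax = -0.5)
  }
  outline <- mask_outline_df(object$final_mask)
  if (nrow(outline))
    p <- p + ggplot2::geom_point(
      data = outline, ggplot2::aes(x = .data$col, y = .data$row),
      colour = "red", size = 0.3)
  if (nrow(object$regions))
    p <- p + ggplot2::geom_point(
      data = object$regions,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row),
      colour = "yellow", shape = 3, size = 2)
  p
}

#' @export
plot.spike_detection <- function(x, ...) print(autoplot(x, ...))

#' Plot a spike-area growth series
#'
#' @param object A `growth_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rel_day, y = .data$area,
                               group = .data$plant_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "day since emergence", y = "spike area (px)")
}

#' @export
plot.growth_series <- function(x, ...) print(autoplot(x, ...))

#' Plot per-plant HTP predictions against ground truth
#'
#' @param object An `htp_report` whose manifest carried `gt_htp`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.htp_report <- function(object, ...) {
  pp <- object$per_plant
  if (!"gt_htp" %in% names(pp))
    abort("report has no ground-truth HTP to plot against")
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$gt_htp, y = .data$htp_day)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ground-truth HTP (day)", y = "detected HTP (day)")
}

#' @export
plot.htp_report <- function(x, ...) print(autoplot(x, ...))
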