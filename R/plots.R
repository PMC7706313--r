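# ggplot2 display methods for images, attention maps and reports.

img_df <- function(img) {
  d <- dim(img)
  data.frame(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(rev(seq_len(d[1])), times = d[2]),
    col = grDevices::rgb(pmin(pmax(img[, , 1], 0), 1),
                         pmin(pmax(img[, , 2], 0), 1),
                         pmin(pmax(img[, , 3], 0), 1)))
}

#' Display an image tensor
#'
#' @param img H x W x 3 array in `[0, 1]`, or a grayscale matrix.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_image <- function(img, title = NULL) {
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  df <- img_df(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$col) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = title) +
    ggplot2::theme_void()
}

jet_colors <- function(n = 256) {
  grDevices::colorRampPalette(c("#00007F", "blue", "#007FFF", "cyan",
                                "#7FFF7F", "yellow", "#FF7F00", "red"))(n)
}

#' Overlay an attention map on its input image
#'
#' Blends a jet-colormapped heatmap over the (grayscaled) input, the usual
#' way attention maps are displayed.
#'
#' @param x an `attention_map`.
#' @param image the input image the map was computed from (optional; the
#'   bare heatmap is shown when missing).
#' @param alpha maximal overlay opacity.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.attention_map <- function(x, image = NULL, alpha = 0.6, ...) {
  h <- x$values
  jet <- jet_colors()
  hcol <- grDevices::col2rgb(jet[pmin(255, floor(h * 255)) + 1]) / 255
  out <- array(0, dim = c(dim(h), 3))
  if (!is.null(image)) {
    gray <- 0.2125 * image[, , 1] + 0.7154 * image[, , 2] + 0.0721 * image[, , 3]
    a <- alpha * h
    for (ch in 1:3)
      out[, , ch] <- (1 - a) * gray + a * matrix(hcol[ch, ], nrow(h), ncol(h))
  } else {
    for (ch in 1:3) out[, , ch] <- matrix(hcol[ch, ], nrow(h), ncol(h))
  }
  plot_image(out, title = sprintf("%s%s", x$method,
                                  if (!is.na(x$layer)) paste0(" @ ", x$layer) else ""))
}

#' @rdname autoplot.attention_map
#' @export
plot.attention_map <- function(x, ...) print(autoplot.attention_map(x, ...))

#' Plot a layer-shaving report
#'
#' Test accuracy per cut layer with the parameter count as point size, the
#' summary view of a [shave_series()] experiment.
#'
#' @param x a `shave_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.shave_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$cut_layer <- factor(df$cut_layer, levels = df$cut_layer)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cut_layer, y = .data$test_acc)) +
    ggplot2::geom_line(group = 1, color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$params)) +
    ggplot2::scale_size_continuous(labels = function(v)
      format(v, big.mark = ",")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "feature extraction ends at", y = "test accuracy",
                  size = "parameters") +
    ggplot2::theme_minimal()
}

#' Plot a layer-scan overlap profile
#'
#' @param x a `layer_scan` with a mask-derived summary.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.layer_scan <- function(x, ...) {
  df <- as.data.frame(x$summary)
  if (!"sensitivity" %in% names(df))
    stopf("layer scan has no overlap summary; supply a mask to layer_scan()")
  df$layer <- factor(df$layer, levels = df$layer)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$sensitivity)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = sprintf("%s target layer", x$method),
                  y = "lesion heat-mass fraction") +
    ggplot2::theme_minimal()
}
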