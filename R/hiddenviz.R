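# Visualization I: hidden-layer (intermediate) output inspection.

#' Capture the intermediate output of a layer
#'
#' Runs the image through the network and halts at the layer of interest,
#' returning its post-activation output as a channel stack.
#'
#' @param graph a `layer_graph`.
#' @param image input image (H x W x C array in `[0, 1]`).
#' @param layer layer name.
#' @return a `channel_stack`: list with `layer`, `activations` (h x w x c
#'   array, or a vector for non-spatial layers) and `shape`.
#' @export
extract_intermediate <- function(graph, image, layer) {
  if (!layer %in% names(graph$specs)) stopf("unknown layer '%s'", layer)
  fw <- forward(graph, image, capture = layer, keep_state = FALSE)
  act <- fw$captured[[layer]]
  structure(list(layer = layer, activations = act,
                 shape = dim(act) %||% length(act)),
            class = "channel_stack")
}

#' Render a channel stack as a tiled grayscale grid
#'
#' Each channel is min-max normalized independently to `[0, 1]` (constant
#' channels render as black tiles) and the channels are tiled row-major
#' into a near-square grid with 1-pixel separators.
#'
#' @param stack a [extract_intermediate()] result (spatial layer).
#' @param max_channels cap on the number of channels shown (>= 1).
#' @param separator gray value of the 1-px separator lines.
#' @return a grayscale matrix in `[0, 1]`.
#' @export
render_grid <- function(stack, max_channels = 64L, separator = 1) {
  stopifnot(inherits(stack, "channel_stack"), max_channels >= 1)
  act <- stack$activations
  if (is.null(dim(act))) stopf("layer '%s' has no spatial extent", stack$layer)
  d <- dim(act)
  n <- min(d[3], max_channels)
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  h <- d[1]; w <- d[2]
  grid <- matrix(separator, nrow_ * h + (nrow_ - 1), ncol_ * w + (ncol_ - 1))
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol_
    cc <- (i - 1) %% ncol_
    tile <- normalize01(act[, , i])
    grid[r * (h + 1) + seq_len(h), cc * (w + 1) + seq_len(w)] <- tile
  }
  grid
}

#' Shannon entropy of an image in bits
#'
#' RGB images are converted to grayscale by the ITU-R 709 luminance triple
#' (0.2125, 0.7154, 0.0721), quantized to 8-bit levels, and the entropy
#' `-sum(p * log2(p))` of the gray-level frequencies is returned.  Ranges
#' from 0 (constant image) to 8 bits (all 256 levels equally frequent).
#'
#' @param image H x W x 3 array or grayscale matrix, values in `[0, 1]`.
#' @return entropy in bits.
#' @examples
#' shannon_entropy(matrix(0.5, 8, 8))                      # 0
#' shannon_entropy(matrix(c(0, 1), 8, 8))                  # 1
#' @export
shannon_entropy <- function(image) {
  if (!length(image)) stopf("empty image")
  gray <- if (!is.null(dim(image)) && length(dim(image)) == 3L) {
    0.2125 * image[, , 1] + 0.7154 * image[, , 2] + 0.0721 * image[, , 3]
  } else image
  levels <- round(pmin(pmax(gray, 0), 1) * 255)
  p <- tabulate(levels + 1L, nbins = 256L)
  p <- p[p > 0] / length(levels)
  -sum(p * log2(p))
}

#' Per-neuron entropy table for a set of layers
#'
#' Applies feature visualization to `n_per_layer` channels of each listed
#' layer and scores each render's Shannon entropy; the depth index allows a
#' direct test of whether feature complexity grows with depth.
#'
#' @param graph a `layer_graph`.
#' @param layers character vector of spatial layer names, ordered shallow to
#'   deep.
#' @param n_per_layer channels per layer to visualize (capped at the layer's
#'   depth).
#' @param steps,lr,seed passed to [visualize_neuron()].
#' @return tibble with columns `layer`, `depth_index`, `channel`, `entropy`.
#' @export
layer_entropy_table <- function(graph, layers, n_per_layer = 16L,
                                steps = 128L, lr = 0.05, seed = 0L) {
  rows <- list()
  for (di in seq_along(layers)) {
    ly <- layers[di]
    n_ch <- graph$shapes[[ly]][3]
    chans <- seq_len(min(n_ch, n_per_layer))
    for (ch in chans) {
      vis <- visualize_neuron(graph, neuron_selector(ly, ch),
                              steps = steps, lr = lr, seed = seed + ch)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = ly, depth_index = di, channel = ch,
        entropy = shannon_entropy(vis$image))
    }
  }
  do.call(rbind, rows)
}
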