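# Visualization IV: attention-map algorithms.
#
# Eight methods in three families produce input-aligned heatmaps scoring
# each pixel's importance for a class decision:
#   perturbation-based: occlusion_map(), superpixel_surrogate_map()
#   gradient-based:     vanilla_saliency(), integrated_gradients_map(),
#                       guided_backprop_map(), grad_cam_map()
#   reference-based:    deeplift_map(), explanation_map()
# All return an `attention_map` whose `values` are min-max normalized to
# [0,1] (a constant map normalizes to all zeros) with the raw
# pre-normalization values retained for quantitative evaluation.

new_attention_map <- function(raw, method, class = NA_integer_,
                              layer = NA_character_) {
  structure(list(values = normalize01(raw), raw = raw, method = method,
                 class = class, layer = layer),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("<attention_map> %s, %dx%d%s%s\n", x$method,
              nrow(x$values), ncol(x$values),
              if (!is.na(x$class)) sprintf(", class %d", x$class) else "",
              if (!is.na(x$layer)) sprintf(", layer %s", x$layer) else ""))
  invisible(x)
}

class_score <- function(graph, image, class, score = "logit") {
  fw <- forward(graph, image, keep_state = FALSE)
  if (score == "logit") fw$logits[class] else fw$probs[class]
}

# Channel-max absolute value, the usual saliency aggregation.
channel_max_abs <- function(a) {
  if (is.null(dim(a)) || length(dim(a)) == 2L) return(abs(a))
  apply(abs(a), c(1, 2), max)
}

#' Occlusion sensitivity map
#'
#' Slides a square mask over the image and records, per mask position, the
#' drop in the class score relative to the unmodified image.  Pixels
#' covered by several mask positions average their drops.
#'
#' @param graph a `layer_graph`.
#' @param image input image (H x W x 3).
#' @param class 1-based target class.
#' @param mask_size mask side length in pixels (default 32).
#' @param stride mask step (default 16).
#' @param mask_value scalar or RGB triple painted into the mask; defaults
#'   to the image's mean color.
#' @param score `"logit"` (default) or `"prob"`.
#' @return an `attention_map`; `raw` holds the averaged score drops.
#' @export
occlusion_map <- function(graph, image, class, mask_size = 32L, stride = 16L,
                          mask_value = NULL, score = "logit") {
  d <- dim(image)
  if (mask_size > min(d[1], d[2])) stopf("mask_size exceeds the image")
  if (stride < 1) stopf("stride must be >= 1")
  if (is.null(mask_value)) mask_value <- apply(image, 3, mean)
  mask_value <- rep(mask_value, length.out = d[3])
  base <- class_score(graph, image, class, score)
  heat <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  r_starts <- unique(c(seq(1, d[1] - mask_size + 1, by = stride)))
  c_starts <- unique(c(seq(1, d[2] - mask_size + 1, by = stride)))
  for (r in r_starts) for (cc in c_starts) {
    xm <- image
    for (ch in seq_len(d[3]))
      xm[r:(r + mask_size - 1), cc:(cc + mask_size - 1), ch] <- mask_value[ch]
    drop_ <- base - class_score(graph, xm, class, score)
    heat[r:(r + mask_size - 1), cc:(cc + mask_size - 1)] <-
      heat[r:(r + mask_size - 1), cc:(cc + mask_size - 1)] + drop_
    cnt[r:(r + mask_size - 1), cc:(cc + mask_size - 1)] <-
      cnt[r:(r + mask_size - 1), cc:(cc + mask_size - 1)] + 1
  }
  raw <- heat / pmax(cnt, 1)
  new_attention_map(raw, "occlusion", class)
}

#' Superpixel segmentation by spatially weighted k-means
#'
#' SLIC-style segmentation: k-means on `(y, x, R, G, B)` features with
#' grid-seeded centers; `compactness` balances spatial against color
#' distance.  Used as the perturbation unit of
#' [superpixel_surrogate_map()].
#'
#' @param image H x W x 3 array.
#' @param n_segments requested number of superpixels (>= 2).
#' @param compactness spatial weight; larger values give squarer segments.
#' @param seed k-means seed.
#' @return integer H x W matrix of segment labels `1..k`.
#' @export
slic_segments <- function(image, n_segments, compactness = 0.2, seed = 0L) {
  if (n_segments < 2) stopf("n_segments must be >= 2")
  d <- dim(image)
  ys <- rep(seq_len(d[1]), times = d[2]) / max(d[1], d[2])
  xs <- rep(seq_len(d[2]), each = d[1]) / max(d[1], d[2])
  feat <- cbind(compactness * ys, compactness * xs, matrix(image, ncol = 3))
  side <- ceiling(sqrt(n_segments))
  gy <- (seq_len(side) - 0.5) / side * d[1]
  gx <- (seq_len(side) - 0.5) / side * d[2]
  centers_px <- cbind(rep(round(gy), times = side), rep(round(gx), each = side))
  centers_px <- centers_px[seq_len(min(n_segments, nrow(centers_px))), , drop = FALSE]
  init <- feat[(centers_px[, 2] - 1) * d[1] + centers_px[, 1], , drop = FALSE]
  init <- init + 1e-6 * seq_len(nrow(init))   # break exact duplicates
  km <- withr::with_seed(as.integer(seed),
    stats::kmeans(feat, centers = init, iter.max = 20))
  matrix(km$cluster, d[1], d[2])
}

#' LIME-style superpixel surrogate map
#'
#' Perturbs the image by switching superpixels off (painting them with the
#' replacement color), scores each perturbed image, and fits a linear
#' surrogate from the on/off design to the class scores; a pixel's heat is
#' its superpixel's regression weight.  When the design is exhaustible
#' (`2^k <= n_samples`) all on/off patterns are enumerated and the fit is
#' exact least squares; otherwise random designs are drawn and a ridge
#' penalty (`lambda = 1e-3`) guards against singular fits.
#'
#' @inheritParams occlusion_map
#' @param n_segments number of superpixels (ignored when `segments` given).
#' @param n_samples perturbed images to evaluate (>= n_segments).
#' @param seed sampling seed.
#' @param replacement replacement color, default the image mean.
#' @param segments optional precomputed H x W segment-label matrix.
#' @return an `attention_map`; `raw` holds per-pixel surrogate weights and
#'   attribute `"weights"` the per-segment weights.
#' @export
superpixel_surrogate_map <- function(graph, image, class, n_segments = 16L,
                                     n_samples = 256L, seed = 0L,
                                     replacement = NULL, segments = NULL,
                                     score = "logit") {
  if (is.null(segments))
    segments <- slic_segments(image, n_segments, seed = seed)
  k <- max(segments)
  if (n_samples < k) stopf("n_samples must be >= the number of superpixels")
  d <- dim(image)
  if (is.null(replacement)) replacement <- apply(image, 3, mean)
  replacement <- rep(replacement, length.out = d[3])
  exhaustive <- 2^k <= n_samples
  design <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, 0)), k)))
  } else {
    withr::with_seed(as.integer(seed),
      matrix(stats::rbinom(n_samples * k, 1, 0.5), nrow = n_samples))
  }
  y <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    xi <- image
    off <- which(design[i, ] == 0)
    if (length(off)) {
      sel <- segments %in% off
      for (ch in seq_len(d[3])) {
        plane <- xi[, , ch]; plane[sel] <- replacement[ch]
        xi[, , ch] <- plane
      }
    }
    y[i] <- class_score(graph, xi, class, score)
  }
  X <- cbind(1, design)
  XtX <- crossprod(X)
  w <- tryCatch(solve(XtX, crossprod(X, y)), error = function(e) NULL)
  if (is.null(w) || !exhaustive && kappa(XtX) > 1e10) {
    if (is.null(w)) warning("singular surrogate design; refitting with ridge damping")
    w <- solve(XtX + diag(1e-3, ncol(X)), crossprod(X, y))
  }
  seg_w <- as.numeric(w[-1])
  raw <- matrix(seg_w[segments], d[1], d[2])
  out <- new_attention_map(raw, "superpixel_surrogate", class)
  attr(out, "weights") <- seg_w
  attr(out, "segments") <- segments
  out
}

#' Gradient-based saliency maps
#'
#' `vanilla_saliency()` back-propagates the class logit with the exact
#' gradient; `guided_backprop_map()` uses the guided rule (ReLU backward
#' signals zeroed where the forward pre-activation or the incoming signal
#' is negative).  Per-pixel heat is the maximum absolute signal over the
#' color channels; the signed per-channel signal is kept in `raw_signed`.
#'
#' @inheritParams occlusion_map
#' @return an `attention_map`.
#' @export
vanilla_saliency <- function(graph, image, class) {
  fw <- forward(graph, image)
  bw <- backward(graph, fw$state, target_logit(class), rule = "vanilla")
  out <- new_attention_map(channel_max_abs(bw$input), "vanilla_saliency", class)
  out$raw_signed <- bw$input
  out
}

#' @rdname vanilla_saliency
#' @export
guided_backprop_map <- function(graph, image, class) {
  fw <- forward(graph, image)
  bw <- backward(graph, fw$state, target_logit(class), rule = "guided")
  out <- new_attention_map(channel_max_abs(bw$input), "guided_backprop", class)
  out$raw_signed <- bw$input
  out
}

#' Integrated gradients attribution map
#'
#' Midpoint-rule path integral of the gradient along the straight line
#' from the baseline to the image:
#' `attr_i = (x_i - x0_i) * mean_k dF/dx_i(x0 + (k - 0.5) / steps * (x - x0))`.
#' Satisfies completeness: the attributions sum to `F(x) - F(x0)` as
#' `steps` grows.
#'
#' @inheritParams occlusion_map
#' @param steps interpolation steps (>= 1, default 50).
#' @param baseline baseline image; default all-black.
#' @return an `attention_map`; `raw_signed` holds the signed per-channel
#'   attributions.
#' @export
integrated_gradients_map <- function(graph, image, class, steps = 50L,
                                     baseline = NULL) {
  if (steps < 1) stopf("steps must be >= 1")
  if (is.null(baseline)) baseline <- array(0, dim = dim(image))
  diff_ <- image - baseline
  gsum <- array(0, dim = dim(image))
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    xi <- baseline + alpha * diff_
    fw <- forward(graph, xi)
    bw <- backward(graph, fw$state, target_logit(class), rule = "vanilla")
    gsum <- gsum + bw$input
  }
  attributions <- diff_ * gsum / steps
  out <- new_attention_map(channel_max_abs(attributions),
                           "integrated_gradients", class)
  out$raw_signed <- attributions
  out
}

#' Grad-CAM map with layer targeting
#'
#' Channel weights are the spatial means of the class-logit gradient at the
#' target layer; the map is the ReLU of the weighted channel sum,
#' bilinearly upsampled to the input resolution.  Any spatial layer can be
#' targeted; at the last feature layer of a GAP + dense network this
#' reduces algebraically to class activation mapping.
#'
#' @inheritParams occlusion_map
#' @param layer target layer name (must have spatial extent).
#' @param relu_rule `"vanilla"` (default) or `"guided"` back-propagation
#'   for the gradient computation.
#' @return an `attention_map`; attribute `"cam"` holds the map at the
#'   layer's native resolution.
#' @export
grad_cam_map <- function(graph, image, class, layer,
                         relu_rule = c("vanilla", "guided")) {
  relu_rule <- match.arg(relu_rule)
  shp <- graph$shapes[[layer]]
  if (is.null(shp)) stopf("unknown layer '%s'", layer)
  if (length(shp) != 3L) stopf("Grad-CAM needs a layer with spatial extent, not '%s'", layer)
  fw <- forward(graph, image, capture = layer)
  bw <- backward(graph, fw$state, target_logit(class), rule = relu_rule,
                 capture_grad = layer)
  act <- fw$captured[[layer]]
  g <- bw$layers[[layer]]
  w <- colMeans(matrix(g, ncol = shp[3]))
  cam <- matrix(matrix(act, ncol = shp[3]) %*% w, shp[1], shp[2])
  cam <- pmax(cam, 0)
  d <- dim(image)
  raw <- resize_bilinear(cam, d[1], d[2])
  out <- new_attention_map(raw, "grad_cam", class, layer)
  attr(out, "cam") <- cam
  out
}

#' DeepLIFT (rescale rule) contribution map
#'
#' Back-propagates contribution multipliers relative to a reference image
#' (rescale rule at ReLUs, exact linear rule at affine layers); the pixel
#' contributions are `multiplier * (x - reference)` and per-pixel heat is
#' the channel-max absolute contribution.  The contributions of all input
#' pixels sum to `F(x) - F(reference)` on affine + ReLU graphs
#' (summation-to-delta).
#'
#' @inheritParams occlusion_map
#' @param reference reference image of the same shape (for leaf diagnosis:
#'   a healthy leaf of the same species).
#' @return an `attention_map`; `raw_signed` holds signed contributions.
#' @export
deeplift_map <- function(graph, image, class, reference) {
  if (is.null(reference)) stopf("deeplift_map requires a reference image")
  if (!identical(dim(reference), dim(image)))
    stopf("reference shape does not match the image")
  fw <- forward(graph, image)
  fr <- forward(graph, reference)
  bw <- backward(graph, fw$state, target_logit(class), rule = "rescale",
                 reference = fr$state)
  contrib <- bw$input * (image - reference)
  out <- new_attention_map(channel_max_abs(contrib), "deeplift", class)
  out$raw_signed <- contrib
  out
}

#' Reference activation thresholds for the explanation map
#'
#' Feeds a batch of reference images (healthy leaves) through the network
#' and records, per channel of `layer`, the mean activation over the batch
#' and all spatial positions -- the "activation threshold" against which an
#' input's activations are normalized.
#'
#' @param graph a `layer_graph`.
#' @param references non-empty list of reference images.
#' @param layer spatial layer name.
#' @return a `reference_set`: list with `layer`, `thresholds` (per-channel
#'   means), `n_images`.
#' @export
activation_thresholds <- function(graph, references, layer) {
  if (!length(references)) stopf("empty reference batch")
  shp <- graph$shapes[[layer]]
  if (is.null(shp) || length(shp) != 3L)
    stopf("explanation map needs a layer with spatial extent")
  acc <- numeric(shp[3])
  for (im in references) {
    a <- forward(graph, im, capture = layer, keep_state = FALSE)$captured[[layer]]
    acc <- acc + colMeans(matrix(a, ncol = shp[3]))
  }
  structure(list(layer = layer, thresholds = acc / length(references),
                 n_images = length(references)),
            class = "reference_set")
}

#' Forward-only explanation map
#'
#' Rectifies each channel of the target layer against its reference-derived
#' activation threshold, `n_k = max(0, a_k - t_k)`, ranks channels by the
#' spatial sum of the normalized activation, and sums the top `top_k`
#' channels into a map (bilinearly upsampled to the input).  Requires no
#' gradient computation at all -- the cost of one forward pass.
#'
#' @inheritParams occlusion_map
#' @param references a [activation_thresholds()] result, or a list of
#'   reference images (thresholds are then computed for `layer`).
#' @param layer target layer; defaults to the layer of a precomputed
#'   `reference_set`.
#' @param top_k number of top-activated channels to sum (default 3).
#' @return an `attention_map`.
#' @export
explanation_map <- function(graph, image, references, layer = NULL,
                            top_k = 3L) {
  ref <- if (inherits(references, "reference_set")) references
  else activation_thresholds(graph, references,
                             layer %||% stopf("layer required with raw references"))
  if (!is.null(layer) && !identical(layer, ref$layer))
    stopf("thresholds were computed for layer '%s'", ref$layer)
  layer <- ref$layer
  shp <- graph$shapes[[layer]]
  if (top_k > shp[3]) stopf("top_k exceeds the channel count (%d)", shp[3])
  a <- forward(graph, image, capture = layer, keep_state = FALSE)$captured[[layer]]
  am <- matrix(a, ncol = shp[3])
  norm <- sweep(am, 2, ref$thresholds, "-")
  norm[norm < 0] <- 0
  ranking <- order(colSums(norm), decreasing = TRUE)
  sel <- ranking[seq_len(top_k)]
  cam <- matrix(rowSums(norm[, sel, drop = FALSE]), shp[1], shp[2])
  d <- dim(image)
  raw <- resize_bilinear(cam, d[1], d[2])
  out <- new_attention_map(raw, "explanation_map", NA_integer_, layer)
  attr(out, "channels") <- sel
  attr(out, "cam") <- cam
  out
}

#' Scan a layer-targetable method over layers
#'
#' Computes one attention map per listed layer with Grad-CAM or the
#' explanation map, and (when a lesion mask is supplied) tabulates each
#' layer's lesion-overlap metrics so the most informative target layer can
#' be identified.
#'
#' @inheritParams occlusion_map
#' @param method `"grad_cam"` or `"explanation"`.
#' @param layers character vector of spatial layer names, shallow to deep.
#' @param mask optional binary lesion mask for the overlap summary.
#' @param references reference images or `reference_set`s (explanation map
#'   only).
#' @param ... passed to the underlying method.
#' @return a `layer_scan`: list with `maps` (named by layer) and `summary`
#'   (tibble: `layer`, `h`, `w`, and overlap metrics when `mask` given).
#' @export
layer_scan <- function(graph, image, method = c("grad_cam", "explanation"),
                       layers, class = NULL, mask = NULL, references = NULL,
                       ...) {
  method <- match.arg(method)
  maps <- list()
  rows <- list()
  for (ly in layers) {
    m <- if (method == "grad_cam") {
      grad_cam_map(graph, image, class, ly, ...)
    } else {
      explanation_map(graph, image, references, layer = ly, ...)
    }
    maps[[ly]] <- m
    shp <- graph$shapes[[ly]]
    row <- tibble::tibble(layer = ly, h = shp[1], w = shp[2])
    if (!is.null(mask)) {
      om <- overlap_metrics(m, mask)
      row <- cbind(row, om)
    }
    rows[[length(rows) + 1L]] <- row
  }
  structure(list(maps = maps, summary = do.call(rbind, rows),
                 method = method),
            class = "layer_scan")
}
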