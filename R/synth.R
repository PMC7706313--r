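# Synthetic leaf-disease imagery with ground-truth lesion masks.
#
# The generator emulates the structure of curated leaf-disease photo
# collections at toy scale: a single leaf on a uniform background, with
# disease classes distinguished solely by the color, texture, size and
# count of their lesions.  Because the lesion is the only class-separating
# feature, a sound classifier must attend to it -- which is what makes the
# imagery a useful ground truth for attention-map evaluation.

#' Describe a synthetic disease class
#'
#' @param class_id integer class label (1-based).
#' @param name human-readable class name.
#' @param leaf_color,lesion_color,background RGB triples in `[0, 1]`.
#' @param lesion_count integer range `c(min, max)` of lesions per image
#'   (`c(0, 0)` for a healthy class).
#' @param lesion_radius radius range in pixels (>= 1).
#' @param texture `"solid"` disks or `"ringed"` (dark center, lighter halo;
#'   `lesion_color` is the halo color and the center is a darkened version).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @return a `class_spec` object.
#' @export
class_spec <- function(class_id, name = paste0("class", class_id),
                       leaf_color = c(0.20, 0.55, 0.20),
                       lesion_color = c(0.45, 0.27, 0.07),
                       lesion_count = c(3, 6), lesion_radius = c(4, 7),
                       texture = c("solid", "ringed"),
                       background = c(0.55, 0.52, 0.48),
                       noise_sd = 0.02) {
  texture <- match.arg(texture)
  stopifnot(length(leaf_color) == 3, length(lesion_color) == 3,
            length(background) == 3,
            all(c(leaf_color, lesion_color, background) >= 0),
            all(c(leaf_color, lesion_color, background) <= 1),
            length(lesion_count) == 2, lesion_count[1] <= lesion_count[2],
            length(lesion_radius) == 2, lesion_radius[1] <= lesion_radius[2],
            lesion_radius[1] >= 1, noise_sd >= 0)
  structure(list(class_id = as.integer(class_id), name = name,
                 leaf_color = leaf_color, lesion_color = lesion_color,
                 lesion_count = as.integer(lesion_count),
                 lesion_radius = lesion_radius, texture = texture,
                 background = background, noise_sd = noise_sd),
            class = "class_spec")
}

#' Default four-class leaf-disease task
#'
#' One healthy class and three diseases separable only by their lesions:
#' few large solid brown spots, ringed lesions with a yellow halo and a dark
#' center, and many small near-black specks.  The variety echoes the
#' "number, size, and color" axes along which real foliar diseases differ.
#' Leaf, background and noise level are identical across classes.
#'
#' @return list of four [class_spec()]s.
#' @export
default_class_specs <- function() {
  list(
    class_spec(1, "healthy", lesion_count = c(0, 0)),
    class_spec(2, "brown_spot", lesion_color = c(0.45, 0.27, 0.07),
               lesion_count = c(3, 6), lesion_radius = c(4, 7)),
    class_spec(3, "ring_blight", lesion_color = c(0.85, 0.78, 0.25),
               lesion_count = c(2, 4), lesion_radius = c(5, 8),
               texture = "ringed"),
    class_spec(4, "black_speck", lesion_color = c(0.10, 0.08, 0.05),
               lesion_count = c(8, 14), lesion_radius = c(2, 3)))
}

#' Generate one synthetic leaf image with its lesion mask
#'
#' Draws an ellipse-shaped leaf on a uniform background, paints the
#' requested number of lesion disks (clipped to the leaf), records the
#' binary lesion mask before noise, then adds clipped Gaussian pixel noise.
#' Fully deterministic under `seed`.
#'
#' @param spec a [class_spec()].
#' @param size square image size in pixels (>= 32).
#' @param seed integer seed.
#' @return a `synthetic_sample`: list with `image` (size x size x 3 in
#'   `[0, 1]`), `mask` (binary lesion matrix), `leaf` (binary leaf-region
#'   matrix), `label`, `spec`, `seed`.
#' @export
make_sample <- function(spec, size = 64L, seed = 0L) {
  stopifnot(inherits(spec, "class_spec"))
  if (size < 32L) stopf("size must be >= 32")
  ax_a <- 0.42 * size; ax_b <- 0.33 * size
  if (spec$lesion_radius[2] > min(ax_a, ax_b))
    stopf("lesion radius (%g px) exceeds the leaf half-width", spec$lesion_radius[2])
  withr::with_seed(as.integer(seed), {
    ctr <- (size + 1) / 2
    theta <- stats::runif(1, -pi / 6, pi / 6)
    rows <- matrix(seq_len(size), size, size)        # y, top-down
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    u <- (cols - ctr) * cos(theta) + (rows - ctr) * sin(theta)
    v <- -(cols - ctr) * sin(theta) + (rows - ctr) * cos(theta)
    r2 <- (u / ax_a)^2 + (v / ax_b)^2
    leaf <- r2 <= 1
    shade <- 1 - 0.12 * pmin(r2, 1)                  # mild radial shading
    img <- array(0, dim = c(size, size, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$background[ch], size, size)
      plane[leaf] <- (spec$leaf_color[ch] * shade)[leaf]
      img[, , ch] <- plane
    }
    mask <- matrix(FALSE, size, size)
    n_lesions <- if (spec$lesion_count[2] == 0) 0L else
      sample(spec$lesion_count[1]:spec$lesion_count[2], 1)
    if (n_lesions > 0) {
      placed <- 0L; tries <- 0L
      while (placed < n_lesions && tries < 200L) {
        tries <- tries + 1L
        cy <- stats::runif(1, 1, size); cx <- stats::runif(1, 1, size)
        rad <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
        if (!leaf[round(cy), round(cx)]) next
        d2 <- (rows - cy)^2 + (cols - cx)^2
        disk <- d2 <= rad^2 & leaf
        if (!any(disk)) next
        if (spec$texture == "solid") {
          for (ch in 1:3) {
            plane <- img[, , ch]; plane[disk] <- spec$lesion_color[ch]
            img[, , ch] <- plane
          }
        } else {
          inner <- d2 <= (0.55 * rad)^2 & leaf
          halo <- disk & !inner
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[halo] <- spec$lesion_color[ch]
            plane[inner] <- 0.35 * spec$lesion_color[ch]
            img[, , ch] <- plane
          }
        }
        mask <- mask | disk
        placed <- placed + 1L
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
      img <- pmin(pmax(img, 0), 1)
      dim(img) <- c(size, size, 3)
    }
    structure(list(image = img, mask = mask * 1, leaf = leaf * 1,
                   label = spec$class_id, spec = spec, seed = as.integer(seed)),
              class = "synthetic_sample")
  })
}

#' Generate a class-balanced dataset with a train/validation/test split
#'
#' Per class, `n_per_class` samples are generated with seeds drawn
#' deterministically from `seed`, then split in the configured ratio.
#' Split sizes use floor for train, then validation, with the remainder
#' going to test (so `n = 10` under 6:2:2 gives exactly 6/2/2).
#'
#' @param specs list of [class_spec()]s.
#' @param n_per_class samples per class (>= 5 so every split holds every
#'   class).
#' @param ratio length-3 split weights, default `c(6, 2, 2)`.
#' @param size image size passed to [make_sample()].
#' @param seed integer master seed.
#' @return a `dataset_splits` object: list with `train`, `validation`,
#'   `test` (lists of `synthetic_sample`), plus `specs`, `ratio`, `seed`.
#' @export
make_dataset <- function(specs, n_per_class, ratio = c(6, 2, 2),
                         size = 64L, seed = 0L) {
  if (!length(specs)) stopf("empty class spec list")
  if (n_per_class < 5L) stopf("n_per_class must be >= 5")
  fr <- ratio / sum(ratio)
  n_tr <- floor(n_per_class * fr[1])
  n_va <- floor(n_per_class * fr[2])
  n_te <- n_per_class - n_tr - n_va
  sample_seeds <- withr::with_seed(as.integer(seed),
    matrix(sample.int(.Machine$integer.max - 1L, n_per_class * length(specs)),
           nrow = n_per_class))
  train <- list(); validation <- list(); test <- list()
  for (ci in seq_along(specs)) {
    samples <- lapply(seq_len(n_per_class), function(i)
      make_sample(specs[[ci]], size = size, seed = sample_seeds[i, ci]))
    train <- c(train, samples[seq_len(n_tr)])
    validation <- c(validation, samples[n_tr + seq_len(n_va)])
    test <- c(test, samples[n_tr + n_va + seq_len(n_te)])
  }
  structure(list(train = train, validation = validation, test = test,
                 specs = specs, ratio = ratio, size = as.integer(size),
                 seed = as.integer(seed)),
            class = "dataset_splits")
}

#' @export
print.dataset_splits <- function(x, ...) {
  cat(sprintf("<dataset_splits> %d classes, %dx%d px; train %d / validation %d / test %d\n",
              length(x$specs), x$size, x$size,
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Build a small CNN classifier graph
#'
#' `build_tiny_cnn()` is three conv/batchnorm/relu/maxpool blocks followed
#' by global average pooling and a dense softmax head -- the standard
#' fixture architecture of this package.  Batchnorm keeps the all-positive
#' image activations centered, which small-batch Adam needs to avoid the
#' dead-ReLU uniform plateau; for the same reason the dense head starts at
#' zero so training begins from the uniform prediction.  `build_inception_mini()` is a miniature
#' two-module inception-style network with (scale-free) batchnorm, used to
#' exercise concat branches and batchnorm under training.
#'
#' @param input_size square input resolution.
#' @param n_classes number of classes.
#' @param filters channels of the three conv blocks.
#' @param seed weight-init seed.
#' @return a `layer_graph` with layers `Conv1..Conv3`, `GAP`, `output`,
#'   `predictions` (tiny_cnn).
#' @export
build_tiny_cnn <- function(input_size, n_classes, filters = c(8, 16, 32),
                           seed = 0L) {
  specs <- list(layer_spec("in", "input", shape = c(input_size, input_size, 3)))
  parent <- "in"
  for (i in seq_along(filters)) {
    cv <- paste0("Conv", i)
    specs <- c(specs, list(
      layer_spec(paste0(cv, "_conv"), "conv2d", parents = parent,
                 filters = filters[i], kernel = 3, padding = "same",
                 use_bias = FALSE),
      layer_spec(paste0(cv, "_bn"), "batchnorm", parents = paste0(cv, "_conv")),
      layer_spec(cv, "relu", parents = paste0(cv, "_bn")),
      layer_spec(paste0("Pool", i), "maxpool", parents = cv,
                 pool = 2, stride = 2)))
    parent <- paste0("Pool", i)
  }
  specs <- c(specs, list(
    layer_spec("GAP", "global_avg_pool", parents = parent),
    layer_spec("output", "dense", parents = "GAP", units = n_classes),
    layer_spec("predictions", "softmax", parents = "output")))
  g <- build_graph(specs, init = "random", seed = seed)
  zero_head(g)
}

# Zero-initialize the classification head so training starts at the uniform
# prediction; keeps small-batch Adam from collapsing the feature stack into
# the dead-ReLU uniform plateau.
zero_head <- function(graph) {
  graph$weights$output$kernel[] <- 0
  if (!is.null(graph$weights$output$bias)) graph$weights$output$bias[] <- 0
  graph
}

#' @rdname build_tiny_cnn
#' @export
build_inception_mini <- function(input_size, n_classes, seed = 0L) {
  mini_mixed <- function(name, parent) {
    c(conv_bn(paste0(name, "_b1"), parent, 8, 1),
      conv_bn(paste0(name, "_b3_1"), parent, 8, 1),
      conv_bn(paste0(name, "_b3_2"), paste0(name, "_b3_1"), 12, 3),
      list(layer_spec(paste0(name, "_pool"), "avgpool", parents = parent,
                      pool = 3, stride = 1, padding = "same")),
      conv_bn(paste0(name, "_bp"), paste0(name, "_pool"), 4, 1),
      list(layer_spec(name, "concat",
                      parents = c(paste0(name, "_b1"), paste0(name, "_b3_2"),
                                  paste0(name, "_bp")))))
  }
  specs <- c(
    list(layer_spec("in", "input", shape = c(input_size, input_size, 3))),
    conv_bn("Conv1", "in", 16, 3, stride = 2),
    mixed_blocks <- mini_mixed("Mixed0", "Conv1"),
    list(layer_spec("Pool1", "maxpool", parents = "Mixed0", pool = 2, stride = 2)),
    mini_mixed("Mixed1", "Pool1"),
    list(layer_spec("GAP", "global_avg_pool", parents = "Mixed1"),
         layer_spec("output", "dense", parents = "GAP", units = n_classes),
         layer_spec("predictions", "softmax", parents = "output")))
  zero_head(build_graph(specs, init = "random", seed = seed))
}

#' Train a small fixture classifier on a synthetic dataset
#'
#' Builds the requested architecture sized to the dataset, trains it, and
#' evaluates it on the test split.  Both built-in architectures end in a
#' global-average-pooling + dense head, which the semantic dictionary and
#' the Grad-CAM/class-activation-mapping equivalence rely on; a custom spec
#' list passed as `arch` is rejected unless it has that head.
#'
#' @param splits a [make_dataset()] result.
#' @param arch `"tiny_cnn"`, `"inception_mini"`, or a list of
#'   [layer_spec()]s ending in global_avg_pool + dense (+ softmax).
#' @param config a [train_config()]; the default trains for 25 epochs with
#'   Adam at lr 0.01 (halved every 15 epochs), batches of 8, which reaches
#'   > 0.9 test accuracy on the default lesion-separable task in about two
#'   minutes on one CPU.
#' @param seed weight-initialization seed.
#' @return the trained `layer_graph`, with the test-set evaluation attached
#'   as attribute `"test_metrics"` and training history as `"history"`.
#' @export
make_fixture_model <- function(splits, arch = "tiny_cnn",
                               config = train_config(lr = 0.01, batch_size = 8,
                                                     epochs = 25, seed = 1L,
                                                     lr_decay = 0.5,
                                                     lr_decay_every = 15L,
                                                     bn_momentum = 0.9),
                               seed = 0L) {
  n_classes <- length(splits$specs)
  size <- splits$size
  graph <- if (is.character(arch)) {
    switch(match.arg(arch, c("tiny_cnn", "inception_mini")),
           tiny_cnn = build_tiny_cnn(size, n_classes, seed = seed),
           inception_mini = build_inception_mini(size, n_classes, seed = seed))
  } else {
    g <- build_graph(arch, init = "random", seed = seed)
    kinds <- vapply(g$specs[g$order], `[[`, character(1), "kind")
    body <- kinds[kinds != "softmax"]
    n <- length(body)
    if (n < 2 || body[n] != "dense" || body[n - 1] != "global_avg_pool")
      stopf("fixture architectures must end in a global_avg_pool + dense head")
    g
  }
  trained <- train(graph, splits, config)
  metrics <- evaluate(trained, splits$test)
  if (metrics$accuracy < 0.9)
    warning(sprintf("fixture model test accuracy %.2f is below 0.9", metrics$accuracy))
  attr(trained, "test_metrics") <- metrics
  trained
}

#' Write a dataset to disk as PNG images plus labels and a manifest
#'
#' Each sample is written as `img_<split>_<i>.png` with its lesion mask as
#' `mask_<split>_<i>.png`, alongside `labels.csv` (file, split, label,
#' class name) and `manifest.json` (generation parameters and seed).
#'
#' @param splits a [make_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the labels data frame.
#' @export
write_dataset <- function(splits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in c("train", "validation", "test")) {
    for (i in seq_along(splits[[split]])) {
      smp <- splits[[split]][[i]]
      img_file <- sprintf("img_%s_%03d.png", split, i)
      mask_file <- sprintf("mask_%s_%03d.png", split, i)
      png::writePNG(smp$image, file.path(dir, img_file))
      png::writePNG(smp$mask, file.path(dir, mask_file))
      rows[[length(rows) + 1L]] <- data.frame(
        file = img_file, mask = mask_file, split = split,
        label = smp$label, class = smp$spec$name)
    }
  }
  labels <- do.call(rbind, rows)
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_classes = length(splits$specs), size = splits$size,
         ratio = splits$ratio, seed = splits$seed,
         classes = lapply(splits$specs, function(s) s[names(s) != "class"])),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(labels)
}
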