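# InceptionV3-like architecture builder and truncation ("layer shaving")
# surgery.  The channel plan follows the canonical InceptionV3 feature
# extractor (stem Conv1..Conv5, inception modules Mixed0..Mixed10, final
# feature depth 2048) topped with a global average pooling layer ("GAP") and
# a dense classification head ("output").  Batchnorm layers follow the usual
# inception convention of a per-channel shift without a scale, so each
# contributes 3 parameters per channel (shift + the two moving statistics);
# with a 38-class head this reproduces the canonical totals of 21,880,646
# parameters for the full model and 5,167,878 when cut at Mixed5.

# A conv -> batchnorm -> relu block; the block name is the relu layer so
# that capturing "Conv1" yields the post-activation output.
conv_bn <- function(name, parent, filters, kernel, stride = 1L, padding = "same") {
  list(
    layer_spec(paste0(name, "_conv"), "conv2d", parents = parent,
               filters = filters, kernel = kernel, stride = stride,
               padding = padding, use_bias = FALSE),
    layer_spec(paste0(name, "_bn"), "batchnorm",
               parents = paste0(name, "_conv"), scale = FALSE),
    layer_spec(name, "relu", parents = paste0(name, "_bn")))
}

# 35x35-type module (Mixed0..Mixed2): 1x1 / 5x5 / double-3x3 / pooled-1x1.
mixed_block_a <- function(name, parent, pool_filters) {
  c(conv_bn(paste0(name, "_b1"), parent, 64, 1),
    conv_bn(paste0(name, "_b5_1"), parent, 48, 1),
    conv_bn(paste0(name, "_b5_2"), paste0(name, "_b5_1"), 64, 5),
    conv_bn(paste0(name, "_bd_1"), parent, 64, 1),
    conv_bn(paste0(name, "_bd_2"), paste0(name, "_bd_1"), 96, 3),
    conv_bn(paste0(name, "_bd_3"), paste0(name, "_bd_2"), 96, 3),
    list(layer_spec(paste0(name, "_pool"), "avgpool", parents = parent,
                    pool = 3, stride = 1, padding = "same")),
    conv_bn(paste0(name, "_bp"), paste0(name, "_pool"), pool_filters, 1),
    list(layer_spec(name, "concat",
                    parents = c(paste0(name, "_b1"), paste0(name, "_b5_2"),
                                paste0(name, "_bd_3"), paste0(name, "_bp")))))
}

# Grid reduction module (Mixed3).
mixed_block_reduce_a <- function(name, parent, reduce_padding) {
  c(conv_bn(paste0(name, "_b3"), parent, 384, 3, stride = 2,
            padding = reduce_padding),
    conv_bn(paste0(name, "_bd_1"), parent, 64, 1),
    conv_bn(paste0(name, "_bd_2"), paste0(name, "_bd_1"), 96, 3),
    conv_bn(paste0(name, "_bd_3"), paste0(name, "_bd_2"), 96, 3, stride = 2,
            padding = reduce_padding),
    list(layer_spec(paste0(name, "_pool"), "maxpool", parents = parent,
                    pool = 3, stride = 2, padding = reduce_padding)),
    list(layer_spec(name, "concat",
                    parents = c(paste0(name, "_b3"), paste0(name, "_bd_3"),
                                paste0(name, "_pool")))))
}

# 17x17-type module (Mixed4..Mixed7) with factorized 7x7 convolutions.
mixed_block_b <- function(name, parent, c7) {
  c(conv_bn(paste0(name, "_b1"), parent, 192, 1),
    conv_bn(paste0(name, "_b7_1"), parent, c7, 1),
    conv_bn(paste0(name, "_b7_2"), paste0(name, "_b7_1"), c7, c(1, 7)),
    conv_bn(paste0(name, "_b7_3"), paste0(name, "_b7_2"), 192, c(7, 1)),
    conv_bn(paste0(name, "_bd_1"), parent, c7, 1),
    conv_bn(paste0(name, "_bd_2"), paste0(name, "_bd_1"), c7, c(7, 1)),
    conv_bn(paste0(name, "_bd_3"), paste0(name, "_bd_2"), c7, c(1, 7)),
    conv_bn(paste0(name, "_bd_4"), paste0(name, "_bd_3"), c7, c(7, 1)),
    conv_bn(paste0(name, "_bd_5"), paste0(name, "_bd_4"), 192, c(1, 7)),
    list(layer_spec(paste0(name, "_pool"), "avgpool", parents = parent,
                    pool = 3, stride = 1, padding = "same")),
    conv_bn(paste0(name, "_bp"), paste0(name, "_pool"), 192, 1),
    list(layer_spec(name, "concat",
                    parents = c(paste0(name, "_b1"), paste0(name, "_b7_3"),
                                paste0(name, "_bd_5"), paste0(name, "_bp")))))
}

# Grid reduction module (Mixed8).
mixed_block_reduce_b <- function(name, parent, reduce_padding) {
  c(conv_bn(paste0(name, "_b3_1"), parent, 192, 1),
    conv_bn(paste0(name, "_b3_2"), paste0(name, "_b3_1"), 320, 3, stride = 2,
            padding = reduce_padding),
    conv_bn(paste0(name, "_b7_1"), parent, 192, 1),
    conv_bn(paste0(name, "_b7_2"), paste0(name, "_b7_1"), 192, c(1, 7)),
    conv_bn(paste0(name, "_b7_3"), paste0(name, "_b7_2"), 192, c(7, 1)),
    conv_bn(paste0(name, "_b7_4"), paste0(name, "_b7_3"), 192, 3, stride = 2,
            padding = reduce_padding),
    list(layer_spec(paste0(name, "_pool"), "maxpool", parents = parent,
                    pool = 3, stride = 2, padding = reduce_padding)),
    list(layer_spec(name, "concat",
                    parents = c(paste0(name, "_b3_2"), paste0(name, "_b7_4"),
                                paste0(name, "_pool")))))
}

# 8x8-type module (Mixed9, Mixed10) with split 1x3 / 3x1 branches.
mixed_block_c <- function(name, parent) {
  c(conv_bn(paste0(name, "_b1"), parent, 320, 1),
    conv_bn(paste0(name, "_b3_1"), parent, 384, 1),
    conv_bn(paste0(name, "_b3_2a"), paste0(name, "_b3_1"), 384, c(1, 3)),
    conv_bn(paste0(name, "_b3_2b"), paste0(name, "_b3_1"), 384, c(3, 1)),
    conv_bn(paste0(name, "_bd_1"), parent, 448, 1),
    conv_bn(paste0(name, "_bd_2"), paste0(name, "_bd_1"), 384, 3),
    conv_bn(paste0(name, "_bd_3a"), paste0(name, "_bd_2"), 384, c(1, 3)),
    conv_bn(paste0(name, "_bd_3b"), paste0(name, "_bd_2"), 384, c(3, 1)),
    list(layer_spec(paste0(name, "_pool"), "avgpool", parents = parent,
                    pool = 3, stride = 1, padding = "same")),
    conv_bn(paste0(name, "_bp"), paste0(name, "_pool"), 192, 1),
    list(layer_spec(name, "concat",
                    parents = c(paste0(name, "_b1"),
                                paste0(name, "_b3_2a"), paste0(name, "_b3_2b"),
                                paste0(name, "_bd_3a"), paste0(name, "_bd_3b"),
                                paste0(name, "_bp")))))
}

#' Build an InceptionV3-like classifier graph
#'
#' Constructs the canonical InceptionV3 feature extractor (Conv1..Conv5,
#' Mixed0..Mixed10, 2048 final channels) followed by global average pooling
#' (`"GAP"`), a dense head (`"output"`, pre-softmax logits) and a softmax
#' layer (`"predictions"`).
#'
#' Two padding dialects are offered.  `"all_same"` (default) pads every
#' convolution and pooling layer `same`, so a 224 x 224 input reaches
#' Mixed10 at 7 x 7 resolution; `"standard_stem"` uses the canonical
#' valid-padded stem and reduction blocks.  The parameter count is identical
#' under both dialects.
#'
#' @param n_classes number of output classes.
#' @param input_size square input resolution in pixels; must be divisible by
#'   32 for the `all_same` dialect.
#' @param padding_dialect `"all_same"` or `"standard_stem"`.
#' @param init,seed weight initialization, as in [build_graph()].
#' @return a `layer_graph`.
#' @examples
#' g <- build_inception_v3_like(38, init = "zeros")
#' count_parameters(g)$total      # 21,880,646
#' g$shapes[["Mixed10"]]          # 7 7 2048
#' @export
build_inception_v3_like <- function(n_classes, input_size = 224L,
                                    padding_dialect = c("all_same", "standard_stem"),
                                    init = "random", seed = 0L) {
  padding_dialect <- match.arg(padding_dialect)
  all_same <- padding_dialect == "all_same"
  if (all_same && input_size %% 32L != 0L)
    stopf("input_size must be divisible by 32 for the all_same dialect")
  if (!all_same && input_size < 75L)
    stopf("input_size too small for the standard_stem dialect")
  vd <- if (all_same) "same" else "valid"
  specs <- c(
    list(layer_spec("in", "input", shape = c(input_size, input_size, 3))),
    conv_bn("Conv1", "in", 32, 3, stride = 2, padding = vd),
    conv_bn("Conv2", "Conv1", 32, 3, padding = vd),
    conv_bn("Conv3", "Conv2", 64, 3, padding = "same"),
    list(layer_spec("Pool1", "maxpool", parents = "Conv3", pool = 3,
                    stride = 2, padding = vd)),
    conv_bn("Conv4", "Pool1", 80, 1, padding = vd),
    conv_bn("Conv5", "Conv4", 192, 3, padding = vd),
    list(layer_spec("Pool2", "maxpool", parents = "Conv5", pool = 3,
                    stride = 2, padding = vd)),
    mixed_block_a("Mixed0", "Pool2", 32),
    mixed_block_a("Mixed1", "Mixed0", 64),
    mixed_block_a("Mixed2", "Mixed1", 64),
    mixed_block_reduce_a("Mixed3", "Mixed2", vd),
    mixed_block_b("Mixed4", "Mixed3", 128),
    mixed_block_b("Mixed5", "Mixed4", 160),
    mixed_block_b("Mixed6", "Mixed5", 160),
    mixed_block_b("Mixed7", "Mixed6", 192),
    mixed_block_reduce_b("Mixed8", "Mixed7", vd),
    mixed_block_c("Mixed9", "Mixed8"),
    mixed_block_c("Mixed10", "Mixed9"),
    list(layer_spec("GAP", "global_avg_pool", parents = "Mixed10"),
         layer_spec("output", "dense", parents = "GAP", units = n_classes),
         layer_spec("predictions", "softmax", parents = "output")))
  build_graph(specs, init = init, seed = seed)
}

# All ancestors of a layer (by name), including the layer itself.
ancestor_set <- function(graph, layer) {
  keep <- character(0)
  stack <- layer
  while (length(stack)) {
    nm <- stack[[1]]; stack <- stack[-1]
    if (nm %in% keep) next
    keep <- c(keep, nm)
    stack <- c(stack, graph$specs[[nm]]$parents)
  }
  keep
}

#' Truncate a graph at a named layer ("layer shaving")
#'
#' Keeps the subgraph up to and including `cut_layer` with its trained
#' weights, and attaches a fresh global average pooling layer (`"GAP"`), a
#' randomly initialized dense head (`"output"`) sized to the cut layer's
#' channel depth, and a softmax (`"predictions"`).  The original graph is
#' not modified.
#'
#' @param graph a `layer_graph` whose cut layer has spatial extent.
#' @param cut_layer name of the last feature layer to keep.
#' @param n_classes number of classes for the new head.
#' @param head_init_seed seed for the head's random initialization.
#' @return a new `layer_graph`.
#' @export
truncate_at <- function(graph, cut_layer, n_classes, head_init_seed = 0L) {
  if (!cut_layer %in% names(graph$specs))
    stopf("unknown layer '%s'", cut_layer)
  kind <- graph$specs[[cut_layer]]$kind
  if (kind %in% c("global_avg_pool", "dense", "softmax"))
    stopf("cannot cut at '%s': layer has no spatial extent", cut_layer)
  if (length(graph$shapes[[cut_layer]]) != 3L)
    stopf("cut layer '%s' must have spatial extent", cut_layer)
  keep <- ancestor_set(graph, cut_layer)
  kept_specs <- unname(graph$specs[graph$order[graph$order %in% keep]])
  head_specs <- list(
    layer_spec("GAP", "global_avg_pool", parents = cut_layer),
    layer_spec("output", "dense", parents = "GAP", units = n_classes),
    layer_spec("predictions", "softmax", parents = "output"))
  if (any(c("GAP", "output", "predictions") %in% keep))
    stopf("cut subgraph already contains a layer named GAP/output/predictions")
  new_graph <- build_graph(c(kept_specs, head_specs), init = "random",
                           seed = head_init_seed)
  for (nm in intersect(names(graph$weights), keep))
    new_graph$weights[[nm]] <- graph$weights[[nm]]
  new_graph
}
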