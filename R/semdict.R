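# Visualization III: semantic dictionary at the global-average-pooling
# layer.  The pre-softmax score of class j decomposes exactly as
#   logit_j = sum_k a_k * W[k, j] + b_j
# where a is the GAP activation vector; each summand a_k * W[k, j] is the
# contribution score of GAP neuron k to class j.  Ranking neurons by their
# mean contribution over a set of same-class images, and pairing the top
# ones with their feature-visualization renders, yields a dictionary of the
# visual features the network actually uses for that diagnosis.

# GAP activation vector and head weights of a GAP+dense graph.
gap_head <- function(graph) {
  gl <- gap_layer(graph)
  dense <- NULL
  for (nm in names(graph$specs)) {
    s <- graph$specs[[nm]]
    if (s$kind == "dense" && gl %in% s$parents) dense <- nm
  }
  if (is.null(dense)) stopf("graph has no dense head on the GAP layer")
  list(gap = gl, dense = dense,
       W = graph$weights[[dense]]$kernel,
       b = graph$weights[[dense]]$bias %||%
         numeric(ncol(graph$weights[[dense]]$kernel)))
}

#' Per-neuron contribution scores for one class
#'
#' `contribution_scores()` is the pure arithmetic: scores
#' `c_k = a_k * W[k, j]`, whose sum plus the bias is exactly the
#' pre-softmax logit.  `contribution_table()` computes the same from a
#' graph and an input image.
#'
#' @param a GAP activation vector.
#' @param W dense head weight matrix (gap_dim x n_classes).
#' @param b bias vector (length n_classes).
#' @param class 1-based class index.
#' @return tibble with columns `neuron`, `score`, plus attributes `bias`
#'   and `logit`.
#' @examples
#' contribution_scores(c(1, 2), matrix(c(0.5, -1), ncol = 1), 0.1, 1)
#' @export
contribution_scores <- function(a, W, b, class) {
  if (is.null(dim(W))) W <- matrix(W, ncol = 1)
  if (length(a) != nrow(W)) stopf("GAP vector length %d does not match W rows %d",
                                  length(a), nrow(W))
  if (class < 1 || class > ncol(W)) stopf("class %d out of range", class)
  scores <- a * W[, class]
  out <- tibble::tibble(neuron = seq_along(a), score = scores)
  attr(out, "bias") <- b[min(class, length(b))]
  attr(out, "logit") <- sum(scores) + attr(out, "bias")
  out
}

#' @rdname contribution_scores
#' @param graph a `layer_graph` with a GAP + dense head.
#' @param image input image.
#' @export
contribution_table <- function(graph, image, class) {
  h <- gap_head(graph)
  fw <- forward(graph, image, capture = h$gap, keep_state = FALSE)
  contribution_scores(fw$captured[[h$gap]], h$W, h$b, class)
}

#' Mean contribution scores over a set of images, ranked
#'
#' Element-wise mean of per-image contribution scores (equivalently, the
#' scores of the mean GAP vector, since the scores are linear in the
#' activations), sorted by descending score with ties broken by neuron
#' index.
#'
#' @inheritParams contribution_table
#' @param images non-empty list of images.
#' @return tibble (`neuron`, `score`) sorted by descending score, with
#'   attributes `bias` and `mean_logit`.
#' @export
mean_contributions <- function(graph, images, class) {
  if (!length(images)) stopf("empty image list")
  h <- gap_head(graph)
  gaps <- vapply(images, function(im)
    forward(graph, im, capture = h$gap, keep_state = FALSE)$captured[[h$gap]],
    numeric(nrow(h$W)))
  a_mean <- if (is.null(dim(gaps))) mean(gaps) else rowMeans(gaps)
  out <- contribution_scores(a_mean, h$W, h$b, class)
  attr_bias <- attr(out, "bias"); attr_logit <- attr(out, "logit")
  out <- out[order(-out$score, out$neuron), ]
  attr(out, "bias") <- attr_bias
  attr(out, "mean_logit") <- attr_logit
  out
}

#' Build a semantic dictionary for a class
#'
#' Ranks GAP neurons by their mean contribution to `class` over `images`,
#' applies feature visualization to the top `top_n` neurons (as channels of
#' the layer feeding the GAP), and tabulates each top neuron's mean
#' contribution to every class in `classes` (the cross-class bar-chart
#' data).
#'
#' @inheritParams mean_contributions
#' @param top_n how many top-contributing neurons to visualize; 6 by
#'   default, configurable (comparable studies also use 5).
#' @param classes integer vector of classes for the cross-class score
#'   table; defaults to all classes of the head.
#' @param steps,lr,seed feature-visualization settings, see
#'   [visualize_neuron()].
#' @return a `semantic_dictionary`: list with `entries` (list of
#'   `neuron`, `score`, `render`), `ranking` (the full ranked tibble),
#'   `cross_class` (tibble `neuron` x `class` x `score`), `class`.
#' @export
build_dictionary <- function(graph, images, class, top_n = 6L, classes = NULL,
                             steps = 128L, lr = 0.05, seed = 0L) {
  h <- gap_head(graph)
  if (top_n > nrow(h$W)) stopf("top_n exceeds the GAP dimension (%d)", nrow(h$W))
  ranking <- mean_contributions(graph, images, class)
  feature_layer <- graph$specs[[h$gap]]$parents[1]
  top <- utils::head(ranking, top_n)
  entries <- lapply(seq_len(nrow(top)), function(i) {
    vis <- visualize_neuron(graph, neuron_selector(feature_layer, top$neuron[i]),
                            steps = steps, lr = lr, seed = seed + i)
    list(neuron = top$neuron[i], score = top$score[i], render = vis$image,
         trace = vis$trace)
  })
  if (is.null(classes)) classes <- seq_len(ncol(h$W))
  cross <- list()
  for (cl in classes) {
    rk <- mean_contributions(graph, images, cl)
    sel <- rk[match(top$neuron, rk$neuron), ]
    cross[[length(cross) + 1L]] <- tibble::tibble(
      neuron = top$neuron, class = cl, score = sel$score)
  }
  structure(list(entries = entries, ranking = ranking,
                 cross_class = do.call(rbind, cross), class = class),
            class = "semantic_dictionary")
}

#' @export
print.semantic_dictionary <- function(x, ...) {
  cat(sprintf("<semantic_dictionary> class %d, top %d neurons: %s\n",
              x$class, length(x$entries),
              paste(vapply(x$entries, `[[`, numeric(1), "neuron"), collapse = ", ")))
  invisible(x)
}
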