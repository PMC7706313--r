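# Layer-graph construction, validation, forward evaluation and parameter
# accounting.

# Instrumentation counters: every full forward and backward pass increments
# one of these.  Used to verify cost contracts of the attention methods
# (e.g. the explanation map never triggers a backward pass).
.counters <- new.env(parent = emptyenv())
.counters$forward <- 0L
.counters$backward <- 0L

#' Reset or read the forward/backward pass counters
#'
#' The engine counts every forward and backward evaluation of a graph.
#' Perturbation methods pay in forward passes, gradient methods in backward
#' passes and the explanation map in neither, so the counters make the cost
#' profile of each attention method observable.
#'
#' @return `viz_counters()` returns a named integer vector with elements
#'   `forward` and `backward`.
#' @export
viz_counters <- function() {
  c(forward = .counters$forward, backward = .counters$backward)
}

#' @rdname viz_counters
#' @export
viz_counters_reset <- function() {
  .counters$forward <- 0L
  .counters$backward <- 0L
  invisible(NULL)
}

topo_sort <- function(specs) {
  names_ <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(names_))
    stopf("duplicate layer name '%s'", names_[duplicated(names_)][1])
  by_name <- stats::setNames(specs, names_)
  for (s in specs) {
    missing <- setdiff(s$parents, names_)
    if (length(missing))
      stopf("layer '%s' references unknown parent '%s'", s$name, missing[1])
  }
  indeg <- vapply(specs, function(s) length(s$parents), integer(1))
  names(indeg) <- names_
  children <- stats::setNames(vector("list", length(names_)), names_)
  for (s in specs) for (p in s$parents) children[[p]] <- c(children[[p]], s$name)
  queue <- names_[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    order <- c(order, n)
    for (ch in children[[n]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(names_))
    stopf("layer graph contains a cycle involving '%s'",
          setdiff(names_, order)[1])
  order
}

#' Build a layer graph with allocated weights
#'
#' Validates a list of [layer_spec()]s (unique names, acyclic, exactly one
#' input, consistent shapes, no conv bias directly under a batchnorm),
#' infers every layer's output shape and allocates its weight arrays.
#'
#' @param specs list of [layer_spec()] objects.
#' @param init `"random"` (glorot-uniform kernels, seed-deterministic),
#'   `"zeros"`, or a named list of per-layer weight lists to use verbatim.
#' @param seed integer seed used when `init = "random"`.
#' @return an object of class `layer_graph` with elements `specs`, `order`
#'   (topological), `shapes`, `weights`, `input` (input layer name).
#' @examples
#' g <- build_graph(list(
#'   layer_spec("in", "input", shape = c(8, 8, 3)),
#'   layer_spec("gap", "global_avg_pool", parents = "in"),
#'   layer_spec("out", "dense", parents = "gap", units = 2),
#'   layer_spec("prob", "softmax", parents = "out")), init = "zeros")
#' count_parameters(g)
#' @export
build_graph <- function(specs, init = "random", seed = 0L) {
  if (!length(specs)) stopf("empty layer list")
  order <- topo_sort(specs)
  by_name <- stats::setNames(specs, vapply(specs, function(s) s$name, character(1)))
  inputs <- names(by_name)[vapply(by_name, function(s) s$kind == "input", logical(1))]
  if (length(inputs) != 1L)
    stopf("graph must have exactly one input layer (found %d)", length(inputs))
  # inception convention: a conv feeding a batchnorm carries no bias
  for (s in specs) {
    if (s$kind == "batchnorm") {
      for (p in s$parents) {
        ps <- by_name[[p]]
        if (ps$kind == "conv2d" && isTRUE(ps$params$use_bias))
          stopf("conv2d '%s' must not use a bias when followed by batchnorm '%s'",
                p, s$name)
      }
    }
  }
  shapes <- list()
  for (nm in order) {
    s <- by_name[[nm]]
    shapes[[nm]] <- unname(infer_shape(s, shapes[s$parents]))
  }
  provided <- is.list(init)
  weights <- list()
  alloc <- function() {
    for (nm in order) {
      s <- by_name[[nm]]
      in_shape <- if (length(s$parents)) shapes[[s$parents[1]]] else NULL
      w <- alloc_weights(s, in_shape, if (provided) "zeros" else init)
      if (!is.null(w)) weights[[nm]] <<- w
    }
  }
  if (provided) {
    alloc()
    for (nm in names(weights)) {
      for (par in names(weights[[nm]])) {
        got <- init[[nm]][[par]]
        if (is.null(got))
          stopf("provided weights missing '%s/%s'", nm, par)
        if (!identical(dim(got) %||% length(got),
                       dim(weights[[nm]][[par]]) %||% length(weights[[nm]][[par]])))
          stopf("provided weights for '%s/%s' have the wrong shape", nm, par)
        weights[[nm]][[par]] <- got
      }
    }
  } else if (identical(init, "random")) {
    withr::with_seed(as.integer(seed), alloc())
  } else if (identical(init, "zeros")) {
    alloc()
  } else stopf("unknown init '%s'", as.character(init)[1])
  structure(list(specs = by_name, order = order, shapes = shapes,
                 weights = weights, input = inputs),
            class = "layer_graph")
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("<layer_graph> %d layers, input '%s' (%s)\n",
              length(x$order), x$input,
              paste(x$shapes[[x$input]], collapse = "x")))
  rep_ <- count_parameters(x)
  cat(sprintf("  parameters: %s (%s trainable)\n",
              format(rep_$total, big.mark = ","),
              format(sum(rep_$report$trainable), big.mark = ",")))
  invisible(x)
}

# Name of the layer producing the pre-softmax logits (parent of the softmax
# layer, or the terminal layer when no softmax is present).
logit_layer <- function(graph) {
  sm <- names(graph$specs)[vapply(graph$specs, function(s) s$kind == "softmax",
                                  logical(1))]
  if (length(sm)) graph$specs[[sm[1]]]$parents[1]
  else graph$order[length(graph$order)]
}

gap_layer <- function(graph) {
  gl <- names(graph$specs)[vapply(graph$specs,
                                  function(s) s$kind == "global_avg_pool",
                                  logical(1))]
  if (!length(gl)) stopf("graph has no global_avg_pool layer")
  gl[1]
}

#' Forward-evaluate a layer graph
#'
#' Runs a single image (H x W x C array) or a list of images through the
#' graph in inference mode (batchnorm uses its moving statistics) and
#' optionally captures the post-activation output of named layers.
#'
#' @param graph a [build_graph()] result.
#' @param x image array matching the input spec, or a list of such arrays.
#' @param capture character vector of layer names whose outputs to return.
#' @param keep_state keep every intermediate activation (needed by
#'   [backward()]); implied for single images.
#' @return for a single image, a list with `probs` (softmax vector, or the
#'   terminal output if the graph has no softmax layer), `logits`,
#'   `captured` (named list) and `state` (all activations).  For a list of
#'   images, a list with a `probs` matrix (images x classes), `logits`
#'   matrix and per-image `captured` lists.
#' @export
forward <- function(graph, x, capture = character(), keep_state = TRUE) {
  unknown <- setdiff(capture, names(graph$specs))
  if (length(unknown)) stopf("unknown capture layer '%s'", unknown[1])
  if (is.list(x) && !is.array(x)) {
    res <- lapply(x, function(xi) forward(graph, xi, capture, keep_state = FALSE))
    return(list(probs = do.call(rbind, lapply(res, `[[`, "probs")),
                logits = do.call(rbind, lapply(res, `[[`, "logits")),
                captured = lapply(res, `[[`, "captured")))
  }
  in_shape <- graph$shapes[[graph$input]]
  if (!identical(as.integer(dim(x)), as.integer(in_shape)))
    stopf("input shape (%s) does not match the graph input (%s)",
          paste(dim(x), collapse = "x"), paste(in_shape, collapse = "x"))
  .counters$forward <- .counters$forward + 1L
  acts <- list()
  for (nm in graph$order) {
    s <- graph$specs[[nm]]
    ins <- if (s$kind == "input") list(x) else acts[s$parents]
    acts[[nm]] <- layer_forward(s, graph$weights[[nm]], ins)
  }
  lgt <- acts[[logit_layer(graph)]]
  out <- acts[[graph$order[length(graph$order)]]]
  list(probs = out, logits = lgt,
       captured = acts[capture],
       state = if (keep_state) acts else NULL)
}

#' Count the parameters of a graph
#'
#' Counts every stored weight-array element layer by layer.  Batchnorm
#' moving statistics are reported as non-trainable but included in the
#' total, matching how deep-learning frameworks report model size.
#'
#' @param graph a `layer_graph`.
#' @return object of class `param_report`: list with `report` (a tibble with
#'   columns `layer`, `trainable`, `non_trainable`) and `total`.
#' @export
count_parameters <- function(graph) {
  rows <- lapply(graph$order, function(nm) {
    w <- graph$weights[[nm]]
    if (is.null(w)) return(NULL)
    tr <- sum(vapply(w[setdiff(names(w), NON_TRAINABLE)], length, numeric(1)))
    nt <- sum(vapply(w[intersect(names(w), NON_TRAINABLE)], length, numeric(1)))
    tibble::tibble(layer = nm, trainable = tr, non_trainable = nt)
  })
  report <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(report))
    report <- tibble::tibble(layer = character(), trainable = numeric(),
                             non_trainable = numeric())
  structure(list(report = report,
                 total = sum(report$trainable) + sum(report$non_trainable)),
            class = "param_report")
}

#' @export
print.param_report <- function(x, ...) {
  cat(sprintf("<param_report> total %s (trainable %s, non-trainable %s)\n",
              format(x$total, big.mark = ","),
              format(sum(x$report$trainable), big.mark = ","),
              format(sum(x$report$non_trainable), big.mark = ",")))
  invisible(x)
}

#' Serialize / restore a layer graph
#'
#' Writes a JSON architecture manifest next to an RDS weights blob.  The
#' manifest (`<path>.json`) fully describes the layer specs so that the
#' architecture is human-readable and portable; the weights
#' (`<path>.rds`) hold the numeric arrays keyed `<layer>/<param>`.
#'
#' @param graph a `layer_graph`.
#' @param path file stem (without extension).
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   rebuilt `layer_graph`.
#' @export
save_model <- function(graph, path) {
  manifest <- lapply(unname(graph$specs), function(s)
    list(name = s$name, kind = s$kind, parents = s$parents, params = s$params))
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- list()
  for (nm in names(graph$weights))
    for (par in names(graph$weights[[nm]]))
      flat[[paste(nm, par, sep = "/")]] <- graph$weights[[nm]][[par]]
  saveRDS(flat, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(paste0(path, ".json")))
    stopf("no model manifest at '%s.json'", path)
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  specs <- lapply(manifest, function(m) {
    do.call(layer_spec, c(list(name = m$name, kind = m$kind,
                               parents = unlist(m$parents) %||% character()),
                          m$params))
  })
  flat <- readRDS(paste0(path, ".rds"))
  weights <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    weights[[parts[1]]][[parts[2]]] <- flat[[key]]
  }
  build_graph(specs, init = weights)
}
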