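# Backward propagation with pluggable unit rules.
#
# Three rules are supported at nonlinearities:
#   vanilla  - exact analytic gradient.
#   guided   - ReLU backward signal zeroed where either the forward
#              pre-activation or the incoming backward signal is negative.
#   rescale  - DeepLIFT-style multipliers: at a ReLU the multiplier is
#              delta-output / delta-input relative to a reference forward
#              pass, falling back to the gradient when |delta-input| < 1e-7;
#              affine layers use the exact linear rule.

#' Backward-pass target selectors
#'
#' Helpers building the scalar target whose sensitivity [backward()]
#' propagates: a class logit, the spatial mean of one channel of a layer, or
#' an arbitrary weighted sum of a layer's output (pass `weights`).
#'
#' @param class integer class index (1-based).
#' @param layer layer name.
#' @param channel channel index within the layer.
#' @param weights array of the layer's output shape; the target is
#'   `sum(weights * activation)`.
#' @return a target descriptor consumed by [backward()].
#' @export
target_logit <- function(class) {
  structure(list(type = "logit", class = as.integer(class)), class = "bw_target")
}

#' @rdname target_logit
#' @export
target_neuron_mean <- function(layer, channel) {
  structure(list(type = "neuron_mean", layer = layer,
                 channel = as.integer(channel)), class = "bw_target")
}

#' @rdname target_logit
#' @export
target_weighted_sum <- function(layer, weights) {
  structure(list(type = "weighted", layer = layer, weights = weights),
            class = "bw_target")
}

resolve_seed <- function(graph, state, target) {
  if (inherits(target, "bw_target")) {
    switch(target$type,
      logit = {
        ll <- logit_layer(graph)
        g <- numeric(length(state[[ll]]))
        g[target$class] <- 1
        list(layer = ll, grad = g)
      },
      neuron_mean = {
        act <- state[[target$layer]]
        if (is.null(act)) stopf("unknown target layer '%s'", target$layer)
        if (is.null(dim(act))) {
          g <- numeric(length(act)); g[target$channel] <- 1
        } else {
          d <- dim(act)
          if (target$channel > d[3]) stopf("channel %d out of range", target$channel)
          g <- array(0, dim = d)
          g[, , target$channel] <- 1 / (d[1] * d[2])
        }
        list(layer = target$layer, grad = g)
      },
      weighted = list(layer = target$layer, grad = target$weights))
  } else if (is.list(target) && !is.null(target$layer) && !is.null(target$grad)) {
    target
  } else stopf("invalid backward target")
}

#' Back-propagate a scalar target through a graph
#'
#' @param graph a `layer_graph`.
#' @param state the `state` element of a [forward()] call on the same graph
#'   and input.
#' @param target a [target_logit()], [target_neuron_mean()],
#'   [target_weighted_sum()], or `list(layer =, grad =)` seed.
#' @param rule propagation rule: `"vanilla"`, `"guided"` or `"rescale"`.
#' @param reference forward `state` of the reference input; required by the
#'   rescale rule.
#' @param capture_grad layer names whose accumulated backward signal to
#'   return in addition to the input's.
#' @return list with `input` (signal w.r.t. the input image; for the rescale
#'   rule these are DeepLIFT multipliers, multiply by `x - reference` to get
#'   contributions) and `layers` (named list for `capture_grad`).
#' @export
backward <- function(graph, state, target,
                     rule = c("vanilla", "guided", "rescale"),
                     reference = NULL, capture_grad = character()) {
  rule <- match.arg(rule)
  if (rule == "rescale" && is.null(reference))
    stopf("the rescale rule requires reference activations")
  seed <- resolve_seed(graph, state, target)
  res <- propagate(graph, state, seed$layer, seed$grad, rule, reference,
                   capture_grad = capture_grad)
  list(input = res$grads[[graph$input]] %||%
         array(0, dim = graph$shapes[[graph$input]]),
       layers = res$grads[capture_grad])
}

# Core reverse traversal.  `trainable` (optional named logical) activates
# weight-gradient computation and subgraph pruning for training: the signal
# is only propagated into parents whose ancestor closure contains a
# trainable layer (or the input, when input_grad = TRUE).
propagate <- function(graph, state, seed_layer, seed_grad, rule,
                      ref_state = NULL, capture_grad = character(),
                      trainable = NULL, input_grad = is.null(trainable)) {
  .counters$backward <- .counters$backward + 1L
  order <- graph$order
  need <- stats::setNames(rep(TRUE, length(order)), order)
  if (!is.null(trainable) || length(capture_grad)) {
    keep <- stats::setNames(rep(FALSE, length(order)), order)
    for (nm in order) {
      self <- (!is.null(trainable) && isTRUE(trainable[[nm]])) ||
        nm %in% capture_grad || (input_grad && nm == graph$input)
      keep[[nm]] <- self || any(vapply(graph$specs[[nm]]$parents,
                                       function(p) keep[[p]], logical(1)))
    }
    # propagate into nm only if nm itself or something upstream is needed
    need <- keep
  }
  grads <- list()
  grads[[seed_layer]] <- seed_grad
  wgrads <- list()
  start <- match(seed_layer, order)
  for (i in seq(start, 1L)) {
    nm <- order[i]
    g <- grads[[nm]]
    if (is.null(g)) next
    s <- graph$specs[[nm]]
    if (s$kind == "input") next
    want_dw <- !is.null(trainable) && isTRUE(trainable[[nm]]) &&
      !is.null(graph$weights[[nm]])
    ins <- state[s$parents]
    parent_needed <- vapply(s$parents, function(p) isTRUE(need[[p]]), logical(1))
    if (!want_dw && !any(parent_needed)) next
    if (s$kind == "relu") {
      x <- ins[[1]]
      dx <- switch(rule,
        vanilla = g * (x > 0),
        guided = g * (x > 0) * (g > 0),
        rescale = {
          xr <- ref_state[[s$parents[1]]]
          dxv <- x - xr
          dyv <- state[[nm]] - ref_state[[nm]]
          mult <- ifelse(abs(dxv) < 1e-7, as.numeric(x > 0), dyv / dxv)
          out <- g * mult
          if (!is.null(dim(x))) dim(out) <- dim(x)
          out
        })
      dins <- list(dx)
      dw <- NULL
    } else if (s$kind == "maxpool") {
      dins <- list(layer_backward_maxpool(s, ins[[1]], g))
      dw <- NULL
    } else {
      bk <- layer_backward_linear(s, graph$weights[[nm]], ins, state[[nm]],
                                  g, want_dw = want_dw)
      dins <- bk$dinputs
      dw <- bk$dweights
    }
    if (!is.null(dw)) wgrads[[nm]] <- dw
    for (k in seq_along(s$parents)) {
      p <- s$parents[k]
      if (!isTRUE(need[[p]])) next
      grads[[p]] <- if (is.null(grads[[p]])) dins[[k]] else grads[[p]] + dins[[k]]
    }
  }
  list(grads = grads, wgrads = wgrads)
}
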