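#' Define a layer of a network graph
#'
#' A `layer_spec` is the declarative description of one node of a graph
#' built by [build_graph()]: its name, its kind, kind-specific hyperparameters
#' and the names of its parent layers.  Supported kinds are `input`,
#' `conv2d`, `batchnorm`, `relu`, `maxpool`, `avgpool`, `global_avg_pool`,
#' `dense`, `concat` and `softmax`.
#'
#' Hyperparameters by kind:
#' * `input`: `shape = c(h, w, c)`.
#' * `conv2d`: `filters`, `kernel` (length 1 or 2), `stride` (default 1),
#'   `padding` (`"same"` or `"valid"`), `use_bias` (default `TRUE`; must be
#'   `FALSE` when the layer feeds a batchnorm, the usual inception
#'   convention).
#' * `batchnorm`: `scale` (`TRUE` keeps a per-channel gamma; the
#'   InceptionV3-like builder uses `FALSE`), `eps` (default `1e-3`).
#' * `maxpool` / `avgpool`: `pool`, `stride`, `padding`.
#' * `dense`: `units`, `use_bias` (default `TRUE`).
#'
#' @param name unique layer name.
#' @param kind layer kind (see Details).
#' @param parents character vector of parent layer names (empty for `input`).
#' @param ... kind-specific hyperparameters.
#' @return an object of class `layer_spec`.
#' @export
layer_spec <- function(name, kind, parents = character(), ...) {
  kinds <- c("input", "conv2d", "batchnorm", "relu", "maxpool", "avgpool",
             "global_avg_pool", "dense", "concat", "softmax")
  kind <- match.arg(kind, kinds)
  params <- list(...)
  defaults <- switch(kind,
    conv2d = list(stride = 1L, padding = "same", use_bias = TRUE),
    batchnorm = list(scale = TRUE, eps = 1e-3),
    maxpool = list(stride = 1L, padding = "valid"),
    avgpool = list(stride = 1L, padding = "valid"),
    dense = list(use_bias = TRUE),
    list())
  for (nm in names(defaults)) {
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  }
  if (kind == "conv2d" && length(params$kernel) == 1L) {
    params$kernel <- rep(as.integer(params$kernel), 2L)
  }
  if (kind %in% c("maxpool", "avgpool") && length(params$pool) == 1L) {
    params$pool <- rep(as.integer(params$pool), 2L)
  }
  structure(list(name = name, kind = kind,
                 parents = as.character(parents), params = params),
            class = "layer_spec")
}

# ---- shape inference ------------------------------------------------------

# Shapes are c(h, w, c) for spatial layers or a single integer for vectors.
infer_shape <- function(spec, parent_shapes) {
  p <- spec$params
  one <- function() {
    if (length(parent_shapes) != 1L)
      stopf("layer '%s' expects exactly one parent", spec$name)
    parent_shapes[[1]]
  }
  switch(spec$kind,
    input = as.integer(p$shape),
    conv2d = {
      s <- one()
      if (length(s) != 3L) stopf("conv2d '%s' needs a spatial parent", spec$name)
      st <- rep(as.integer(p$stride), length.out = 2L)
      c(conv_out_len(s[1], p$kernel[1], st[1], p$padding),
        conv_out_len(s[2], p$kernel[2], st[2], p$padding),
        as.integer(p$filters))
    },
    batchnorm = one(),
    relu = one(),
    softmax = one(),
    maxpool = ,
    avgpool = {
      s <- one()
      st <- rep(as.integer(p$stride), length.out = 2L)
      c(conv_out_len(s[1], p$pool[1], st[1], p$padding),
        conv_out_len(s[2], p$pool[2], st[2], p$padding), s[3])
    },
    global_avg_pool = {
      s <- one()
      if (length(s) != 3L) stopf("global_avg_pool '%s' needs a spatial parent", spec$name)
      s[3]
    },
    dense = as.integer(p$units),
    concat = {
      hs <- vapply(parent_shapes, function(s) s[1], numeric(1))
      ws <- vapply(parent_shapes, function(s) s[2], numeric(1))
      if (length(unique(hs)) != 1L || length(unique(ws)) != 1L)
        stopf("concat '%s': parents have unequal spatial dimensions", spec$name)
      c(hs[1], ws[1], sum(vapply(parent_shapes, function(s) s[3], numeric(1))))
    })
}

# ---- weight allocation ----------------------------------------------------

# Glorot-uniform initialization for conv/dense kernels.
glorot <- function(dim, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}

alloc_weights <- function(spec, in_shape, init) {
  p <- spec$params
  zeros <- identical(init, "zeros")
  mk <- function(dim, fan_in, fan_out) {
    if (zeros) array(0, dim = dim) else glorot(dim, fan_in, fan_out)
  }
  switch(spec$kind,
    conv2d = {
      kh <- p$kernel[1]; kw <- p$kernel[2]
      cin <- in_shape[3]; cout <- as.integer(p$filters)
      w <- list(kernel = mk(c(kh, kw, cin, cout), kh * kw * cin, kh * kw * cout))
      if (isTRUE(p$use_bias)) w$bias <- numeric(cout)
      w
    },
    batchnorm = {
      ch <- in_shape[length(in_shape)]
      w <- list(beta = numeric(ch),
                moving_mean = numeric(ch),
                moving_var = rep(1, ch))
      if (isTRUE(p$scale)) w <- c(list(gamma = rep(1, ch)), w)
      w
    },
    dense = {
      din <- if (length(in_shape) == 1L) in_shape else prod(in_shape)
      dout <- as.integer(p$units)
      w <- list(kernel = mk(c(din, dout), din, dout))
      if (isTRUE(p$use_bias)) w$bias <- numeric(dout)
      w
    },
    NULL)
}

# Which parameter arrays are trainable (moving batchnorm statistics are not).
NON_TRAINABLE <- c("moving_mean", "moving_var")

# ---- per-kind forward kernels --------------------------------------------

layer_forward <- function(spec, weights, inputs) {
  p <- spec$params
  x <- inputs[[1]]
  switch(spec$kind,
    input = x,
    relu = pmax(x, 0),
    softmax = softmax_vec(x),
    conv2d = {
      st <- rep(as.integer(p$stride), length.out = 2L)
      ic <- im2col(x, p$kernel[1], p$kernel[2], st[1], st[2], p$padding)
      wm <- matrix(weights$kernel, nrow = prod(dim(weights$kernel)[1:3]))
      out <- ic$patches %*% wm
      if (!is.null(weights$bias)) out <- sweep(out, 2, weights$bias, "+")
      array(out, dim = c(ic$ho, ic$wo, ncol(wm)))
    },
    batchnorm = {
      ch <- dim(x)[3] %||% length(x)
      g <- weights$gamma %||% rep(1, ch)
      sd_inv <- 1 / sqrt(weights$moving_var + p$eps)
      scale <- g * sd_inv
      shift <- weights$beta - weights$moving_mean * scale
      if (is.null(dim(x))) x * scale + shift
      else {
        d <- dim(x)
        array(sweep(sweep(matrix(x, ncol = d[3]), 2, scale, "*"),
                    2, shift, "+"), dim = d)
      }
    },
    maxpool = {
      d <- dim(x); st <- rep(as.integer(p$stride), length.out = 2L)
      if (all(p$pool == 2L) && all(st == 2L) && d[1] %% 2L == 0L &&
          d[2] %% 2L == 0L) {
        # non-overlapping 2x2 fast path
        m1 <- pmax(x[seq(1, d[1], 2), , , drop = FALSE],
                   x[seq(2, d[1], 2), , , drop = FALSE])
        pmax(m1[, seq(1, d[2], 2), , drop = FALSE],
             m1[, seq(2, d[2], 2), , drop = FALSE])
      } else {
        ch_out <- lapply(seq_len(d[3]), function(ci) {
          ic <- im2col(x[, , ci, drop = FALSE], p$pool[1], p$pool[2],
                       st[1], st[2], p$padding, pad_value = -Inf)
          row_max_arg(ic$patches)$max
        })
        ho <- conv_out_len(d[1], p$pool[1], st[1], p$padding)
        wo <- conv_out_len(d[2], p$pool[2], st[2], p$padding)
        array(unlist(ch_out), dim = c(ho, wo, d[3]))
      }
    },
    avgpool = {
      d <- dim(x); st <- rep(as.integer(p$stride), length.out = 2L)
      # "same" padding excludes padded cells from the mean (TF convention)
      ones <- array(1, dim = c(d[1], d[2], 1L))
      cnt <- rowSums(im2col(ones, p$pool[1], p$pool[2], st[1], st[2], p$padding)$patches)
      ch_out <- lapply(seq_len(d[3]), function(ci) {
        ic <- im2col(x[, , ci, drop = FALSE], p$pool[1], p$pool[2],
                     st[1], st[2], p$padding)
        rowSums(ic$patches) / cnt
      })
      ho <- conv_out_len(d[1], p$pool[1], st[1], p$padding)
      wo <- conv_out_len(d[2], p$pool[2], st[2], p$padding)
      array(unlist(ch_out), dim = c(ho, wo, d[3]))
    },
    global_avg_pool = {
      d <- dim(x)
      colMeans(matrix(x, nrow = d[1] * d[2], ncol = d[3]))
    },
    dense = {
      v <- as.numeric(x)
      out <- drop(v %*% weights$kernel)
      if (!is.null(weights$bias)) out <- out + weights$bias
      out
    },
    concat = {
      d1 <- dim(inputs[[1]])
      array(unlist(inputs, use.names = FALSE),
            dim = c(d1[1], d1[2], sum(vapply(inputs, function(a) dim(a)[3], numeric(1)))))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- per-kind backward kernels -------------------------------------------
#
# Each returns list(dinputs = list of gradients w.r.t. each parent,
#                   dweights = list of gradients w.r.t. parameter arrays or NULL).
# `g` is the gradient (or DeepLIFT multiplier) w.r.t. the layer output;
# nonlinearities (relu, maxpool) are handled by the caller so that the
# propagation rule (vanilla / guided / rescale) can be applied there.

layer_backward_linear <- function(spec, weights, inputs, output, g, want_dw = FALSE) {
  p <- spec$params
  x <- inputs[[1]]
  switch(spec$kind,
    input = list(dinputs = list(), dweights = NULL),
    softmax = {
      y <- output
      list(dinputs = list(y * (g - sum(g * y))), dweights = NULL)
    },
    conv2d = {
      st <- rep(as.integer(p$stride), length.out = 2L)
      ic <- im2col(x, p$kernel[1], p$kernel[2], st[1], st[2], p$padding)
      wm <- matrix(weights$kernel, nrow = prod(dim(weights$kernel)[1:3]))
      gm <- matrix(g, nrow = ic$ho * ic$wo)
      dpatch <- gm %*% t(wm)
      dx <- col2im(dpatch, p$kernel[1], p$kernel[2], st[1], st[2],
                   ic$ho, ic$wo, dim(x)[3], ic$padded_dim, ic$ph, ic$pw, dim(x))
      dw <- NULL
      if (want_dw) {
        dk <- array(t(ic$patches) %*% gm, dim = dim(weights$kernel))
        dw <- list(kernel = dk)
        if (!is.null(weights$bias)) dw$bias <- colSums(gm)
      }
      list(dinputs = list(dx), dweights = dw)
    },
    batchnorm = {
      ch <- if (is.null(dim(x))) length(x) else dim(x)[3]
      gam <- weights$gamma %||% rep(1, ch)
      sd_inv <- 1 / sqrt(weights$moving_var + p$eps)
      scale <- gam * sd_inv
      dx <- if (is.null(dim(x))) g * scale
      else array(sweep(matrix(g, ncol = ch), 2, scale, "*"), dim = dim(x))
      dw <- NULL
      if (want_dw) {
        gm <- matrix(g, ncol = ch)
        xm <- matrix(x, ncol = ch)
        xhat <- sweep(sweep(xm, 2, weights$moving_mean, "-"), 2, sd_inv, "*")
        dw <- list(beta = colSums(gm))
        if (!is.null(weights$gamma)) dw <- c(list(gamma = colSums(gm * xhat)), dw)
      }
      list(dinputs = list(dx), dweights = dw)
    },
    avgpool = {
      d <- dim(x); st <- rep(as.integer(p$stride), length.out = 2L)
      ones <- array(1, dim = c(d[1], d[2], 1L))
      ic1 <- im2col(ones, p$pool[1], p$pool[2], st[1], st[2], p$padding)
      cnt <- rowSums(ic1$patches)
      k2 <- p$pool[1] * p$pool[2]
      dx <- array(0, dim = d)
      for (ci in seq_len(d[3])) {
        gci <- matrix(g[, , ci], ncol = 1L)
        dpatch <- matrix(gci, nrow = length(gci), ncol = k2) / cnt * ic1$patches
        dx[, , ci] <- col2im(dpatch, p$pool[1], p$pool[2], st[1], st[2],
                             ic1$ho, ic1$wo, 1L, ic1$padded_dim, ic1$ph, ic1$pw,
                             c(d[1], d[2], 1L))
      }
      list(dinputs = list(dx), dweights = NULL)
    },
    global_avg_pool = {
      d <- dim(x)
      n <- d[1] * d[2]
      dx <- array(rep(g / n, each = n), dim = d)
      list(dinputs = list(dx), dweights = NULL)
    },
    dense = {
      v <- as.numeric(x)
      dv <- drop(weights$kernel %*% g)
      dx <- if (is.null(dim(x))) dv else array(dv, dim = dim(x))
      dw <- NULL
      if (want_dw) {
        dw <- list(kernel = outer(v, g))
        if (!is.null(weights$bias)) dw$bias <- g
      }
      list(dinputs = list(dx), dweights = dw)
    },
    concat = {
      chans <- vapply(inputs, function(a) dim(a)[3], numeric(1))
      stops <- cumsum(chans); starts <- c(1, utils::head(stops, -1) + 1)
      dins <- lapply(seq_along(inputs), function(i)
        g[, , starts[i]:stops[i], drop = FALSE])
      list(dinputs = dins, dweights = NULL)
    },
    stopf("no linear backward for kind '%s'", spec$kind))
}

# Max pooling backward: routes the incoming gradient to the argmax cell
# (ties broken toward the first cell in (dh, dw) order).
layer_backward_maxpool <- function(spec, x, g) {
  p <- spec$params
  d <- dim(x); st <- rep(as.integer(p$stride), length.out = 2L)
  dx <- array(0, dim = d)
  if (all(p$pool == 2L) && all(st == 2L) && d[1] %% 2L == 0L && d[2] %% 2L == 0L) {
    or <- seq(1, d[1], 2); er <- seq(2, d[1], 2)
    oc <- seq(1, d[2], 2); ec <- seq(2, d[2], 2)
    x11 <- x[or, oc, , drop = FALSE]; x21 <- x[er, oc, , drop = FALSE]
    x12 <- x[or, ec, , drop = FALSE]; x22 <- x[er, ec, , drop = FALSE]
    s11 <- x11 >= pmax(x21, x12, x22)
    s21 <- !s11 & x21 >= pmax(x12, x22)
    s12 <- !s11 & !s21 & x12 >= x22
    s22 <- !(s11 | s21 | s12)
    dx[or, oc, ] <- g * s11
    dx[er, oc, ] <- dx[er, oc, ] + g * s21
    dx[or, ec, ] <- dx[or, ec, ] + g * s12
    dx[er, ec, ] <- dx[er, ec, ] + g * s22
    return(dx)
  }
  for (ci in seq_len(d[3])) {
    ic <- im2col(x[, , ci, drop = FALSE], p$pool[1], p$pool[2],
                 st[1], st[2], p$padding, pad_value = -Inf)
    arg <- row_max_arg(ic$patches)$arg
    dpatch <- matrix(0, nrow = nrow(ic$patches), ncol = ncol(ic$patches))
    dpatch[cbind(seq_along(arg), arg)] <- as.numeric(g[, , ci])
    dx[, , ci] <- col2im(dpatch, p$pool[1], p$pool[2], st[1], st[2],
                         ic$ho, ic$wo, 1L, ic$padded_dim, ic$ph, ic$pw,
                         c(d[1], d[2], 1L))
  }
  dx
}
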