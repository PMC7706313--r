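# Low-level array kernels shared by the layer-graph engine.
#
# Conventions used throughout the package: images and feature maps are
# channels-last H x W x C double arrays (row 1 = top of the image), stored
# column-major as R arrays always are.  Vectors (GAP output, logits) are
# plain numeric vectors.

# Output length of a 1-D convolution/pooling axis.
conv_out_len <- function(n, k, stride, padding) {
  if (padding == "same") as.integer(ceiling(n / stride))
  else as.integer(floor((n - k) / stride) + 1L)
}

# TensorFlow-style "same" padding: total pad so that out = ceil(n / stride),
# split with the smaller half before.
pad_amounts <- function(n, k, stride, padding) {
  if (padding == "valid") return(c(0L, 0L))
  out <- conv_out_len(n, k, stride, "same")
  total <- max((out - 1L) * stride + k - n, 0L)
  before <- total %/% 2L
  c(before, total - before)
}

pad_hw <- function(x, ph, pw, value = 0) {
  if (all(ph == 0L) && all(pw == 0L)) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1] + sum(ph), d[2] + sum(pw), d[3]))
  out[ph[1] + seq_len(d[1]), pw[1] + seq_len(d[2]), ] <- x
  out
}

# Patch-extraction index matrix ("im2col").  Returns an (ho*wo) x (kh*kw*c)
# integer matrix of linear indices into the padded array (hp x wp x c).
# Rows enumerate output positions column-major (row index fastest), matching
# array(x, c(ho, wo, ...)); columns enumerate (dh, dw, channel) with dh
# fastest, matching matrix(kernel, kh*kw*c, filters).
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(hp, wp, c, kh, kw, sh, sw, ho, wo) {
  key <- paste(hp, wp, c, kh, kw, sh, sw, ho, wo, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  r0 <- (seq_len(ho) - 1L) * sh          # 0-based top row of each patch
  c0 <- (seq_len(wo) - 1L) * sw
  base_pos <- rep(r0 + 1L, times = wo) + rep(c0, each = ho) * hp
  off <- rep(0:(kh - 1L), times = kw * c) +
    rep(rep(0:(kw - 1L), each = kh), times = c) * hp +
    rep(0:(c - 1L), each = kh * kw) * (hp * wp)
  idx <- outer(base_pos, off, "+")
  storage.mode(idx) <- "integer"
  .im2col_cache[[key]] <- idx
  idx
}

# im2col for a single H x W x C array.  pad_value = -Inf for max pooling.
im2col <- function(x, kh, kw, sh, sw, padding, pad_value = 0) {
  d <- dim(x)
  ph <- pad_amounts(d[1], kh, sh, padding)
  pw <- pad_amounts(d[2], kw, sw, padding)
  xp <- pad_hw(x, ph, pw, value = pad_value)
  dp <- dim(xp)
  ho <- conv_out_len(d[1], kh, sh, padding)
  wo <- conv_out_len(d[2], kw, sw, padding)
  idx <- im2col_index(dp[1], dp[2], d[3], kh, kw, sh, sw, ho, wo)
  list(patches = matrix(xp[idx], nrow = ho * wo),
       idx = idx, padded_dim = dp, ph = ph, pw = pw, ho = ho, wo = wo)
}

# Scatter-add of patch gradients back to the (unpadded) input ("col2im").
# Grouped by kernel offset: each (dh, dw) pair is one strided block add over
# all channels at once.
col2im <- function(dpatches, kh, kw, sh, sw, ho, wo, cin,
                   padded_dim, ph, pw, out_dim) {
  g <- array(0, dim = padded_dim)
  ch_off <- (0:(cin - 1)) * (kh * kw)
  rows0 <- (0:(ho - 1)) * sh
  cols0 <- (0:(wo - 1)) * sw
  for (dw in 0:(kw - 1)) for (dh in 0:(kh - 1)) {
    j <- dh + 1L + dw * kh + ch_off
    ri <- rows0 + dh + 1L
    ci <- cols0 + dw + 1L
    g[ri, ci, ] <- g[ri, ci, , drop = FALSE] +
      array(dpatches[, j], dim = c(ho, wo, cin))
  }
  g[ph[1] + seq_len(out_dim[1]), pw[1] + seq_len(out_dim[2]), , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise max and argmax over a small number of columns (pool windows).
row_max_arg <- function(m) {
  a <- max.col(m, ties.method = "first")
  v <- m[cbind(seq_len(nrow(m)), a)]
  list(max = v, arg = a)
}

#' Bilinearly resize a 2-D map
#'
#' Thin wrapper around [EBImage::resize()] used to upsample coarse
#' layer-resolution attention maps to the input resolution.
#'
#' @param m numeric matrix (H x W).
#' @param h,w target height and width in pixels.
#' @return an `h x w` numeric matrix.
#' @export
resize_bilinear <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  out <- EBImage::resize(m, w = h, h = w)  # EBImage's first dim is our rows
  matrix(as.numeric(out), nrow = h, ncol = w)
}

# Min-max normalize to [0,1]; constant input maps to all zeros.
normalize01 <- function(m) {
  rng <- range(m)
  if (!is.finite(rng[1]) || !is.finite(rng[2]) || rng[2] - rng[1] < 1e-12) {
    return(array(0, dim = dim(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
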