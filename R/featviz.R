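# Visualization II: activation maximization ("feature visualization") by
# gradient ascent over a color-decorrelated Fourier image parameterization.
#
# The image is parameterized by independent real/imaginary spectral
# coefficients per color component.  Rendering is: scale the coefficients
# by 1/frequency (so the parameterization is energy-balanced across
# scales), inverse-FFT each component, mix the three components with a 3x3
# color decorrelation matrix, and squash to [0,1] with a sigmoid.  The map
# is linear up to the sigmoid, so its adjoint (used for gradient ascent) is
# an FFT followed by the transposed color mixing.

# Empirical sqrt-covariance of natural-image RGB channels, the convention
# popularized by the activation-maximization literature; columns mix the
# decorrelated components into RGB.
COLOR_DECORRELATION <- {
  m <- matrix(c(0.26, 0.09, 0.02,
                0.27, 0.00, -0.05,
                0.27, -0.09, 0.03), nrow = 3, byrow = TRUE)
  m / max(sqrt(colSums(m^2)))
}

#' Estimate a color decorrelation matrix from images
#'
#' Returns the Cholesky factor of the empirical RGB covariance of the
#' supplied images, usable as the `decorrelation` matrix of a
#' [spectral_image()] in place of the built-in natural-image default.
#'
#' @param images list of H x W x 3 arrays.
#' @return a 3 x 3 matrix (rows = RGB, columns = decorrelated components).
#' @export
estimate_decorrelation <- function(images) {
  px <- do.call(rbind, lapply(images, function(im) matrix(im, ncol = 3)))
  cv <- stats::cov(px)
  m <- t(chol(cv + diag(1e-8, 3)))
  m / max(sqrt(colSums(m^2)))
}

# Frequency magnitudes of an n x n FFT grid (cycles per pixel).
fft_freqs <- function(n) {
  f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  sqrt(outer(f^2, f^2, "+"))
}

#' Initialize a spectral image parameterization
#'
#' Coefficients are iid Gaussian noise of standard deviation `noise_sd`;
#' the frequency scaling applied at render time gives the corresponding
#' pixel image a natural 1/f energy spectrum.  `noise_sd = 0` renders as a
#' uniform mid-gray image.
#'
#' @param size square image size in pixels (>= 8).
#' @param seed integer seed.
#' @param noise_sd coefficient noise scale (default 0.1, which renders as
#'   clearly visible low-frequency noise; deep neurons of a trained network
#'   are often inactive on a flatter start, leaving no ascent gradient).
#' @param decorrelation 3 x 3 color mixing matrix (see
#'   [estimate_decorrelation()]); defaults to the natural-image triple.
#' @return a `spectral_image`: list with `coef` (size x size x 3 complex),
#'   `scale` (frequency weights), `decorrelation`, `size`.
#' @export
init_spectral <- function(size, seed = 0L, noise_sd = 0.1,
                          decorrelation = COLOR_DECORRELATION) {
  if (size < 8L) stopf("size must be >= 8")
  freqs <- fft_freqs(size)
  scale <- 1 / pmax(freqs, 1 / size)
  coef <- withr::with_seed(as.integer(seed), {
    array(complex(real = stats::rnorm(size * size * 3, 0, noise_sd),
                  imaginary = stats::rnorm(size * size * 3, 0, noise_sd)),
          dim = c(size, size, 3))
  })
  structure(list(coef = coef, scale = scale, decorrelation = decorrelation,
                 size = as.integer(size), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "spectral_image")
}

# Unitary-style inverse FFT (1/n rather than 1/n^2): keeps the pixel-space
# noise of a sd ~ 0.01 coefficient draw visible, so that even deep neurons
# receive a non-degenerate starting point for the ascent.
ifft2 <- function(z) stats::fft(z, inverse = TRUE) / sqrt(length(z))

# Pixel-space render; also returns the pre-sigmoid field for the adjoint.
render_pixel_full <- function(spectral) {
  n <- spectral$size
  comp <- vapply(1:3, function(ch)
    Re(ifft2(spectral$coef[, , ch] * spectral$scale)),
    matrix(0, n, n))
  pre <- array(0, dim = c(n, n, 3))
  m <- spectral$decorrelation
  for (rgb in 1:3)
    pre[, , rgb] <- m[rgb, 1] * comp[, , 1] + m[rgb, 2] * comp[, , 2] +
      m[rgb, 3] * comp[, , 3]
  list(image = sigmoid(pre), pre = pre, components = comp)
}

#' Render a spectral image to pixel space
#'
#' @param spectral a [init_spectral()] object.
#' @return H x W x 3 array with values in `[0, 1]`.
#' @export
render_pixel <- function(spectral) render_pixel_full(spectral)$image

# Adjoint of the render map: pixel-space gradient -> coefficient gradient.
spectral_gradient <- function(spectral, g_image, pre) {
  n <- spectral$size
  g_pre <- g_image * sigmoid(pre) * (1 - sigmoid(pre))
  m <- spectral$decorrelation
  g_coef <- array(complex(real = 0, imaginary = 0), dim = c(n, n, 3))
  for (comp in 1:3) {
    g_comp <- m[1, comp] * g_pre[, , 1] + m[2, comp] * g_pre[, , 2] +
      m[3, comp] * g_pre[, , 3]
    g_coef[, , comp] <- stats::fft(g_comp) / n * spectral$scale
  }
  g_coef
}

#' Select a neuron for feature visualization
#'
#' @param layer layer name.
#' @param channel channel index; the optimization objective is the spatial
#'   mean activation of that channel (or the single unit for vector layers).
#' @return a `neuron_selector`.
#' @export
neuron_selector <- function(layer, channel) {
  structure(list(layer = layer, channel = as.integer(channel)),
            class = "neuron_selector")
}

#' Synthesize the image that maximally activates a neuron
#'
#' Gradient ascent with Adam on the spectral coefficients of a
#' color-decorrelated Fourier parameterization, maximizing the selected
#' channel's mean activation.  No explicit regularization terms are used;
#' the parameterization itself is the only prior.
#'
#' @param graph a frozen `layer_graph`.
#' @param selector a [neuron_selector()].
#' @param steps ascent steps (default 512).
#' @param lr Adam learning rate (default 0.05).
#' @param seed seed for the noise initialization.
#' @param size render resolution; defaults to the graph's input size.
#' @param noise_sd starting noise scale; if the selected neuron is inactive
#'   on the initial render (zero gradient, common for deep neurons), the
#'   noise is doubled and the ascent restarted, up to two times.
#' @param decorrelation optional 3 x 3 color mixing matrix.
#' @return list with `image` (final render), `trace` (per-step activation
#'   values, length `steps + 1` including the initial value), `selector`.
#'   A truly constant (zero-gradient) neuron returns the initial render
#'   with a warning.
#' @export
visualize_neuron <- function(graph, selector, steps = 512L, lr = 0.05,
                             seed = 0L, size = NULL, noise_sd = 0.1,
                             decorrelation = COLOR_DECORRELATION) {
  stopifnot(inherits(selector, "neuron_selector"))
  in_shape <- graph$shapes[[graph$input]]
  if (is.null(size)) size <- in_shape[1]
  if (size != in_shape[1] || in_shape[1] != in_shape[2])
    stopf("render size must match the graph's square input (%d px)", in_shape[1])
  shp <- graph$shapes[[selector$layer]]
  if (is.null(shp)) stopf("unknown layer '%s'", selector$layer)
  n_ch <- shp[length(shp)]
  if (selector$channel < 1 || selector$channel > n_ch)
    stopf("channel %d out of range for layer '%s' (%d channels)",
          selector$channel, selector$layer, n_ch)
  target <- target_neuron_mean(selector$layer, selector$channel)
  act_of <- function(state) {
    a <- state[[selector$layer]]
    if (is.null(dim(a))) a[selector$channel] else mean(a[, , selector$channel])
  }
  ascend <- function(noise_sd) {
    spectral <- init_spectral(size, seed = seed, noise_sd = noise_sd,
                              decorrelation = decorrelation)
    opt <- new.env(parent = emptyenv()); opt$state <- list()
    trace <- numeric(steps + 1L)
    init_render <- NULL
    for (step in 0:steps) {
      rp <- render_pixel_full(spectral)
      if (step == 0L) init_render <- rp$image
      fw <- forward(graph, rp$image)
      trace[step + 1L] <- act_of(fw$state)
      if (step == steps) break
      bw <- backward(graph, fw$state, target, rule = "vanilla")
      g <- spectral_gradient(spectral, bw$input, rp$pre)
      if (step == 0L && max(Mod(g)) == 0) {
        return(list(dead = TRUE, init_render = init_render, trace = trace[1L]))
      }
      gre <- Re(g); gim <- Im(g)
      upr <- adam_step(opt, "re", -gre, lr)  # ascent: step against -gradient
      upi <- adam_step(opt, "im", -gim, lr)
      spectral$coef <- spectral$coef - complex(real = upr, imaginary = upi)
      dim(spectral$coef) <- c(size, size, 3)
    }
    list(dead = FALSE, image = render_pixel(spectral), trace = trace,
         spectral = spectral)
  }
  res <- NULL
  for (attempt in 0:2) {
    res <- ascend(noise_sd * 2^attempt)
    if (!res$dead) break
  }
  if (res$dead) {
    warning(sprintf("zero gradient for %s/%d: neuron is constant; returning the initial render",
                    selector$layer, selector$channel))
    return(list(image = res$init_render, trace = res$trace,
                selector = selector))
  }
  list(image = res$image, trace = res$trace, selector = selector,
       spectral = res$spectral)
}
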