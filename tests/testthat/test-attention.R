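# Attention maps: closed-form oracles on linear scorers, propagation-rule
# reductions, reference-based properties and cost contracts.

lin_w <- function(seed = 3, h = 8) {
  withr::with_seed(seed, array(stats::rnorm(h * h * 3), c(h, h, 3)))
}

test_that("occlusion drops match the closed form for a linear scorer", {
  w <- lin_w(); g <- linear_scorer(w)
  x <- random_image(1)
  mv <- 0.25
  om <- occlusion_map(g, x, 1, mask_size = 4, stride = 4, mask_value = mv)
  for (r in c(1, 5)) for (cc in c(1, 5)) {
    want <- sum(w[r:(r + 3), cc:(cc + 3), ] * (x[r:(r + 3), cc:(cc + 3), ] - mv))
    expect_equal(om$raw[r, cc], want, tolerance = 1e-10)
  }
})

test_that("occlusion over a zero-weight region drops nothing", {
  w <- lin_w(); w[1:4, 1:4, ] <- 0
  g <- linear_scorer(w)
  om <- occlusion_map(g, random_image(2), 1, mask_size = 4, stride = 4,
                      mask_value = 0)
  expect_equal(om$raw[1:4, 1:4], matrix(0, 4, 4), tolerance = 1e-12)
})

test_that("constant models produce all-zero normalized maps", {
  g <- linear_scorer(array(0, c(8, 8, 3)))
  x <- random_image(3)
  expect_equal(occlusion_map(g, x, 1, mask_size = 4, stride = 4)$values,
               matrix(0, 8, 8))
  expect_equal(vanilla_saliency(g, x, 1)$values, matrix(0, 8, 8))
  seg <- matrix(rep(1:2, each = 32), 8, 8)
  sm <- superpixel_surrogate_map(g, x, 1, segments = seg, n_samples = 4)
  expect_equal(attr(sm, "weights"), c(0, 0), tolerance = 1e-10)
})

test_that("an exhaustive superpixel design recovers exact region scores", {
  w <- lin_w(); g <- linear_scorer(w)
  x <- random_image(4)
  seg <- matrix(1, 8, 8); seg[, 5:8] <- 2
  sm <- superpixel_surrogate_map(g, x, 1, segments = seg, n_samples = 4,
                                 replacement = 0)
  wts <- attr(sm, "weights")
  expect_equal(wts[1], sum(w[, 1:4, ] * x[, 1:4, ]), tolerance = 1e-10)
  expect_equal(wts[2], sum(w[, 5:8, ] * x[, 5:8, ]), tolerance = 1e-10)
  # a model reading only region 1 gives region 2 weight ~ 0
  w2 <- w; w2[, 5:8, ] <- 0
  sm2 <- superpixel_surrogate_map(linear_scorer(w2), x, 1, segments = seg,
                                  n_samples = 4, replacement = 0)
  expect_lt(abs(attr(sm2, "weights")[2]), 1e-6)
  expect_gt(abs(attr(sm2, "weights")[1]), 1e-3)
})

test_that("slic-style segmentation produces the requested label range", {
  x <- fixture_splits()$test[[1]]$image
  seg <- slic_segments(x, 9, seed = 1)
  expect_equal(dim(seg), dim(x)[1:2])
  expect_true(all(seg %in% 1:9))
  expect_identical(seg, slic_segments(x, 9, seed = 1))
})

test_that("vanilla saliency is the channel-max absolute gradient", {
  w <- lin_w(); g <- linear_scorer(w)
  vs <- vanilla_saliency(g, random_image(5), 1)
  expect_equal(vs$raw, apply(abs(w), c(1, 2), max), tolerance = 1e-12)
  expect_equal(vs$raw_signed, w, tolerance = 1e-12)
})

test_that("integrated gradients are exact for linear models and zero at baseline", {
  w <- lin_w(); g <- linear_scorer(w)
  x <- random_image(6)
  ig <- integrated_gradients_map(g, x, 1, steps = 3)
  expect_equal(ig$raw_signed, w * x, tolerance = 1e-10)
  ig0 <- integrated_gradients_map(g, x, 1, steps = 3, baseline = x)
  expect_equal(ig0$raw_signed, array(0, dim(x)))
})

test_that("integrated gradients satisfy completeness on the fixture", {
  m <- fixture_model()
  x <- fixture_diseased(1)[[1]]$image
  F1 <- forward(m, x, keep_state = FALSE)$logits[2]
  F0 <- forward(m, array(0, dim(x)), keep_state = FALSE)$logits[2]
  ig <- integrated_gradients_map(m, x, 2, steps = 128)
  expect_lt(abs(sum(ig$raw_signed) - (F1 - F0)), 0.01 * abs(F1 - F0))
})

test_that("completeness error shrinks as interpolation steps double", {
  m <- fixture_model()
  imgs <- lapply(fixture_diseased(3), `[[`, "image")
  errs <- sapply(c(8, 16, 32, 64), function(st) {
    mean(sapply(imgs, function(x) {
      F1 <- forward(m, x, keep_state = FALSE)$logits[2]
      F0 <- forward(m, array(0, dim(x)), keep_state = FALSE)$logits[2]
      ig <- integrated_gradients_map(m, x, 2, steps = st)
      abs(sum(ig$raw_signed) - (F1 - F0))
    }))
  })
  expect_lt(errs[4], errs[1])            # clear overall decrease
  expect_true(all(errs[-1] <= errs[-4] * 2))  # no step explodes (noise band)
})

test_that("grad-CAM at the last feature layer reduces to class activation mapping", {
  m <- fixture_model()
  gl <- m$specs[["GAP"]]$parents[1]
  x <- fixture_diseased(2)[[2]]$image
  gm <- grad_cam_map(m, x, 3, gl)
  A <- forward(m, x, capture = gl, keep_state = FALSE)$captured[[gl]]
  W <- m$weights$output$kernel
  cam <- pmax(matrix(matrix(A, ncol = dim(A)[3]) %*% W[, 3],
                     dim(A)[1], dim(A)[2]), 0)
  got <- attr(gm, "cam")
  cosine <- sum(got * cam) / sqrt(sum(got^2) * sum(cam^2))
  expect_gt(cosine, 0.999)
})

test_that("grad-CAM handles degenerate heads and rejects vector layers", {
  m <- fixture_model()
  x <- fixture_diseased(1)[[1]]$image
  expect_error(grad_cam_map(m, x, 1, "GAP"), "spatial")
  # class with all-zero head weights -> zero map
  m0 <- m; m0$weights$output$kernel[, 4] <- 0; m0$weights$output$bias[4] <- 0
  gm <- grad_cam_map(m0, x, 4, "Conv2")
  expect_equal(gm$values, matrix(0, 64, 64))
})

test_that("deeplift contributions are exact for linear scorers and zero at the reference", {
  w <- lin_w(); g <- linear_scorer(w)
  x <- random_image(7); ref <- random_image(8)
  dm <- deeplift_map(g, x, 1, ref)
  expect_equal(dm$raw_signed, w * (x - ref), tolerance = 1e-12)
  dm0 <- deeplift_map(g, x, 1, x)
  expect_equal(dm0$values, matrix(0, 8, 8))
  expect_error(deeplift_map(g, x, 1, random_image(1, h = 4)), "shape")
})

test_that("deeplift satisfies summation-to-delta on affine+relu graphs", {
  g <- build_graph(list(
    layer_spec("in", "input", shape = c(8, 8, 3)),
    layer_spec("c1", "conv2d", parents = "in", filters = 4, kernel = 3,
               padding = "same", use_bias = FALSE),
    layer_spec("b1", "batchnorm", parents = "c1"),
    layer_spec("r1", "relu", parents = "b1"),
    layer_spec("c2", "conv2d", parents = "r1", filters = 3, kernel = 3,
               stride = 2, padding = "valid"),
    layer_spec("r2", "relu", parents = "c2"),
    layer_spec("gap", "global_avg_pool", parents = "r2"),
    layer_spec("d", "dense", parents = "gap", units = 2)), seed = 9)
  for (seed in c(1, 5)) {
    x <- random_image(seed); ref <- random_image(seed + 50)
    dm <- deeplift_map(g, x, 1, ref)
    delta <- forward(g, x, keep_state = FALSE)$logits[1] -
      forward(g, ref, keep_state = FALSE)$logits[1]
    expect_lt(abs(sum(dm$raw_signed) - delta), 1e-4)
  }
})

test_that("explanation maps floor at the reference thresholds", {
  m <- fixture_model()
  refs <- fixture_healthy_refs()
  thr <- activation_thresholds(m, refs, "Conv2")
  expect_length(thr$thresholds, 16)
  # inputs whose activations cannot exceed the thresholds -> zero map
  dark <- array(0, c(64, 64, 3))
  a <- forward(m, dark, capture = "Conv2", keep_state = FALSE)$captured$Conv2
  if (all(sweep(matrix(a, ncol = 16), 2, thr$thresholds, "-") <= 0)) {
    em <- explanation_map(m, dark, thr)
    expect_equal(em$values, matrix(0, 64, 64))
  }
  expect_error(activation_thresholds(m, list(), "Conv2"), "empty")
  expect_error(explanation_map(m, dark, thr, layer = "Conv1"), "Conv2")
  expect_error(explanation_map(m, dark, thr, top_k = 99), "channel count")
})

test_that("top_k = 1 on a single channel reproduces that channel's excess", {
  g <- build_graph(list(
    layer_spec("in", "input", shape = c(8, 8, 1)),
    layer_spec("r", "relu", parents = "in")), init = "zeros")
  ref <- array(0.2, c(8, 8, 1))
  thr <- activation_thresholds(g, list(ref), "r")
  expect_equal(thr$thresholds, 0.2)
  x <- random_image(3, h = 8, c = 1)
  em <- explanation_map(g, x, thr, top_k = 1)
  expect_equal(em$raw, pmax(pmax(x[, , 1], 0) - 0.2, 0), tolerance = 1e-12)
})

test_that("cost contracts hold: forwards for perturbation, no backwards for explanation", {
  w <- lin_w(); g <- linear_scorer(w)
  x <- random_image(9)
  viz_counters_reset()
  occlusion_map(g, x, 1, mask_size = 4, stride = 4)
  expect_equal(unname(viz_counters()["forward"]), 1L + 4L)  # base + 2x2 grid
  expect_equal(unname(viz_counters()["backward"]), 0L)

  seg <- matrix(rep(1:2, each = 32), 8, 8)
  viz_counters_reset()
  superpixel_surrogate_map(g, x, 1, segments = seg, n_samples = 4)
  expect_equal(unname(viz_counters()["forward"]), 4L)       # exhaustive design
  expect_equal(unname(viz_counters()["backward"]), 0L)

  m <- fixture_model()
  refs <- fixture_healthy_refs()[1:2]
  thr <- activation_thresholds(m, refs, "Conv2")
  viz_counters_reset()
  explanation_map(m, fixture_diseased(1)[[1]]$image, thr)
  expect_equal(unname(viz_counters()["backward"]), 0L)
  expect_equal(unname(viz_counters()["forward"]), 1L)

  viz_counters_reset()
  vanilla_saliency(m, fixture_diseased(1)[[1]]$image, 2)
  expect_equal(unname(viz_counters()["backward"]), 1L)
})

test_that("layer_scan reproduces direct calls and native resolutions shrink with depth", {
  m <- fixture_model()
  s <- fixture_diseased(3)[[3]]
  sc <- layer_scan(m, s$image, "grad_cam", c("Conv1", "Conv2", "Conv3"),
                   class = s$label, mask = s$mask)
  direct <- grad_cam_map(m, s$image, s$label, "Conv2")
  expect_equal(sc$maps$Conv2$values, direct$values)
  expect_true(all(diff(sc$summary$h) <= 0))
  expect_true(all(c("sensitivity", "iou") %in% names(sc$summary)))
  one <- layer_scan(m, s$image, "grad_cam", "Conv2", class = s$label)
  expect_equal(one$maps$Conv2$values, direct$values)
})

test_that("normalized map values stay in [0,1] with raw values retained", {
  m <- fixture_model()
  s <- fixture_diseased(2)[[1]]
  maps <- list(
    grad_cam_map(m, s$image, s$label, "Conv2"),
    vanilla_saliency(m, s$image, s$label),
    integrated_gradients_map(m, s$image, s$label, steps = 8))
  for (mp in maps) {
    expect_true(all(mp$values >= 0 & mp$values <= 1))
    expect_false(is.null(mp$raw))
    expect_equal(dim(mp$values), c(64L, 64L))
  }
})
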