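# Graph construction, validation, forward contracts and serialization.

test_that("zeros init allocates correctly shaped zero weights", {
  g <- build_graph(list(
    layer_spec("in", "input", shape = c(1, 1, 4)),
    layer_spec("gap", "global_avg_pool", parents = "in"),
    layer_spec("d", "dense", parents = "gap", units = 2)), init = "zeros")
  expect_equal(g$weights$d$kernel, array(0, c(4, 2)))
  expect_equal(g$weights$d$bias, numeric(2))
})

test_that("random init is seed-deterministic", {
  specs <- list(
    layer_spec("in", "input", shape = c(4, 4, 2)),
    layer_spec("c", "conv2d", parents = "in", filters = 3, kernel = 3),
    layer_spec("gap", "global_avg_pool", parents = "c"),
    layer_spec("d", "dense", parents = "gap", units = 2))
  g1 <- build_graph(specs, seed = 42)
  g2 <- build_graph(specs, seed = 42)
  g3 <- build_graph(specs, seed = 43)
  expect_identical(g1$weights, g2$weights)
  expect_false(identical(g1$weights, g3$weights))
})

test_that("invalid graphs are rejected with informative errors", {
  expect_error(build_graph(list(
    layer_spec("a", "relu", parents = "b"),
    layer_spec("b", "relu", parents = "a"))), "cycle|input")
  expect_error(build_graph(list(
    layer_spec("in", "input", shape = c(4, 4, 1)),
    layer_spec("x", "relu", parents = "in"),
    layer_spec("x", "relu", parents = "in"))), "duplicate")
  # concat parents with unequal spatial size
  expect_error(build_graph(list(
    layer_spec("in", "input", shape = c(4, 4, 1)),
    layer_spec("p", "maxpool", parents = "in", pool = 2, stride = 2),
    layer_spec("cat", "concat", parents = c("in", "p")))),
    "spatial")
  # conv bias directly under batchnorm violates the inception convention
  expect_error(build_graph(list(
    layer_spec("in", "input", shape = c(4, 4, 1)),
    layer_spec("c", "conv2d", parents = "in", filters = 2, kernel = 3,
               use_bias = TRUE),
    layer_spec("bn", "batchnorm", parents = "c"))), "bias")
  expect_error(build_graph(list(
    layer_spec("in", "input", shape = c(4, 4, 1)),
    layer_spec("in2", "input", shape = c(4, 4, 1)))), "exactly one input")
})

test_that("softmax outputs form a probability simplex on random graphs", {
  for (seed in 1:3) {
    g <- small_random_graph(seed)
    x <- random_image(seed + 10)
    p <- forward(g, x, keep_state = FALSE)$probs
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("forward validates input shape and capture names", {
  g <- small_random_graph(1)
  expect_error(forward(g, array(0, c(4, 4, 2))), "shape")
  expect_error(forward(g, random_image(1), capture = "nope"), "unknown capture")
})

test_that("batch forward stacks per-image probabilities", {
  g <- small_random_graph(2)
  imgs <- list(random_image(1), random_image(2))
  fw <- forward(g, imgs)
  expect_equal(dim(fw$probs), c(2L, 3L))
  expect_equal(fw$probs[2, ], forward(g, imgs[[2]], keep_state = FALSE)$probs)
})

test_that("save_model / load_model round-trips weights and predictions", {
  g <- small_random_graph(5)
  path <- file.path(withr::local_tempdir(), "model")
  save_model(g, path)
  g2 <- load_model(path)
  expect_identical(g$weights, g2$weights)
  x <- random_image(9)
  expect_equal(forward(g2, x, keep_state = FALSE)$probs,
               forward(g, x, keep_state = FALSE)$probs)
})

test_that("parameter report separates trainable and non-trainable counts", {
  g <- build_graph(list(
    layer_spec("in", "input", shape = c(4, 4, 3)),
    layer_spec("c", "conv2d", parents = "in", filters = 32, kernel = 3,
               use_bias = FALSE),
    layer_spec("bn", "batchnorm", parents = "c"),
    layer_spec("gap", "global_avg_pool", parents = "bn"),
    layer_spec("d", "dense", parents = "gap", units = 38)), init = "zeros")
  rep_ <- count_parameters(g)
  df <- rep_$report
  expect_equal(df$trainable[df$layer == "c"], 3 * 3 * 3 * 32)  # 864
  expect_equal(df$trainable[df$layer == "bn"], 2 * 32)          # gamma + beta
  expect_equal(df$non_trainable[df$layer == "bn"], 2 * 32)      # moving stats
  expect_equal(df$trainable[df$layer == "d"], 32 * 38 + 38)
  expect_equal(rep_$total, sum(df$trainable) + sum(df$non_trainable))
})
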