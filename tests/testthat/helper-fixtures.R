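# Shared fixtures, built lazily once per test session.

.fx <- new.env(parent = emptyenv())

# Default 4-class leaf task, 40 images per class (24/8/8 per class).
fixture_splits <- function() {
  if (is.null(.fx$splits))
    .fx$splits <- make_dataset(default_class_specs(), n_per_class = 40,
                               seed = 101)
  .fx$splits
}

# Trained tiny-CNN classifier on the default task.
fixture_model <- function() {
  if (is.null(.fx$model))
    .fx$model <- suppressWarnings(make_fixture_model(fixture_splits()))
  .fx$model
}

fixture_diseased <- function(n = 20) {
  Filter(function(s) s$label != 1, fixture_splits()$test)[seq_len(n)]
}

fixture_healthy_refs <- function() {
  lapply(Filter(function(s) s$label == 1, fixture_splits()$train), `[[`, "image")
}

# A graph computing a plain linear score y_j = sum_i W_ij x_i on an
# H x H x 3 image (no softmax, no hidden layers): the closed-form oracle
# for perturbation and gradient methods.
linear_scorer <- function(w, n_classes = 2) {
  d <- dim(w)
  g <- build_graph(list(
    layer_spec("in", "input", shape = d),
    layer_spec("score", "dense", parents = "in", units = n_classes)),
    init = "zeros")
  g$weights$score$kernel[, 1] <- as.numeric(w)
  g
}

# Small random conv net for finite-difference and property tests.
small_random_graph <- function(seed = 1, h = 8, cin = 3) {
  build_graph(list(
    layer_spec("in", "input", shape = c(h, h, cin)),
    layer_spec("c1", "conv2d", parents = "in", filters = 3, kernel = 3,
               padding = "same"),
    layer_spec("r1", "relu", parents = "c1"),
    layer_spec("p1", "maxpool", parents = "r1", pool = 2, stride = 2),
    layer_spec("c2", "conv2d", parents = "p1", filters = 4, kernel = 3,
               padding = "valid"),
    layer_spec("r2", "relu", parents = "c2"),
    layer_spec("gap", "global_avg_pool", parents = "r2"),
    layer_spec("d", "dense", parents = "gap", units = 3),
    layer_spec("sm", "softmax", parents = "d")), seed = seed)
}

# Central finite-difference gradient of a class logit w.r.t. the input.
fd_gradient <- function(graph, x, class, eps = 1e-5) {
  fd <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd[i] <- (forward(graph, xp, keep_state = FALSE)$logits[class] -
                forward(graph, xm, keep_state = FALSE)$logits[class]) / (2 * eps)
  }
  fd
}

random_image <- function(seed, h = 8, c = 3) {
  withr::with_seed(seed, array(stats::runif(h * h * c), c(h, h, c)))
}
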