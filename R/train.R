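# Minimal Adam training loop over a layer graph with categorical
# cross-entropy loss and lowest-validation-loss model selection.

#' Training configuration
#'
#' Defaults follow common practice for this class of models: Adam with a
#' learning rate of 0.05, batches of 128 images, categorical cross-entropy,
#' and selection of the epoch with the lowest validation loss.  The 0.05
#' learning rate is unusually high for full-network training and works best
#' with small fixture networks; it is a plain default, override freely.
#'
#' @param optimizer only `"adam"` is implemented (bias-corrected moments,
#'   beta1 = 0.9, beta2 = 0.999, eps = 1e-7).
#' @param lr learning rate (> 0).
#' @param batch_size images per gradient step (>= 1).
#' @param epochs number of passes over the training split.
#' @param seed integer seed controlling shuffling (and any weight init done
#'   by the caller).
#' @param bn_momentum EMA momentum for batchnorm moving statistics.
#' @param lr_decay multiplicative step decay applied to the learning rate
#'   every `lr_decay_every` epochs (1 = constant).
#' @param lr_decay_every epochs between decay steps.
#' @return a `train_config` list.
#' @export
train_config <- function(optimizer = "adam", lr = 0.05, batch_size = 128L,
                         epochs = 10L, seed = 0L, bn_momentum = 0.99,
                         lr_decay = 1, lr_decay_every = 15L) {
  stopifnot(lr > 0, batch_size >= 1, lr_decay > 0, lr_decay <= 1)
  structure(list(optimizer = match.arg(optimizer), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 bn_momentum = bn_momentum, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every)),
            class = "train_config")
}

onehot <- function(label, k) {
  y <- numeric(k); y[label] <- 1; y
}

#' Evaluate a graph on a list of labelled samples
#'
#' @param graph a `layer_graph` ending in a softmax layer.
#' @param samples list of samples, each with `$image` and `$label` (1-based).
#' @return list with `loss` (mean categorical cross-entropy), `accuracy`,
#'   and `pred` (vector of argmax labels).
#' @export
evaluate <- function(graph, samples) {
  k <- graph$shapes[[logit_layer(graph)]][1]
  losses <- numeric(length(samples))
  pred <- integer(length(samples))
  for (i in seq_along(samples)) {
    fw <- forward(graph, samples[[i]]$image, keep_state = FALSE)
    p <- pmax(fw$probs, 1e-12)
    losses[i] <- -log(p[samples[[i]]$label])
    pred[i] <- which.max(fw$probs)
  }
  labs <- vapply(samples, function(s) as.integer(s$label), integer(1))
  list(loss = mean(losses), accuracy = mean(pred == labs), pred = pred)
}

adam_step <- function(opt, key, grad, lr) {
  st <- opt$state[[key]]
  if (is.null(st)) st <- list(m = grad * 0, v = grad * 0, t = 0L)
  st$t <- st$t + 1L
  st$m <- 0.9 * st$m + 0.1 * grad
  st$v <- 0.999 * st$v + 0.001 * grad^2
  mhat <- st$m / (1 - 0.9^st$t)
  vhat <- st$v / (1 - 0.999^st$t)
  opt$state[[key]] <- st
  lr * mhat / (sqrt(vhat) + 1e-7)
}

#' Train a layer graph
#'
#' Stochastic minibatch training with Adam and categorical cross-entropy.
#' Batchnorm layers train in frozen-statistics mode: the affine transform's
#' learnable shift/scale receive gradients through the inference-mode
#' forward pass while the moving statistics are updated as an exponential
#' moving average of per-batch input statistics.  The returned graph carries
#' the weight snapshot of the epoch with the lowest validation loss.
#'
#' @param graph a `layer_graph` ending in a softmax layer.
#' @param splits a [make_dataset()] result or any list with `train`,
#'   `validation` (lists of samples holding `$image`, `$label`).
#' @param config a [train_config()].
#' @param freeze character vector of layer names whose weights stay fixed.
#' @return the trained `layer_graph`, with the per-epoch history tibble
#'   (`epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`) attached as
#'   attribute `"history"` and retrievable via [training_history()].
#' @export
train <- function(graph, splits, config = train_config(), freeze = NULL) {
  if (!length(splits$train)) stopf("empty training split")
  if (!length(splits$validation)) stopf("empty validation split")
  unknown <- setdiff(freeze, names(graph$specs))
  if (length(unknown)) stopf("cannot freeze unknown layer '%s'", unknown[1])
  ll <- logit_layer(graph)
  k <- graph$shapes[[ll]][1]
  trainable <- stats::setNames(
    vapply(graph$order, function(nm)
      !is.null(graph$weights[[nm]]) && !(nm %in% freeze), logical(1)),
    graph$order)
  bn_layers <- names(graph$specs)[vapply(graph$specs, function(s)
    s$kind == "batchnorm", logical(1))]
  bn_layers <- bn_layers[vapply(bn_layers, function(nm) trainable[[nm]], logical(1))]
  opt <- new.env(parent = emptyenv()); opt$state <- list()
  history <- vector("list", config$epochs)
  best <- list(loss = Inf, weights = graph$weights)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr_epoch <- config$lr *
        config$lr_decay^((epoch - 1L) %/% config$lr_decay_every)
      idx <- sample(seq_along(splits$train))
      ep_loss <- 0; ep_hit <- 0
      for (b0 in seq(1, length(idx), by = config$batch_size)) {
        bidx <- idx[b0:min(b0 + config$batch_size - 1L, length(idx))]
        acc_w <- list()
        bn_stats <- list()
        for (i in bidx) {
          smp <- splits$train[[i]]
          fw <- forward(graph, smp$image)
          p <- fw$probs
          ep_loss <- ep_loss - log(max(p[smp$label], 1e-12))
          ep_hit <- ep_hit + (which.max(p) == smp$label)
          dlogit <- p - onehot(smp$label, k)   # softmax + CE combined
          pr <- propagate(graph, fw$state, ll, dlogit, "vanilla",
                          trainable = trainable, input_grad = FALSE)
          for (nm in names(pr$wgrads)) for (par in names(pr$wgrads[[nm]])) {
            cur <- acc_w[[nm]][[par]]
            acc_w[[nm]][[par]] <- if (is.null(cur)) pr$wgrads[[nm]][[par]]
              else cur + pr$wgrads[[nm]][[par]]
          }
          for (nm in bn_layers) {
            xin <- fw$state[[graph$specs[[nm]]$parents[1]]]
            ch <- if (is.null(dim(xin))) length(xin) else dim(xin)[3]
            xm <- matrix(xin, ncol = ch)
            st <- bn_stats[[nm]]
            if (is.null(st)) st <- list(s = 0, s2 = 0, n = 0)
            st$s <- st$s + colSums(xm); st$s2 <- st$s2 + colSums(xm^2)
            st$n <- st$n + nrow(xm)
            bn_stats[[nm]] <- st
          }
        }
        nb <- length(bidx)
        if (!is.nan(ep_loss) && !is.finite(ep_loss))
          stopf("training diverged (non-finite loss) in epoch %d", epoch)
        for (nm in names(acc_w)) for (par in names(acc_w[[nm]])) {
          g <- acc_w[[nm]][[par]] / nb
          if (any(!is.finite(g)))
            stopf("training diverged (non-finite gradient at '%s') in epoch %d",
                  nm, epoch)
          graph$weights[[nm]][[par]] <- graph$weights[[nm]][[par]] -
            adam_step(opt, paste(nm, par, sep = "/"), g, lr_epoch)
        }
        mom <- config$bn_momentum
        for (nm in names(bn_stats)) {
          st <- bn_stats[[nm]]
          mu <- st$s / st$n
          va <- pmax(st$s2 / st$n - mu^2, 0)
          graph$weights[[nm]]$moving_mean <-
            mom * graph$weights[[nm]]$moving_mean + (1 - mom) * mu
          graph$weights[[nm]]$moving_var <-
            mom * graph$weights[[nm]]$moving_var + (1 - mom) * va
        }
      }
      val <- evaluate(graph, splits$validation)
      if (!is.finite(val$loss))
        stopf("training diverged (non-finite validation loss) in epoch %d", epoch)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = ep_loss / length(idx),
        train_acc = ep_hit / length(idx),
        val_loss = val$loss, val_acc = val$accuracy)
      if (val$loss < best$loss)
        best <- list(loss = val$loss, weights = graph$weights)
    }
  })
  graph$weights <- best$weights
  attr(graph, "history") <- do.call(rbind, history)
  graph
}

#' @rdname train
#' @param trained a graph returned by [train()].
#' @export
training_history <- function(trained) attr(trained, "history")
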