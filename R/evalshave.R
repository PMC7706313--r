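# Quantitative evaluation: attention-map vs lesion-mask overlap metrics,
# misclassification inspection, and the layer-shaving experiment series.

#' Overlap metrics between an attention map and a lesion mask
#'
#' * `sensitivity`: fraction of total heat mass lying on lesion pixels.
#' * `specificity`: 1 minus the mean heat on non-lesion pixels (heat is in
#'   `[0, 1]`, so this is area-normalized off-lesion attention).
#' * `iou`: intersection-over-union of the map thresholded at `tau` with
#'   the mask.
#' * `pointing_hit`: whether the map's maximum falls inside the mask.
#'
#' @param map an `attention_map` (or a plain matrix in `[0, 1]`).
#' @param mask binary matrix of the same dimensions.
#' @param tau binarization threshold for the IoU (default 0.5).
#' @return one-row tibble `sensitivity`, `specificity`, `iou`,
#'   `pointing_hit`.  An empty mask yields `NA` sensitivity/IoU/pointing.
#' @export
overlap_metrics <- function(map, mask, tau = 0.5) {
  v <- if (inherits(map, "attention_map")) map$values else map
  if (!identical(dim(v), dim(mask))) stopf("map and mask shapes differ")
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary")
  m <- mask > 0
  if (!any(m)) {
    return(tibble::tibble(sensitivity = NA_real_,
                          specificity = 1 - mean(v),
                          iou = NA_real_, pointing_hit = NA))
  }
  total <- sum(v)
  sens <- if (total > 0) sum(v[m]) / total else NA_real_
  spec <- 1 - (if (any(!m)) mean(v[!m]) else 0)
  bin <- v >= tau
  iou <- sum(bin & m) / sum(bin | m)
  arg <- which.max(v)
  tibble::tibble(sensitivity = sens, specificity = spec, iou = iou,
                 pointing_hit = m[arg])
}

# Fraction of a map's heat mass outside a (leaf) region.
background_fraction <- function(map, region) {
  v <- if (inherits(map, "attention_map")) map$values else map
  total <- sum(v)
  if (total == 0) return(0)
  sum(v[region == 0]) / total
}

#' Inspect misclassified images with attention maps
#'
#' For every misclassified sample of a split: the true label, the top
#' predicted labels with their probabilities, one attention map per
#' requested method, and the fraction of each map's heat mass falling
#' outside the leaf region (high background attention on errors is the
#' typical signature of a dataset/background confound).
#'
#' @param graph a trained `layer_graph`.
#' @param samples list of `synthetic_sample`s (or any samples with
#'   `$image`, `$label` and optionally `$leaf`).
#' @param methods character subset of `c("grad_cam", "guided_backprop")`.
#' @param top_m number of top predictions to report (default 3).
#' @param gradcam_layer target layer for Grad-CAM (default: the layer
#'   feeding the GAP).
#' @return a `misclassification_report`: list with `table` (tibble: sample
#'   id, true label, `pred1..predm`, `prob1..probm`, one
#'   `bg_fraction_<method>` column per method) and `maps` (per-sample list
#'   of attention maps).  Empty when nothing is misclassified.
#' @export
misclassification_report <- function(graph, samples,
                                     methods = c("grad_cam", "guided_backprop"),
                                     top_m = 3L, gradcam_layer = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(gradcam_layer) && "grad_cam" %in% methods)
    gradcam_layer <- graph$specs[[gap_layer(graph)]]$parents[1]
  rows <- list(); all_maps <- list()
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    fw <- forward(graph, smp$image, keep_state = FALSE)
    pred <- which.max(fw$probs)
    if (pred == smp$label) next
    ord <- order(fw$probs, decreasing = TRUE)[seq_len(min(top_m, length(fw$probs)))]
    row <- list(sample = i, true_label = smp$label)
    for (j in seq_along(ord)) {
      row[[paste0("pred", j)]] <- ord[j]
      row[[paste0("prob", j)]] <- fw$probs[ord[j]]
    }
    maps <- list()
    for (met in methods) {
      m <- switch(met,
        grad_cam = grad_cam_map(graph, smp$image, pred, gradcam_layer),
        guided_backprop = guided_backprop_map(graph, smp$image, pred))
      maps[[met]] <- m
      row[[paste0("bg_fraction_", met)]] <-
        if (!is.null(smp$leaf)) background_fraction(m, smp$leaf) else NA_real_
    }
    rows[[length(rows) + 1L]] <- tibble::as_tibble(row)
    all_maps[[length(all_maps) + 1L]] <- maps
  }
  structure(list(table = if (length(rows)) do.call(rbind, rows)
                 else tibble::tibble(),
                 maps = all_maps, methods = methods),
            class = "misclassification_report")
}

#' @export
print.misclassification_report <- function(x, ...) {
  cat(sprintf("<misclassification_report> %d misclassified samples\n",
              nrow(x$table)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Layer-shaving experiment series
#'
#' For each cut layer (ordered shallow to deep): truncate the trained graph
#' there ([truncate_at()]), transfer-learn the fresh GAP + dense head (the
#' copied feature layers stay frozen by default; set `fine_tune = TRUE` to
#' update everything), evaluate on the test split and count parameters.
#' A reference row for the uncut source model is appended.
#'
#' @param graph a trained `layer_graph`.
#' @param cut_layers character vector of feature layer names, shallow to
#'   deep.
#' @param splits dataset splits used for transfer learning and testing.
#' @param config a [train_config()] for the transfer phase.
#' @param fine_tune update the copied feature weights too (default FALSE).
#' @param head_init_seed seed for each new head.
#' @return a `shave_report`: tibble with columns `cut_layer`, `params`,
#'   `test_acc`, `test_loss`, `epochs`; attribute `"models"` holds the
#'   retrained graphs.
#' @export
shave_series <- function(graph, cut_layers, splits,
                         config = train_config(lr = 0.02, batch_size = 8,
                                               epochs = 15, seed = 0L,
                                               lr_decay = 0.5,
                                               lr_decay_every = 8L),
                         fine_tune = FALSE, head_init_seed = 0L) {
  n_classes <- graph$shapes[[logit_layer(graph)]][1]
  rows <- list(); models <- list()
  for (cl in cut_layers) {
    cut <- truncate_at(graph, cl, n_classes, head_init_seed = head_init_seed)
    cut <- zero_head(cut)
    freeze <- if (fine_tune) NULL else setdiff(names(cut$weights), "output")
    trained <- train(cut, splits, config, freeze = freeze)
    ev <- evaluate(trained, splits$test)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cut_layer = cl, params = count_parameters(trained)$total,
      test_acc = ev$accuracy, test_loss = ev$loss, epochs = config$epochs)
    models[[cl]] <- trained
  }
  ev_full <- evaluate(graph, splits$test)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    cut_layer = "(full model)", params = count_parameters(graph)$total,
    test_acc = ev_full$accuracy, test_loss = ev_full$loss, epochs = 0L)
  report <- do.call(rbind, rows)
  structure(report, models = models, class = c("shave_report", class(report)))
}

#' Parameter reduction achieved by a cut
#'
#' @param full,truncated `layer_graph`s or parameter totals.
#' @return percentage of parameters removed, `100 * (1 - cut / full)`.
#' @export
param_reduction_pct <- function(full, truncated) {
  tot <- function(x) if (inherits(x, "layer_graph")) count_parameters(x)$total
    else as.numeric(x)
  100 * (1 - tot(truncated) / tot(full))
}
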