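# Overlap metrics, misclassification inspection and the shaving series.

test_that("overlap metrics hit their closed-form anchors", {
  mask <- matrix(0, 8, 8); mask[3:5, 3:5] <- 1
  # map identical to the mask
  om <- overlap_metrics(mask, mask)
  expect_equal(om$iou, 1)
  expect_true(om$pointing_hit)
  expect_equal(om$sensitivity, 1)
  # nonzero map disjoint from the mask
  dis <- matrix(0, 8, 8); dis[7, 7] <- 1
  expect_equal(overlap_metrics(dis, mask)$sensitivity, 0)
  # uniform map over a 25% mask
  mask25 <- matrix(0, 8, 8); mask25[1:4, 1:4] <- 1
  expect_equal(overlap_metrics(matrix(0.5, 8, 8), mask25)$sensitivity, 0.25)
  # empty mask -> sensitivity undefined
  expect_true(is.na(overlap_metrics(matrix(0.5, 8, 8),
                                    matrix(0, 8, 8))$sensitivity))
  expect_error(overlap_metrics(matrix(0, 4, 4), mask), "shapes")
  expect_error(overlap_metrics(matrix(0, 8, 8), mask * 0.5), "binary")
})

test_that("a perfect classifier yields an empty misclassification report", {
  m <- fixture_model()
  correct <- Filter(function(s) {
    which.max(forward(m, s$image, keep_state = FALSE)$probs) == s$label
  }, fixture_splits()$test)
  rep_ <- misclassification_report(m, correct[1:5])
  expect_equal(nrow(rep_$table), 0)
})

test_that("top_m = 1 reports exactly the argmax prediction", {
  m <- fixture_model()
  # force errors with a freshly initialized (untrained) head
  m$weights$output$kernel[] <- withr::with_seed(3,
    stats::rnorm(length(m$weights$output$kernel)))
  samples <- fixture_splits()$test[1:6]
  rep_ <- misclassification_report(m, samples, methods = "grad_cam", top_m = 1)
  if (nrow(rep_$table)) {
    for (i in seq_len(nrow(rep_$table))) {
      smp <- samples[[rep_$table$sample[i]]]
      expect_equal(rep_$table$pred1[i],
                   which.max(forward(m, smp$image, keep_state = FALSE)$probs))
      expect_false(rep_$table$pred1[i] == rep_$table$true_label[i])
    }
    expect_false("pred2" %in% names(rep_$table))
  } else skip("random head classified everything correctly (unexpected)")
})

test_that("a background-confounded class drives attention off the leaf on errors", {
  specA <- class_spec(1, "brown_gray", lesion_color = c(0.45, 0.27, 0.07),
                      lesion_count = c(3, 5), lesion_radius = c(4, 6),
                      background = c(0.55, 0.52, 0.48))
  specB <- class_spec(2, "ring_red", lesion_color = c(0.85, 0.78, 0.25),
                      lesion_count = c(2, 4), lesion_radius = c(5, 7),
                      texture = "ringed", background = c(0.75, 0.45, 0.40))
  ds <- make_dataset(list(specA, specB), n_per_class = 15, size = 48, seed = 31)
  m <- train(build_tiny_cnn(48, 2, seed = 0), ds,
             train_config(lr = 0.01, batch_size = 8, epochs = 15, seed = 2,
                          lr_decay = 0.5, bn_momentum = 0.9))
  # class-B lesions rendered on class-A's background: the confound breaks
  specB_swap <- class_spec(2, "ring_gray", lesion_color = c(0.85, 0.78, 0.25),
                           lesion_count = c(2, 4), lesion_radius = c(5, 7),
                           texture = "ringed",
                           background = c(0.55, 0.52, 0.48))
  swapped <- lapply(1:8, function(i) make_sample(specB_swap, size = 48,
                                                 seed = 9000 + i))
  rep_ <- misclassification_report(m, swapped, methods = "grad_cam")
  expect_gt(nrow(rep_$table), 0)
  gl <- m$specs[["GAP"]]$parents[1]
  correct_bg <- sapply(Filter(function(s) s$label == 2, ds$test), function(s) {
    mp <- grad_cam_map(m, s$image, 2, gl)
    lesionviz:::background_fraction(mp, s$leaf)
  })
  expect_gt(mean(rep_$table$bg_fraction_grad_cam), mean(correct_bg))
})

test_that("shave series parameters increase with cut depth and report full model", {
  m <- fixture_model()
  splits <- fixture_splits()
  rep_ <- shave_series(m, c("Conv1", "Conv2"), splits,
                       config = train_config(lr = 0.02, batch_size = 8,
                                             epochs = 4, seed = 0))
  expect_equal(rep_$cut_layer, c("Conv1", "Conv2", "(full model)"))
  expect_lt(rep_$params[1], rep_$params[2])
  expect_lt(rep_$params[2], rep_$params[3])
  expect_true(all(rep_$test_acc >= 0 & rep_$test_acc <= 1))
  # frozen features: the retrained cut keeps the source conv weights
  models <- attr(rep_, "models")
  expect_identical(models$Conv1$weights$Conv1_conv, m$weights$Conv1_conv)
})
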