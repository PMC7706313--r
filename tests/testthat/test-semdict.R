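# Semantic dictionary: contribution-score arithmetic, conservation,
# ranking and the fixture's class specificity.

test_that("contribution scores follow the dot-product decomposition", {
  out <- contribution_scores(c(1, 2), matrix(c(0.5, -1), ncol = 1), 0.1, 1)
  expect_equal(out$score, c(0.5, -2.0))
  expect_equal(attr(out, "logit"), -1.4)
  zero <- contribution_scores(c(0, 0), matrix(c(0.5, -1), ncol = 1), 0.1, 1)
  expect_equal(zero$score, c(0, 0))
  expect_equal(attr(zero, "logit"), 0.1)
  expect_error(contribution_scores(1:3, matrix(0, 2, 1), 0, 1), "match")
})

test_that("scores conserve the pre-softmax logit on the fixture", {
  m <- fixture_model()
  for (smp in fixture_splits()$test[c(1, 9, 20)]) {
    for (cls in c(1, 3)) {
      ct <- contribution_table(m, smp$image, cls)
      fw <- forward(m, smp$image, keep_state = FALSE)
      expect_lt(abs(attr(ct, "logit") - fw$logits[cls]), 1e-5)
    }
  }
})

test_that("mean contributions equal scores of the mean GAP vector", {
  m <- fixture_model()
  imgs <- lapply(fixture_splits()$test[1:4], `[[`, "image")
  mc <- mean_contributions(m, imgs, 2)
  per <- sapply(imgs, function(im) {
    ct <- contribution_table(m, im, 2)
    ct$score[order(ct$neuron)]
  })
  want <- rowMeans(per)
  expect_equal(mc$score[order(mc$neuron)], want, tolerance = 1e-10)
  # idempotence: duplicating the image list leaves the mean unchanged
  mc2 <- mean_contributions(m, c(imgs, imgs), 2)
  expect_equal(mc2$score, mc$score, tolerance = 1e-12)
  # single image reduces to contribution_table
  one <- mean_contributions(m, imgs[1], 2)
  ct1 <- contribution_table(m, imgs[[1]], 2)
  expect_equal(one$score[order(one$neuron)], ct1$score, tolerance = 1e-12)
  expect_error(mean_contributions(m, list(), 2), "empty")
})

test_that("ranking is by descending score with ties broken by neuron index", {
  m <- fixture_model()
  mc <- mean_contributions(m, lapply(fixture_splits()$test[1:3], `[[`, "image"), 1)
  expect_true(all(diff(mc$score) <= 0))
  ties <- mc$neuron[duplicated(mc$score) | duplicated(mc$score, fromLast = TRUE)]
  if (length(ties) > 1) {
    tied_groups <- split(mc$neuron, mc$score)
    for (grp in tied_groups) expect_true(all(diff(grp) > 0))
  }
})

test_that("scores are linear in the GAP activation", {
  W <- matrix(stats::rnorm(12), 4, 3)
  a <- stats::runif(4)
  s1 <- contribution_scores(a, W, numeric(3), 2)$score
  s2 <- contribution_scores(3 * a, W, numeric(3), 2)$score
  expect_equal(s2, 3 * s1, tolerance = 1e-12)
})

test_that("the top diseased-class contributor is class-specific", {
  m <- fixture_model()
  imgs2 <- lapply(Filter(function(s) s$label == 2, fixture_splits()$test),
                  `[[`, "image")
  own <- mean_contributions(m, imgs2, 2)
  top <- own$neuron[1]
  for_healthy <- mean_contributions(m, imgs2, 1)
  expect_lt(for_healthy$score[for_healthy$neuron == top],
            own$score[own$neuron == top])
})

test_that("the dictionary ranks, renders and tabulates cross-class scores", {
  m <- fixture_model()
  imgs2 <- lapply(Filter(function(s) s$label == 2, fixture_splits()$test),
                  `[[`, "image")
  dict <- build_dictionary(m, imgs2, 2, top_n = 2, steps = 24, seed = 3)
  expect_length(dict$entries, 2)
  expect_gte(dict$entries[[1]]$score, dict$entries[[2]]$score)
  expect_equal(dim(dict$entries[[1]]$render)[3], 3)
  expect_equal(nrow(dict$cross_class), 2 * 4)
  # top_n = 0 -> empty dictionary
  empty <- build_dictionary(m, imgs2, 2, top_n = 0, steps = 2)
  expect_length(empty$entries, 0)
  expect_error(build_dictionary(m, imgs2, 2, top_n = 1e5), "GAP dimension")
})

test_that("the lesion class's top-neuron render is closer to lesion than leaf color", {
  m <- fixture_model()
  imgs2 <- lapply(Filter(function(s) s$label == 2, fixture_splits()$test),
                  `[[`, "image")
  dict <- build_dictionary(m, imgs2, 2, top_n = 1, steps = 128, seed = 3)
  mc <- apply(dict$entries[[1]]$render, 3, mean)
  spec2 <- fixture_splits()$specs[[2]]
  d_lesion <- sqrt(sum((mc - spec2$lesion_color)^2))
  d_leaf <- sqrt(sum((mc - spec2$leaf_color)^2))
  d_bg <- sqrt(sum((mc - spec2$background)^2))
  expect_lt(d_lesion, d_leaf)
  expect_lt(d_lesion, d_bg)
})
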