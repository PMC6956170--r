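test_that("label encodings are injective and round-trip", {
  e <- encode_labels(c("A", "B", "A"), "signed_binary")
  expect_equal(unname(e$matrix[, 1L]), c(-1, 1, -1)) # sorted: A -> -1, B -> +1
  expect_error(encode_labels(c("A", "B", "C"), "signed_binary"), "exactly 2")
  oh <- encode_labels(c("A", "B", "C"), "one_hot")
  expect_equal(unname(oh$encoding$mapping), diag(3))
  withr::with_seed(23, {
    for (scheme in c("one_hot", "integer_code")) {
      y <- sample(letters[1:4], 30, replace = TRUE)
      enc <- encode_labels(y, scheme)
      expect_identical(decode_labels(enc$encoding, enc$matrix), y)
    }
    y2 <- sample(c("A", "B"), 20, replace = TRUE)
    enc2 <- encode_labels(y2, "signed_binary")
    expect_identical(decode_labels(enc2$encoding, enc2$matrix), y2)
  })
})

test_that("label-space neighborhood lengths follow the encoding geometry", {
  fx <- fit_noisy_advised(seed = 7L)
  md <- find_misclassified(fx$base, fx$ds)
  # binary signed encoding, plain distance: NL = |(-1) - (+1)| = 2
  enc <- encode_labels(fx$ds$y, "signed_binary")$encoding
  out <- label_neighborhood_lengths(md, fx$ds, enc)
  expect_true(all(out$nl == 2))
  # label RBF: NL = sqrt(2 - 2 exp(-4 gamma))
  g <- 0.3
  outk <- label_neighborhood_lengths(md, fx$ds, enc, rbf_kernel(g))
  expect_equal(unique(outk$nl), sqrt(2 - 2 * exp(-4 * g)))
  # one-hot with 3 classes: distinct classes sit at distance sqrt(2)
  d3 <- make_blobs(n_per_class = 25L, n_classes = 3L, spread = 1.6,
                   label_noise = 0.1, seed = 5L)
  m3 <- train_svm(d3, "c", rbf_kernel(0.5), cost = 1)
  md3 <- find_misclassified(m3, d3)
  expect_gt(length(md3$indices), 0L)
  enc3 <- encode_labels(d3$y, "one_hot")$encoding
  out3 <- label_neighborhood_lengths(md3, d3, enc3)
  expect_true(all(out3$nl == sqrt(2)))
})

test_that("binary label space is degenerate: all of MD qualifies and LAW counts label agreement", {
  fx <- fit_noisy_advised(seed = 7L, space = "label")
  adv <- fx$adv
  expect_identical(adv$encoding$scheme, "signed_binary")
  expect_true(all(adv$md$nl == 2))
  # distances from any predicted label to MD labels are 0 or 2 <= NL = 2:
  # the qualifying set is all of MD and LAW is the fraction of MD whose
  # true label equals the predicted label
  for (cl in adv$base$classes) {
    expect_equal(label_advised_weight(adv, cl),
                 mean(adv$md$labels == cl))
  }
  law <- label_advised_weight(adv, predict(adv$base, fx$ds$X))
  expect_true(all(law >= 0 & law <= 1))
})

test_that("label advising reduces to the base SVM when MD is empty", {
  sep <- separable_blobs(seed = 10L)
  m <- train_svm(sep, "c", rbf_kernel(1), cost = 10)
  adv <- label_self_advise(m, sep)
  expect_length(adv$md$indices, 0L)
  withr::with_seed(3, Xt <- matrix(rnorm(60), 30))
  expect_identical(lsa_predict(adv, Xt), predict(m, Xt))
  expect_equal(label_advised_weight(adv, rep("c1", 5)), rep(0, 5))
})

test_that("the label relabel branch fires on a planted low-confidence point", {
  fx <- make_planted_fixture(seed = 2L)
  base <- train_svm(fx$train, "c", rbf_kernel(fx$params$gamma),
                    cost = fx$params$C)
  adv <- label_self_advise(base, fx$train)
  # MD is dominated by the planted "a"-labeled points; a test point the
  # base SVM assigns to "a" with low confidence has LAW near 1 and is
  # routed through the relabel branch; its nearest qualifying MD point in
  # feature space then determines the label (rule mechanics, not accuracy)
  expect_gt(mean(adv$md$labels == "a"), 0.5)
  pred <- lsa_predict(adv, fx$test$X)
  expect_true(all(pred %in% fx$train$classes))
  dec <- lsasvm:::ovo_decide(base, fx$test$X)
  sdv <- scale_decision_values(dec$proxy)
  law <- label_advised_weight(adv, dec$labels)
  override <- which(law >= sdv)
  expect_gt(length(override), 0L)
  act <- which(!is.na(adv$md$nl))
  for (k in override) {
    # relabeled to the feature-space-nearest qualifying MD point's label
    d <- lsasvm:::induced_distance_matrix(base$kernel,
                                          fx$test$X[k, , drop = FALSE],
                                          adv$md$points[act, , drop = FALSE])
    expect_identical(pred[k], adv$md$labels[act][which.min(d)])
  }
  # the branch that keeps the SVM label is untouched
  keep <- which(law < sdv)
  expect_identical(pred[keep], dec$labels[keep])
})

test_that("label advising scales with the class count, not the feature dimension", {
  # the label-space pass evaluates one distance per (class, MD point)
  # pair, independent of the test-set size; the feature-space pass
  # evaluates one per (test point, MD point) pair — fewer label-space
  # operations whenever there are at least as many test points as classes
  fx <- fit_noisy_advised(seed = 7L)
  n_md <- sum(!is.na(fx$adv$md$nl))
  n_classes <- length(fx$base$classes)
  n_test <- 50L
  label_ops <- n_classes * n_md
  feature_ops <- n_test * n_md
  expect_lte(label_ops, feature_ops)
})
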