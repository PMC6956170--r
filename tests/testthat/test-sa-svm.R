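test_that("find_misclassified matches the definitional brute-force set", {
  fx <- fit_noisy_advised(seed = 7L)
  md <- find_misclassified(fx$base, fx$ds)
  pred <- predict(fx$base, fx$ds$X)
  expect_identical(md$indices, which(pred != fx$ds$y))
  expect_gt(length(md$indices), 0L)
  expect_identical(md$labels, fx$ds$y[md$indices])
  # perfectly fitted separable data: empty MD
  sep <- separable_blobs(seed = 4L)
  m <- train_svm(sep, "c", rbf_kernel(1), cost = 10)
  expect_length(find_misclassified(m, sep)$indices, 0L)
})

test_that("neighborhood lengths reproduce the single-neighbor geometry", {
  # MD point (0,0) labeled +1; non-MD neighbors (0,3) labeled -1 and
  # (1,0) labeled +1: only the opposite-label point qualifies, NL = 3
  train <- labeled_dataset(rbind(c(0, 0), c(0, 3), c(1, 0)),
                           c("pos", "neg", "pos"))
  md <- manual_md(rbind(c(0, 0)), "pos", indices = 1L)
  out <- neighborhood_lengths(md, train, linear_kernel())
  expect_equal(out$nl, 3)
})

test_that("neighborhood lengths match the double-loop oracle exactly", {
  withr::with_seed(31, {
    n <- 50L
    X <- matrix(rnorm(n * 3), n)
    y <- sample(c("a", "b"), n, replace = TRUE)
    md_idx <- sort(sample(n, 8L))
  })
  train <- labeled_dataset(X, y)
  md <- manual_md(X[md_idx, , drop = FALSE], y[md_idx], indices = md_idx)
  kern <- rbf_kernel(0.4)
  out <- neighborhood_lengths(md, train, kern)
  oracle <- vapply(seq_along(md_idx), function(i) {
    best <- Inf
    for (j in setdiff(seq_len(n), md_idx)) {
      if (y[j] != y[md_idx[i]]) {
        best <- min(best, induced_distance(kern, X[md_idx[i], ], X[j, ]))
      }
    }
    if (is.finite(best)) best else NA_real_
  }, numeric(1))
  expect_identical(out$nl, oracle)
})

test_that("points with no opposite-label correctly-classified neighbor are flagged", {
  train <- labeled_dataset(rbind(c(0, 0), c(1, 0), c(2, 0)),
                           c("a", "a", "b"))
  # MD = {1, 3}: the only non-MD point (row 2) shares row 1's label
  md <- manual_md(train$X[c(1L, 3L), ], c("a", "b"), indices = c(1L, 3L))
  out <- neighborhood_lengths(md, train, linear_kernel())
  expect_true(is.na(out$nl[1L]))
  expect_equal(out$nl[2L], 1) # row 3 vs row 2: labels differ, distance 1
})

test_that("advised weight honors the zero branches and the coincident case", {
  kern <- linear_kernel()
  # empty MD -> 0 everywhere
  adv0 <- manual_advised(kern, manual_md(matrix(numeric(0), 0, 2),
                                         character(0), integer(0)))
  expect_equal(advised_weight(adv0, matrix(rnorm(10), 5)), rep(0, 5))
  # single MD point, NL = 1
  adv1 <- manual_advised(kern, manual_md(rbind(c(0, 0)), "a", 1L, nl = 1))
  expect_equal(advised_weight(adv1, c(0, 0)), 1)       # coincident -> 1
  expect_equal(advised_weight(adv1, c(5, 0)), 0)       # outside every NL
  expect_equal(advised_weight(adv1, c(0.25, 0)), 0.75) # 1 - d/NL
})

test_that("advised weights stay in [0,1] on random instances", {
  fx <- fit_noisy_advised(seed = 7L)
  withr::with_seed(8, Xt <- matrix(rnorm(400, sd = 3), 200))
  aw <- advised_weight(fx$adv, Xt)
  expect_true(all(aw >= 0 & aw <= 1))
  # probing at the MD points themselves guarantees nonzero weights
  aw_md <- advised_weight(fx$adv, fx$adv$md$points)
  expect_true(any(aw_md > 0))
  expect_true(all(aw_md >= 0 & aw_md <= 1))
})

test_that("decision-value scaling maps onto [0,1] with order preserved", {
  expect_equal(scale_decision_values(c(-2, 1, 0)), c(1, 0.5, 0))
  expect_equal(scale_decision_values(c(0, 0)), c(0, 0))
  expect_identical(scale_decision_values(numeric(0)), numeric(0))
  withr::with_seed(17, {
    for (i in 1:20) {
      v <- rnorm(25, sd = 10^runif(1, -3, 3))
      s <- scale_decision_values(v)
      expect_true(all(s >= 0 & s <= 1))
      expect_identical(order(abs(v)), order(s))
    }
  })
})

test_that("advising reduces to the base SVM when nothing qualifies", {
  sep <- separable_blobs(seed = 6L)
  m <- train_svm(sep, "c", rbf_kernel(1), cost = 10)
  adv <- self_advise(m, sep)
  expect_length(adv$md$indices, 0L)
  withr::with_seed(2, Xt <- matrix(rnorm(60), 30))
  expect_identical(predict(adv, Xt), predict(m, Xt))
  expect_identical(advised_predict(adv, Xt), predict(m, Xt))
})

test_that("the planted fixture's expected test points are corrected", {
  fx <- make_planted_fixture(seed = 3L)
  base <- train_svm(fx$train, "c", rbf_kernel(fx$params$gamma),
                    cost = fx$params$C)
  adv <- self_advise(base, fx$train)
  bp <- predict(base, fx$test$X)
  ap <- predict(adv, fx$test$X)
  expect_true(all(bp[fx$expected_flips] != ap[fx$expected_flips]))
  expect_identical(ap[fx$expected_flips], fx$test$y[fx$expected_flips])
  expect_gt(accuracy(fx$test$y, ap), accuracy(fx$test$y, bp))
  # labels never leave the training class set
  expect_true(all(ap %in% fx$train$classes))
})

test_that("multiclass advising reduces exactly to the binary rule for 2 classes", {
  # the advising proxy for the one-vs-one vote winner is its minimal
  # pairwise |h|; with a single pair this is |h|, i.e. the binary rule
  fx <- fit_noisy_advised(seed = 9L)
  H <- decision_value(fx$base, fx$ds$X)
  dec <- lsasvm:::ovo_decide(fx$base, fx$ds$X)
  expect_equal(dec$proxy, H)
})
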