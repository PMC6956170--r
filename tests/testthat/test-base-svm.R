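test_that("separable blobs are fitted perfectly and decision values reconstruct", {
  ds <- separable_blobs(seed = 3L)
  m <- train_svm(ds, "c", rbf_kernel(1), cost = 1)
  expect_equal(accuracy(ds$y, predict(m, ds$X)), 1.0)
  # explicit loop over support vectors reproduces decision_value
  h <- decision_value(m, ds$X)
  p <- m$pairs[[1L]]
  brute <- vapply(seq_len(nrow(ds$X)), function(i) {
    sum(p$coefs * vapply(seq_len(nrow(p$sv)), function(j) {
      kernel_eval(m$kernel, ds$X[i, ], p$sv[j, ])
    }, numeric(1))) - p$rho
  }, numeric(1))
  expect_lt(max(abs(h - brute)), 1e-9)
  # sign contract: a point deep inside a cluster has a decisive margin
  deep <- ds$X[which(ds$y == predict(m, ds$X))[1L], ]
  lab <- if (decision_value(m, deep) > 0) m$pairs[[1]]$pos else m$pairs[[1]]$neg
  expect_identical(predict(m, deep), lab)
})

test_that("degenerate training inputs error", {
  X <- matrix(rnorm(20), 10)
  expect_error(train_svm(labeled_dataset(X, rep("a", 10)), "c",
                         rbf_kernel(1)), "single class")
  expect_error(train_svm(labeled_dataset(X, c(rep("a", 8), "b", "b")),
                         "nu", rbf_kernel(1), nu = 0.9), "infeasible")
  m <- train_svm(separable_blobs(), "c", rbf_kernel(1), cost = 1)
  expect_error(decision_value(m, matrix(rnorm(9), 3)), "dimension mismatch")
})

test_that("nu-SVM fits and its stored parameters reconstruct decision values", {
  ds <- separable_blobs(seed = 9L)
  m <- train_svm(ds, "nu", rbf_kernel(1), nu = 0.2)
  expect_identical(m$variant, "nu")
  expect_null(m$cost)
  expect_equal(accuracy(ds$y, predict(m, ds$X)), 1.0)
})

test_that("negating the geometry flips every binary prediction", {
  # mirror symmetry: reflecting the features through the origin swaps the
  # two (symmetric) clusters, so predictions must swap too
  ds <- separable_blobs(seed = 13L)
  m <- train_svm(ds, "c", rbf_kernel(1), cost = 1)
  ds_flipped <- labeled_dataset(ds$X, ifelse(ds$y == "c1", "c2", "c1"))
  m2 <- train_svm(ds_flipped, "c", rbf_kernel(1), cost = 1)
  withr::with_seed(1, Xt <- matrix(rnorm(40), 20))
  p1 <- predict(m, Xt); p2 <- predict(m2, Xt)
  expect_true(all(p1 != p2))
})

test_that("one-vs-one trains all class pairs and votes deterministically", {
  d4 <- make_blobs(n_per_class = 20L, n_classes = 4L, spread = 0.5, seed = 5L)
  m <- train_svm(d4, "c", rbf_kernel(0.5), cost = 10)
  expect_identical(m$multiclass_scheme, "one_vs_one")
  expect_length(m$pairs, 6L) # choose(4, 2)
  expect_equal(accuracy(d4$y, predict(m, d4$X)), 1.0)
  H <- decision_value(m, d4$X[1:3, ])
  expect_identical(dim(H), c(3L, 6L))
  expect_true(all(predict(m, d4$X) %in% d4$classes))
})

test_that("grid search evaluates the full grid, breaks ties toward small params", {
  ds <- separable_blobs(seed = 2L, n = 10L)
  g1 <- grid_search(ds, "c", param_grid(C_values = 2, gamma_values = 0.5),
                    folds = 2L, seed = 1L)
  expect_equal(g1$best$C_or_nu, 2)
  expect_equal(g1$best$gamma, 0.5)
  gs <- grid_search(ds, "c",
                    param_grid(C_values = c(1, 4), gamma_values = c(0.25, 1)),
                    folds = 2L, seed = 1L)
  expect_equal(nrow(gs$table), 4L)
  # all combinations separate this fixture perfectly: tie-break picks the
  # smallest C, then the smallest gamma
  expect_true(all(gs$table$mean_accuracy == 1))
  expect_equal(gs$best$C_or_nu, 1)
  expect_equal(gs$best$gamma, 0.25)
  # reproducibility
  gs2 <- grid_search(ds, "c",
                     param_grid(C_values = c(1, 4), gamma_values = c(0.25, 1)),
                     folds = 2L, seed = 1L)
  expect_identical(gs$table, gs2$table)
})

test_that("grid search rejects a badly underfitting gamma on an xor fixture", {
  # two classes on the corners of a square: not linearly separable, so a
  # near-linear rbf (tiny gamma) underfits while a moderate gamma fits
  withr::with_seed(21, {
    centers <- rbind(c(2, 2), c(-2, -2), c(2, -2), c(-2, 2))
    X <- do.call(rbind, lapply(1:4, function(cl) {
      sweep(matrix(rnorm(2 * 15, sd = 0.4), ncol = 2), 2, centers[cl, ], "+")
    }))
  })
  y <- rep(c("p", "p", "q", "q"), each = 15L)
  ds <- labeled_dataset(X, y)
  gs <- grid_search(ds, "c", param_grid(C_values = 1,
                                        gamma_values = c(2^-9, 1)),
                    folds = 3L, seed = 4L)
  tab <- gs$table
  expect_lt(tab$mean_accuracy[tab$gamma == 2^-9],
            tab$mean_accuracy[tab$gamma == 1])
  expect_identical(gs$best$gamma, 1)
})
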