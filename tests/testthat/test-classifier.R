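test_that("compute_class_weights is balanced and conserves sample mass", {
  expect_equal(compute_class_weights(c(PK = 10, DEMOGRAPHICS = 10,
                                       OTHER = 10)),
               c(PK = 1, DEMOGRAPHICS = 1, OTHER = 1))
  # corpus-scale counts: w_c = N / (3 n_c), computed here as the oracle
  counts <- c(PK = 532, DEMOGRAPHICS = 233, OTHER = 819)
  w <- compute_class_weights(counts)
  expect_equal(unname(w), 1584 / (3 * unname(counts)))
  expect_equal(round(unname(w), 4), c(0.9925, 2.2661, 0.6447))
  # extreme imbalance
  w2 <- compute_class_weights(c(PK = 1, DEMOGRAPHICS = 1, OTHER = 998))
  expect_equal(round(unname(w2), 4), c(333.3333, 333.3333, 0.334))

  expect_error(compute_class_weights(c(PK = 1, OTHER = 2)), "DEMOGRAPHICS")

  set.seed(30)
  for (i in 1:1000) {
    n_c <- sample(1:5000, 3)
    names(n_c) <- PK_LABELS
    w <- compute_class_weights(n_c)
    expect_equal(sum(n_c * w), sum(n_c))  # weighted mass conserved
  }
})

test_that("grid_candidates enumerates the default grid in row-major order", {
  g <- grid_candidates()
  expect_equal(nrow(g), 3600)
  expect_equal(unlist(g[1, ]), c(max_depth = 2, min_child_weight = 1,
                                 gamma = 0.1, subsample = 0.5,
                                 colsample_bytree = 0.3))
  # last dimension varies fastest
  expect_equal(g$colsample_bytree[1:8], seq(0.3, 1.0, by = 0.1))
  expect_equal(g$max_depth[1], g$max_depth[2])
  # one value per dimension -> one candidate
  g1 <- grid_candidates(list(max_depth = c(4, 4, 1),
                             min_child_weight = c(1, 1, 1),
                             gamma = c(0, 0, 1), subsample = c(1, 1, 1),
                             colsample_bytree = c(1, 1, 1)))
  expect_equal(nrow(g1), 1)
  expect_error(grid_candidates(list(a = c(1, 2, 0))), "step")
})

test_that("grid size equals the product of per-dimension counts (oracle)", {
  set.seed(31)
  for (i in 1:20) {
    spec <- lapply(1:5, function(d) {
      lo <- stats::runif(1); step <- stats::runif(1, 0.05, 0.5)
      k <- sample(1:6, 1)
      c(lo, lo + (k - 1) * step, step)
    })
    names(spec) <- names(default_grid_spec())
    counts <- vapply(spec, function(tr) {
      n <- 0L; x <- tr[1]
      while (x <= tr[2] + 1e-9) { n <- n + 1L; x <- x + tr[3] }  # oracle loop
      n
    }, integer(1))
    expect_equal(nrow(grid_candidates(spec)), prod(counts))
  }
})

test_that("training separates separable data and stops before the cap", {
  d <- separable_data(n_per_class = 100, seed = 32)
  model <- train_boosted(d$X, d$labels, seed = 32)
  pred <- predict(model, d$X)
  expect_equal(mean(pred$label == d$labels), 1.0)
  expect_lt(model$rounds_used, 1000)
  # early stopping contract: at most patience rounds past the best iteration
  expect_lte(model$rounds_used,
             model$best_iter + model$hp$early_stopping_rounds)
})

test_that("training is deterministic given the seed", {
  d <- separable_data(n_per_class = 30, seed = 33)
  probe <- matrix(stats::runif(60), 10, 6)
  hp <- hyperparameters(max_depth = 3, subsample = 0.8,
                        colsample_bytree = 0.8)
  m1 <- train_boosted(d$X, d$labels, hp = hp, seed = 9)
  m2 <- train_boosted(d$X, d$labels, hp = hp, seed = 9)
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("train validates inputs", {
  d <- separable_data(10)
  expect_error(train_boosted(d$X, d$labels[-1]), "mismatch")
  expect_error(train_boosted(d$X[1:10, ], rep("PK", 10)), "2 classes")
})

test_that("predictions are simplex vectors; ties break by class order", {
  d <- separable_data(n_per_class = 20, seed = 34)
  model <- train_boosted(d$X, d$labels, seed = 34)
  pred <- predict(model, matrix(stats::runif(120), 20, 6))
  probs <- as.matrix(pred[, paste0("prob_", PK_LABELS)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_true(all(probs >= 0))
  expect_equal(pred$confidence, apply(probs, 1, max))
  expect_error(predict(model, matrix(0, 2, 5)), "dimension mismatch")

  # engineered exact tie: a zero-tree model gives 1/3 each -> PK wins
  flat <- model
  flat$best_iter <- 0L
  p0 <- predict(flat, d$X[1, , drop = FALSE])
  expect_equal(unname(unlist(p0[, 1:3])), rep(1 / 3, 3))
  expect_equal(p0$label, "PK")
})

test_that("tune selects by mean macro-F1 over stratified folds", {
  d <- separable_data(n_per_class = 15, seed = 35)
  grid <- grid_candidates(list(max_depth = c(2, 4, 2),
                               min_child_weight = c(1, 1, 1),
                               gamma = c(0.1, 0.1, 1),
                               subsample = c(1, 1, 1),
                               colsample_bytree = c(1, 1, 1)))
  res <- tune_boosted(d$X, d$labels, grid, folds = 3, seed = 35)
  fs <- attr(res$report, "fold_scores")
  expect_equal(dim(fs), c(2, 3))
  expect_equal(res$report$mean_macro_f1, rowMeans(fs))
  expect_equal(res$best_index, which.max(rowMeans(fs)))
  expect_s3_class(res$best, "pk_hyperparameters")
  # single-candidate grid returns that candidate
  res1 <- tune_boosted(d$X, d$labels, grid[1, , drop = FALSE], folds = 3,
                       seed = 35)
  expect_equal(res1$best$max_depth, grid$max_depth[1])
  # class smaller than fold count is rejected with advice
  expect_error(tune_boosted(d$X[1:9, ], rep(PK_LABELS, each = 3),
                            grid[1, , drop = FALSE], folds = 5, seed = 1),
               "fewer folds")
})

test_that("stratified folds partition the data with every sample used once", {
  labels <- rep(PK_LABELS, c(20, 12, 28))
  assign <- pktables:::stratified_folds(labels, 4, seed = 36)
  expect_equal(sort(unique(assign)), 1:4)
  expect_equal(length(assign), 60)
  for (cls in PK_LABELS) {
    sizes <- table(assign[labels == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
})
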