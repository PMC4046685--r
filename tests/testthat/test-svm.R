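# small separable fixture: two Gaussian blobs, imbalanced
separableToy <- function(n = 60, gap = 6, seed = 1) {
  set.seed(seed)
  nPos <- round(n / 3)
  x <- rbind(matrix(rnorm(nPos * 2, mean = gap / 2), ncol = 2),
             matrix(rnorm((n - nPos) * 2, mean = -gap / 2), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- c(rep("stabilising", nPos), rep("destabilising", n - nPos))
  list(x = x, y = y)
}

test_that("the default dyadic grids have the declared extent", {
  gc <- defaultGrid("classification")
  expect_equal(nrow(gc), 495L)
  expect_equal(min(gc$C), 2^-5)
  expect_equal(max(gc$C), 2^15)
  expect_equal(sort(unique(gc$w)), c(1, 1.5, 2, 2.5, 3))
  expect_equal(length(unique(gc$gamma)), 9L)
  gr <- defaultGrid("regression")
  expect_equal(nrow(gr), 1024L)
  expect_equal(range(gr$gamma), c(2^-15, 2^0))
  expect_equal(range(gr$epsilon), c(2^-8, 2^-1))
  expect_equal(length(unique(gr$C)), 8L)
})

test_that("a separable toy reaches MCC 1 in training and cross-validation", {
  toy <- separableToy()
  params <- data.frame(C = 8, gamma = 0.5, w = 1)
  model <- trainModel(toy$x, toy$y, params, "classification")
  pred <- predictModel(model, toy$x)
  expect_equal(classificationMetrics(confusionCounts(toy$y, pred$label))[["mcc"]],
               1)
  folds <- rep(1:3, length.out = length(toy$y))
  gs <- gridSearch(toy$x, toy$y, folds, "classification",
                   compactGrid("classification"))
  expect_equal(max(gs$scores$score, na.rm = TRUE), 1)
})

test_that("randomly shuffled labels give near-zero cross-validated MCC", {
  toy <- separableToy(n = 200, seed = 5)
  set.seed(6)
  yShuf <- sample(toy$y)
  folds <- rep(1:4, length.out = length(yShuf))
  gs <- gridSearch(toy$x, yShuf, folds, "classification",
                   compactGrid("classification"))
  expect_lt(max(gs$scores$score, na.rm = TRUE), 0.25)
})

test_that("a larger positive-class weight raises sensitivity on imbalanced data", {
  set.seed(9)
  n <- 150
  x <- matrix(rnorm(n * 2), ncol = 2)
  # weak signal, 20% positives: unweighted SVM collapses to the majority
  y <- ifelse(x[, 1] + rnorm(n, 0, 1.5) > qnorm(0.8) * sqrt(1 + 1.5^2),
              "stabilising", "destabilising")
  se <- vapply(c(1, 3), function(w) {
    m <- trainModel(x, y, data.frame(C = 1, gamma = 0.5, w = w),
                    "classification")
    p <- predictModel(m, x)
    classificationMetrics(confusionCounts(y, p$label))[["se"]]
  }, 1)
  expect_gte(se[2], se[1])
})

test_that("regression on a constant target predicts within epsilon", {
  set.seed(3)
  x <- matrix(rnorm(40), ncol = 2)
  y <- rep(1.5, 20)
  m <- trainModel(x, y, data.frame(C = 1, gamma = 0.5, epsilon = 0.125),
                  "regression")
  expect_true(all(abs(predictModel(m, x) - 1.5) <= 0.125 + 1e-8))
})

test_that("predictions are deterministic, dimension-checked, and empty-safe", {
  toy <- separableToy(seed = 12)
  m <- trainModel(toy$x, toy$y, data.frame(C = 1, gamma = 0.5, w = 1),
                  "classification")
  p1 <- predictModel(m, toy$x)
  p2 <- predictModel(m, toy$x)
  expect_identical(p1, p2)
  expect_error(predictModel(m, toy$x[, 1, drop = FALSE]), "dimensionality")
  empty <- predictModel(m, toy$x[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
  expect_error(trainModel(toy$x, rep("stabilising", nrow(toy$x)),
                          data.frame(C = 1, gamma = 0.5, w = 1),
                          "classification"), "both classes")
})

test_that("the grid-search winner is invariant to candidate enumeration order", {
  toy <- separableToy(n = 80, gap = 1.5, seed = 21)
  folds <- rep(1:3, length.out = length(toy$y))
  grid <- compactGrid("classification")
  gs1 <- gridSearch(toy$x, toy$y, folds, "classification", grid)
  set.seed(2)
  gs2 <- gridSearch(toy$x, toy$y, folds, "classification",
                    grid[sample(nrow(grid)), ])
  expect_equal(gs1$best, gs2$best, ignore_attr = TRUE)
})

test_that("replicate comparison handles identical runs and single replicates", {
  sim <- simulateDataset(smallSyntheticConfig(seed = 33))
  x <- encodeFeatures(sim$dataset, sim$annotations, sim$profiles, "easeAA")
  run <- runReplicates(sim$dataset, sim$clustering, encoder = x,
                       scheme = "unseen_mutation", task = "classification",
                       R = 2, k = 2, seed = 7,
                       grid = data.frame(C = 1, gamma = 0.25, w = 1))
  expect_equal(nrow(run$perReplicate), 2L)
  cmp <- comparePerformance(run, run, "mcc")
  expect_equal(cmp$p.value, 1)
  expect_equal(cmp$estimate, 0)
  run1 <- runReplicates(sim$dataset, sim$clustering, encoder = x,
                        scheme = "unseen_mutation", task = "classification",
                        R = 1, k = 2, seed = 7,
                        grid = data.frame(C = 1, gamma = 0.25, w = 1))
  expect_equal(run1$aggregate[["mcc"]], run1$perReplicate$mcc[1])
  expect_true(is.na(comparePerformance(run1, run1, "mcc")$p.value))
})

test_that("an informative encoder beats noise features significantly", {
  sim <- simulateDataset(syntheticConfig(nClusters = 10, proteinsPerCluster = 2,
                                         mutationsPerProtein = 12, seed = 41))
  x <- encodeFeatures(sim$dataset, sim$annotations, sim$profiles, "easeAA")
  set.seed(42)
  noise <- matrix(rnorm(length(x)), nrow = nrow(x))
  grid <- data.frame(C = 8, gamma = 1 / 14, w = 1)
  good <- runReplicates(sim$dataset, sim$clustering, encoder = x,
                        scheme = "unseen_mutation", task = "classification",
                        R = 5, k = 3, seed = 19, grid = grid)
  bad <- runReplicates(sim$dataset, sim$clustering, encoder = noise,
                       scheme = "unseen_mutation", task = "classification",
                       R = 5, k = 3, seed = 19, grid = grid)
  cmp <- comparePerformance(good, bad, "mcc")
  expect_gt(cmp$estimate, 0)
  expect_lt(cmp$p.value, 0.05)
})
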