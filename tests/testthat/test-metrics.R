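test_that("confusion counts treat stabilising as the positive class", {
  truth <- c(rep("stabilising", 3), rep("destabilising", 5))
  expect_equal(confusionCounts(truth, truth),
               c(TP = 3L, TN = 5L, FP = 0L, FN = 0L))
  allNeg <- rep("destabilising", 8)
  expect_equal(confusionCounts(truth, allNeg),
               c(TP = 0L, TN = 5L, FP = 0L, FN = 3L))
  expect_error(confusionCounts(character(), character()), "empty")
  expect_error(confusionCounts(truth, truth[-1]), "mismatch")
})

test_that("classification metrics match direct formula evaluation", {
  m <- classificationMetrics(c(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(m[["mcc"]], 1)
  expect_equal(m[["q2"]], 100)
  m <- classificationMetrics(c(TP = 50, TN = 50, FP = 50, FN = 50))
  expect_equal(m[["mcc"]], 0)
  expect_equal(m[["q2"]], 50)
  m <- classificationMetrics(c(TP = 8, TN = 10, FP = 2, FN = 4))
  want <- oracleClassificationMetrics(8, 10, 2, 4)
  expect_equal(m, want, tolerance = 1e-12)
  expect_equal(m[["mcc"]], 0.50709255, tolerance = 1e-6)
  expect_equal(m[["q2"]], 75)
  expect_equal(m[["ppv"]], 80)
})

test_that("zero denominators give missing rates and MCC zero", {
  m <- classificationMetrics(c(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m[["se"]]))
  expect_true(is.na(m[["ppv"]]))
  expect_equal(m[["mcc"]], 0)
  expect_equal(m[["q2"]], 100)
})

test_that("metrics agree with brute-force oracles on random instances", {
  set.seed(99)
  for (i in 1:300) {
    counts <- sample(0:30, 4, replace = TRUE)
    if (sum(counts) == 0) next
    got <- classificationMetrics(setNames(counts, c("TP", "TN", "FP", "FN")))
    want <- oracleClassificationMetrics(counts[1], counts[2], counts[3], counts[4])
    expect_equal(got, want, tolerance = 1e-10)
  }
  for (i in 1:100) {
    n <- sample(4:20, 1)
    truth <- sample(c("stabilising", "destabilising"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(n), 1)   # rounding forces score ties
    expect_equal(rocAuc(scores, truth)$auc, oracleAuc(scores, truth),
                 tolerance = 1e-10)
  }
})

test_that("ROC/AUC handles perfect ranking, ties, and the 3/4 pair example", {
  truth <- c(rep("stabilising", 4), rep("destabilising", 4))
  expect_equal(rocAuc(c(4, 3.5, 3, 2.5, 2, 1, 0.5, 0), truth)$auc, 1)
  expect_equal(rocAuc(rep(1, 8), truth)$auc, 0.5)
  auc <- rocAuc(c(0.8, 0.4, 0.6, 0.2),
                c("stabilising", "stabilising", "destabilising",
                  "destabilising"))$auc
  expect_equal(auc, 0.75)
  expect_error(rocAuc(1:3, rep("stabilising", 3)), "both classes")
})

test_that("AUC is invariant under monotone transforms and flips on negation", {
  set.seed(7)
  truth <- sample(c("stabilising", "destabilising"), 40, replace = TRUE,
                  prob = c(0.3, 0.7))
  scores <- rnorm(40)
  a <- rocAuc(scores, truth)$auc
  expect_equal(rocAuc(exp(scores), truth)$auc, a)
  expect_equal(rocAuc(100 + 3 * scores, truth)$auc, a)
  flipped <- ifelse(truth == "stabilising", "destabilising", "stabilising")
  expect_equal(rocAuc(-scores, flipped)$auc, a)
  expect_equal(rocAuc(-scores, truth)$auc, 1 - a)
})

test_that("regression metrics follow their closed forms", {
  obs <- c(0.5, -1, 2, 0)
  expect_equal(regressionMetrics(obs, obs), c(r = 1, rmse = 0))
  expect_equal(regressionMetrics(-obs, obs)[["r"]], -1)
  expect_equal(regressionMetrics(c(1, 2), c(0, 0))[["rmse"]], sqrt(5 / 2))
  m <- regressionMetrics(c(1, 2), c(3, 3))
  expect_true(is.na(m[["r"]]))
  expect_equal(m[["rmse"]], sqrt(mean(c(4, 1))))
  expect_error(regressionMetrics(1, 1), "two")
})

test_that("percent metrics and correlations stay within their bounds", {
  set.seed(31)
  for (i in 1:200) {
    counts <- setNames(sample(0:15, 4, replace = TRUE), c("TP", "TN", "FP", "FN"))
    if (sum(counts) == 0) next
    m <- classificationMetrics(counts)
    expect_true(all(m[c("q2", "se", "sp", "ppv", "npv")] >= 0, na.rm = TRUE))
    expect_true(all(m[c("q2", "se", "sp", "ppv", "npv")] <= 100, na.rm = TRUE))
    expect_gte(m[["mcc"]], -1); expect_lte(m[["mcc"]], 1)
  }
})

test_that("stratification applies the boundary rules inclusively", {
  rec <- data.frame(protein_id = "p1", wt_aa = "A", position = 1:4,
                    mut_aa = "G", ddg = c(1.0, 1.01, -0.3, -2))
  ds <- MutationDataset(rec)
  ann <- data.frame(ss = c("helix", "coil", "sheet", "coil"),
                    asa = c(0.25, 0.1, NA, 0.8),
                    sift = 0.5, disorder = 0.5)
  s <- stratify(ds, ann)
  expect_equal(s$exposure, c("exposed", "buried", NA, "exposed"))
  expect_equal(s$magnitude, c("small", "large", "small", "large"))
  expect_equal(s$ss, ann$ss)
})

test_that("stratified metrics isolate badly predicted strata", {
  rec <- data.frame(protein_id = "p1", wt_aa = "A", position = 1:12,
                    mut_aa = "G",
                    ddg = rep(c(1, -1), 6))
  ds <- MutationDataset(rec)
  ann <- data.frame(ss = rep(c("helix", "coil"), each = 6),
                    asa = 0.5, sift = 0.5, disorder = 0.5)
  truth <- labelSign(rec$ddg)
  pred <- truth
  coil <- ann$ss == "coil"
  pred[coil] <- ifelse(truth[coil] == "stabilising", "destabilising",
                       "stabilising")   # coil fully mispredicted
  sm <- stratifiedMetrics(truth, pred, stratify(ds, ann))
  helixRow <- sm[sm$stratum == "helix", ]
  coilRow <- sm[sm$stratum == "coil", ]
  expect_equal(helixRow$mcc, 1)
  expect_equal(coilRow$mcc, -1)
  expect_lt(coilRow$mcc, helixRow$mcc)
  # single-class strata are flagged and use the MCC-zero convention
  sm2 <- stratifiedMetrics(rep("stabilising", 6), truth[1:6],
                           data.frame(all = rep("x", 6)))
  expect_true(sm2$single_class)
  expect_equal(sm2$mcc, 0)
})
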