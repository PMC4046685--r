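## RBF-kernel support vector classification and regression (via libsvm
## through e1071), the dyadic grid-search protocol scored by pooled
## cross-validated MCC / RMSE, and the replicated train/evaluate
## workflow.

.TASKS <- c("classification", "regression")

#' The default hyperparameter grids
#'
#' Classification: all combinations of C in 2^{-5, -3, ..., 15} (11
#' values), gamma in 2^{-15, -13, ..., 1} (9 values), and positive-class
#' weight w in {1, 1.5, 2, 2.5, 3} — 495 candidates.  Regression: C in
#' 2^{-1, 0, ..., 6} (8), gamma in 2^{-15, -14, ..., 0} (16), epsilon in
#' 2^{-8, -7, ..., -1} (8) — 1024 candidates.  Rows are ordered by C,
#' then gamma, then w/epsilon, which is also the tie-break order of
#' [gridSearch()].
#'
#' @param task `"classification"` or `"regression"`.
#' @return data.frame of candidate parameter rows.
#' @export
defaultGrid <- function(task = .TASKS) {
  task <- match.arg(task)
  if (task == "classification") {
    g <- expand.grid(w = c(1, 1.5, 2, 2.5, 3),
                     gamma = 2^seq(-15, 1, by = 2),
                     C = 2^seq(-5, 15, by = 2))
    g <- g[order(g$C, g$gamma, g$w), c("C", "gamma", "w")]
  } else {
    g <- expand.grid(epsilon = 2^seq(-8, -1),
                     gamma = 2^seq(-15, 0),
                     C = 2^seq(-1, 6))
    g <- g[order(g$C, g$gamma, g$epsilon), c("C", "gamma", "epsilon")]
  }
  rownames(g) <- NULL
  g
}

#' A coarse grid for scaled-down experiments
#'
#' Four candidates spanning the interesting C/gamma region, used by the
#' synthetic leakage demonstration and other desk-scale runs where the
#' full 495/1024-point scan is unnecessary.
#'
#' @inheritParams defaultGrid
#' @return data.frame of candidate parameter rows.
#' @export
compactGrid <- function(task = .TASKS) {
  task <- match.arg(task)
  if (task == "classification") {
    g <- expand.grid(w = c(1, 3), gamma = 2^c(-7, -3), C = c(1, 32))
    g[order(g$C, g$gamma, g$w), c("C", "gamma", "w")]
  } else {
    g <- expand.grid(epsilon = 2^-3, gamma = 2^c(-7, -3), C = c(1, 32))
    g[order(g$C, g$gamma, g$epsilon), c("C", "gamma", "epsilon")]
  }
}

.fitScaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

.applyScaler <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

#' Fit an RBF-kernel SVM with standardised features
#'
#' Features are standardised per dimension (centre and unit variance,
#' fitted on the training data only; constant dimensions are left
#' unscaled) before kernel evaluation, and the scaling is stored as part
#' of the model.  Classification uses a penalty weight `w` on the
#' positive (stabilising) class; regression is epsilon-insensitive.
#'
#' @param x numeric feature matrix (rows = records).
#' @param y labels (`"stabilising"`/`"destabilising"`) or ddGu values.
#' @param params one-row data.frame with `C`, `gamma`, and `w`
#'   (classification) or `epsilon` (regression), e.g. a row of
#'   [defaultGrid()].
#' @param task `"classification"` or `"regression"`.
#' @param encoder encoder id recorded on the model.
#' @return a [StabilityModel-class].
#' @export
trainModel <- function(x, y, params, task = .TASKS, encoder = "custom") {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y disagree in length")
  sc <- .fitScaler(x)
  xs <- .applyScaler(x, sc$center, sc$scale)
  if (task == "classification") {
    .checkLabels(y)
    if (length(unique(y)) < 2L)
      stop("classification training data must contain both classes")
    yf <- factor(y, levels = c(.POS, .NEG))
    fit <- e1071::svm(xs, yf, type = "C-classification", kernel = "radial",
                      cost = params$C, gamma = params$gamma,
                      class.weights = setNames(c(params$w, 1), c(.POS, .NEG)),
                      scale = FALSE)
  } else {
    y <- as.numeric(y)
    fit <- if (sd(y) == 0) {
      # degenerate constant target: every point lies inside the epsilon
      # tube, so the solution is the constant itself
      structure(list(constant = y[1]), class = "mutstabConstantFit")
    } else {
      e1071::svm(xs, y, type = "eps-regression",
                 kernel = "radial", cost = params$C,
                 gamma = params$gamma, epsilon = params$epsilon,
                 scale = FALSE)
    }
  }
  new("StabilityModel", fit = fit, task = task,
      params = as.data.frame(params), center = sc$center, scale = sc$scale,
      encoder = encoder,
      fingerprint = sprintf("n=%d d=%d sum=%.6g", nrow(x), ncol(x), sum(x)))
}

#' Predict stability changes with a fitted model
#'
#' @param model a [StabilityModel-class].
#' @param x feature matrix with the training dimensionality.
#' @return classification: data.frame with `score` (signed decision
#'   value, positive means stabilising) and `label`; regression: numeric
#'   vector of predicted ddGu.
#' @export
predictModel <- function(model, x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) {
    return(if (model@task == "classification")
      data.frame(score = numeric(), label = character()) else numeric())
  }
  if (ncol(x) != length(model@center))
    stop("feature dimensionality (", ncol(x), ") differs from training (",
         length(model@center), ")")
  xs <- .applyScaler(x, model@center, model@scale)
  if (model@task == "classification") {
    pred <- predict(model@fit, xs, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    score <- dv[, 1]
    # libsvm reports the decision value for the first-named class of the
    # column label; orient so that positive always means stabilising
    if (!startsWith(colnames(dv)[1], .POS)) score <- -score
    data.frame(score = unname(score),
               label = ifelse(score >= 0, .POS, .NEG),
               stringsAsFactors = FALSE)
  } else if (inherits(model@fit, "mutstabConstantFit")) {
    rep(model@fit$constant, nrow(xs))
  } else {
    unname(predict(model@fit, xs))
  }
}

#' Grid search by pooled cross-validated MCC or RMSE
#'
#' For every candidate parameter row, trains on k-1 folds and predicts
#' the held-out fold, pools the held-out predictions over all folds into
#' one confusion matrix (classification) or residual vector
#' (regression), and scores the pool.  The winner maximises MCC or
#' minimises RMSE; ties are broken towards smaller C, then gamma, then
#' w/epsilon (the grids are ordered that way).  Candidates whose fit
#' fails on some fold are scored `NA`.
#'
#' @param x feature matrix.
#' @param y labels or ddGu values.
#' @param folds integer fold id per row of `x`.
#' @param task `"classification"` or `"regression"`.
#' @param grid candidate rows (default [defaultGrid()]).
#' @return list with `best` (the winning row) and `scores` (the grid
#'   with a `score` column).
#' @export
gridSearch <- function(x, y, folds, task = .TASKS, grid = defaultGrid(task)) {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (length(folds) != nrow(x)) stop("folds must cover the training records")
  scores <- rep(NA_real_, nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    params <- grid[ci, , drop = FALSE]
    pooledPred <- rep(if (task == "classification") NA_character_ else NA_real_,
                      length(y))
    ok <- TRUE
    for (f in unique(folds)) {
      inTrain <- folds != f
      fitted <- tryCatch(
        trainModel(x[inTrain, , drop = FALSE], y[inTrain], params, task),
        error = function(e) NULL)
      if (is.null(fitted)) { ok <- FALSE; break }
      p <- predictModel(fitted, x[!inTrain, , drop = FALSE])
      pooledPred[!inTrain] <- if (task == "classification") p$label else p
    }
    if (!ok) next
    scores[ci] <- if (task == "classification")
      classificationMetrics(confusionCounts(y, pooledPred))[["mcc"]]
    else
      regressionMetrics(pooledPred, y)[["rmse"]]
  }
  if (all(is.na(scores))) stop("all grid candidates failed")
  ## winner is independent of candidate enumeration order: ties break
  ## towards smaller C, then gamma, then w/epsilon
  third <- grid[[setdiff(colnames(grid), c("C", "gamma"))[1]]]
  canon <- order(grid$C, grid$gamma, third)
  sc <- scores[canon]
  bestPos <- if (task == "classification") which(sc == max(sc, na.rm = TRUE))
             else which(sc == min(sc, na.rm = TRUE))
  best <- canon[bestPos[1]]
  out <- grid; out$score <- scores
  list(best = grid[best, , drop = FALSE], scores = out)
}

.evaluatePlan <- function(x, y, plan, task, grid, k) {
  train <- trainIds(plan); test <- testIds(plan)
  foldVec <- foldAssignments(plan)[as.character(train)]
  gs <- gridSearch(x[train, , drop = FALSE], y[train], foldVec, task, grid)
  model <- trainModel(x[train, , drop = FALSE], y[train], gs$best, task)
  pred <- predictModel(model, x[test, , drop = FALSE])
  if (task == "classification") {
    m <- classificationMetrics(confusionCounts(y[test], pred$label))
    auc <- if (length(unique(y[test])) == 2L) rocAuc(pred$score, y[test])$auc
           else NA_real_
    metrics <- c(m, auc = auc, n = length(test))
  } else {
    metrics <- c(regressionMetrics(pred, y[test]), n = length(test))
  }
  list(metrics = metrics, best = gs$best, model = model, predictions = pred)
}

#' Replicated homology-aware training and evaluation
#'
#' Runs the full protocol R times: draw a train/test split under
#' `scheme`, build k cross-validation folds under `foldScheme`, grid
#' search on the folds, re-train on the whole training set with the
#' winning parameters, and evaluate on the independent test set.
#' Per-replicate metrics are averaged arithmetically.
#'
#' @param dataset a labelled [MutationDataset-class].
#' @param clustering a [HomologyClustering-class].
#' @param encoder feature encoder id (see [encodeFeatures()]) or a
#'   pre-computed feature matrix.
#' @param scheme evaluation scheme for the train/test split.
#' @param foldScheme scheme for the cross-validation folds.
#' @param task `"classification"` or `"regression"`.
#' @param R number of replicates (default 10).
#' @param k cross-validation folds (default 10).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param grid hyperparameter candidates.
#' @param annotations,profiles feature inputs for the encoders that need
#'   them.
#' @return list with `perReplicate` (data.frame, one row per replicate),
#'   `aggregate` (mean of each metric), and `plans` (the SplitPlans).
#' @export
runReplicates <- function(dataset, clustering, encoder = "easeAA",
                          scheme = .SCHEMES, foldScheme = scheme,
                          task = .TASKS, R = 10L, k = 10L, seed = 1L,
                          grid = NULL, annotations = NULL, profiles = NULL) {
  scheme <- match.arg(scheme, .SCHEMES)
  foldScheme <- match.arg(foldScheme, .SCHEMES)
  task <- match.arg(task)
  if (is.null(grid)) grid <- defaultGrid(task)
  x <- if (is.matrix(encoder)) encoder
       else encodeFeatures(dataset, annotations, profiles, encoder)
  encName <- if (is.matrix(encoder)) "precomputed" else encoder
  rec <- records(dataset)
  y <- if (task == "classification") rec$label else rec$ddg
  perRep <- list(); plans <- list()
  for (r in seq_len(R)) {
    plan <- makeTrainTest(dataset, clustering, scheme,
                          seed = as.integer(seed) + r, replicate = r)
    plan <- makeCvFolds(plan, dataset, clustering, foldScheme, k)
    ev <- .evaluatePlan(x, y, plan, task, grid, k)
    perRep[[r]] <- data.frame(replicate = r, t(ev$metrics))
    plans[[r]] <- plan
  }
  perReplicate <- do.call(rbind, perRep)
  agg <- colMeans(perReplicate[, setdiff(colnames(perReplicate), "replicate"),
                               drop = FALSE], na.rm = TRUE)
  list(perReplicate = perReplicate, aggregate = agg, plans = plans,
       encoder = encName, scheme = scheme, foldScheme = foldScheme,
       task = task)
}

#' Paired t-test between two replicated runs
#'
#' Two-sided paired t-test across replicates for runs that share their
#' splits (same seeds and scheme).  With fewer than two replicates, or
#' when the two runs are metrically identical on every replicate, no
#' t-statistic exists; the p-value is then reported as `NA` or 1
#' respectively.
#'
#' @param runA,runB results from [runReplicates()].
#' @param metric metric column to compare (e.g. `"mcc"`, `"auc"`, `"r"`).
#' @return list with `estimate` (mean difference A - B) and `p.value`.
#' @export
comparePerformance <- function(runA, runB, metric = "mcc") {
  a <- runA$perReplicate[[metric]]; b <- runB$perReplicate[[metric]]
  if (is.null(a) || is.null(b) || length(a) != length(b))
    stop("runs do not share a replicate structure for metric ", metric)
  d <- a - b
  if (length(d) < 2L) return(list(estimate = mean(d), p.value = NA_real_))
  if (all(abs(d - mean(d)) < 1e-12)) {
    p <- if (abs(mean(d)) < 1e-12) 1 else 0
    return(list(estimate = mean(d), p.value = p))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(estimate = unname(tt$estimate), p.value = tt$p.value)
}
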