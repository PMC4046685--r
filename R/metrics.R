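## Evaluation measures: confusion counts, MCC/Q2/Se/Sp/PPV/NPV, ROC/AUC,
## Pearson r and RMSE, and Figure-style stratification by secondary
## structure, exposure, and stability-change magnitude.  Percent metrics
## are reported on the 0-100 scale; MCC, AUC and r as fractions.

.POS <- "stabilising"
.NEG <- "destabilising"

.checkLabels <- function(labels) {
  if (!all(labels %in% c(.POS, .NEG)))
    stop("labels must be '", .POS, "' or '", .NEG, "'")
}

#' Confusion counts with stabilising as the positive class
#'
#' @param truth,predicted equal-length character vectors of
#'   `"stabilising"` / `"destabilising"`.
#' @return named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusionCounts <- function(truth, predicted) {
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  .checkLabels(truth); .checkLabels(predicted)
  c(TP = sum(truth == .POS & predicted == .POS),
    TN = sum(truth == .NEG & predicted == .NEG),
    FP = sum(truth == .NEG & predicted == .POS),
    FN = sum(truth == .POS & predicted == .NEG))
}

#' Classification measures from confusion counts
#'
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined
#' as 0 when the denominator vanishes; Q2 = (TP+TN)/n, Se = TP/(TP+FN),
#' Sp = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN), all reported as
#' percentages.  A rate with a zero denominator is reported as `NA`
#' (missing), never as 0.
#'
#' @param counts named vector as from [confusionCounts()].
#' @return named numeric vector `c(mcc, q2, se, sp, ppv, npv)`.
#' @export
classificationMetrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion counts")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  mcc <- min(1, max(-1, mcc))   # guard against floating-point overshoot
  c(mcc = mcc,
    q2 = 100 * (tp + tn) / total,
    se = rate(tp, tp + fn),
    sp = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn))
}

#' ROC curve and area under it
#'
#' The curve sweeps all distinct score thresholds (higher score means
#' more stabilising); AUC is computed by rank statistics with ties
#' contributing half-concordance, so it equals the Mann-Whitney
#' statistic and trapezoidal integration of the curve.
#'
#' @param scores numeric decision scores.
#' @param truth labels (`"stabilising"` positive).
#' @return list with `curve` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
rocAuc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  .checkLabels(truth)
  pos <- truth == .POS
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tie group
  tpr <- cumsum(p)[keep] / nP
  fpr <- cumsum(!p)[keep] / nN
  list(curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)), auc = auc)
}

#' Pearson correlation and root mean square error
#'
#' @param predicted,observed equal-length numeric vectors (n >= 2).
#' @return named vector `c(r, rmse)`; `r` is `NA` when the observed
#'   values have zero variance.
#' @export
regressionMetrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least two observations")
  rmse <- sqrt(mean((predicted - observed)^2))
  r <- if (sd(observed) > 0 && sd(predicted) > 0)
    cor(predicted, observed) else NA_real_
  c(r = r, rmse = rmse)
}

#' Stratify records by structure, exposure, and magnitude
#'
#' Three orthogonal stratum labels per record: the predicted secondary
#' structure type; `exposed` when relative ASA >= 0.25 (else `buried`);
#' and `small` when ddGu lies in [-1, 1] kcal/mol (else `large`).
#' Records lacking an annotation get `NA` in the affected stratification.
#'
#' @param dataset a [MutationDataset-class].
#' @param annotations per-record annotation data.frame (columns `ss`,
#'   `asa`).
#' @return data.frame with columns `ss`, `exposure`, `magnitude`.
#' @export
stratify <- function(dataset, annotations) {
  rec <- records(dataset)
  if (nrow(annotations) != nrow(rec))
    stop("one annotation row per record required")
  data.frame(ss = ifelse(annotations$ss %in% .SS_TYPES, annotations$ss,
                         NA_character_),
             exposure = ifelse(is.na(annotations$asa), NA_character_,
                               ifelse(annotations$asa >= 0.25,
                                      "exposed", "buried")),
             magnitude = ifelse(is.na(rec$ddg), NA_character_,
                                ifelse(abs(rec$ddg) <= 1, "small", "large")),
             stringsAsFactors = FALSE)
}

#' Classification metrics within each stratum
#'
#' @param truth,predicted label vectors aligned with the records.
#' @param strata data.frame from [stratify()].
#' @return data.frame with one row per (stratification, stratum):
#'   metrics from [classificationMetrics()], the stratum size `n`, and
#'   `single_class` flagging strata whose truth holds only one class
#'   (their MCC is 0 by the zero-denominator convention).  Empty strata
#'   are omitted; records with a missing stratum are skipped and counted
#'   in `n_missing`.
#' @export
stratifiedMetrics <- function(truth, predicted, strata) {
  if (length(truth) != nrow(strata)) stop("length mismatch")
  out <- list()
  for (col in colnames(strata)) {
    v <- strata[[col]]
    for (lev in unique(v[!is.na(v)])) {
      idx <- which(!is.na(v) & v == lev)
      m <- classificationMetrics(confusionCounts(truth[idx], predicted[idx]))
      out[[length(out) + 1L]] <-
        data.frame(stratification = col, stratum = lev, t(m),
                   n = length(idx), n_missing = sum(is.na(v)),
                   single_class = length(unique(truth[idx])) == 1L)
    }
  }
  if (!length(out))
    return(data.frame(stratification = character(), stratum = character()))
  do.call(rbind, out)
}
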