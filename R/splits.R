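## Scheme-aware train/test splits and cross-validation folds for the
## unseen-mutation, unseen-residue, and unseen-protein evaluations.

.SCHEMES <- c("unseen_mutation", "unseen_residue", "unseen_protein")

## run expr with a private RNG stream seeded by `seed`
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed))
  expr
}

## unit key per record for a scheme
.unitKeys <- function(dataset, clustering, scheme) {
  rec <- records(dataset)
  switch(scheme,
         unseen_mutation = as.character(seq_len(nrow(rec))),
         unseen_residue = {
           k <- residueGroupKeys(dataset, clustering)
           paste(k$cluster_id, k$mapped_position)
         },
         unseen_protein = {
           cl <- unname(clusterAssignments(clustering)[rec$protein_id])
           if (anyNA(cl)) stop("clustering does not cover all proteins")
           cl
         },
         stop("unknown scheme: ", scheme))
}

## Greedy allocation of atomic units to sides:  units are shuffled, then
## each is assigned to the side with the largest remaining per-class
## deficit relative to its targets.  Deterministic given the RNG state.
.allocateUnits <- function(unitKey, isPos, targets) {
  units <- split(seq_along(unitKey), unitKey)
  ord <- sample(length(units))
  sides <- names(targets)
  got <- lapply(targets, function(t) c(pos = 0, neg = 0))
  assignment <- character(length(units))
  names(assignment) <- names(units)
  for (u in ord) {
    idx <- units[[u]]
    nPos <- sum(isPos[idx]); nNeg <- length(idx) - nPos
    score <- vapply(sides, function(s) {
      tg <- targets[[s]]; cur <- got[[s]]
      dPos <- (tg["pos"] - cur["pos"]) / max(tg["pos"], 1)
      dNeg <- (tg["neg"] - cur["neg"]) / max(tg["neg"], 1)
      (dPos * nPos + dNeg * nNeg) / (nPos + nNeg)
    }, 1)
    best <- sides[which.max(score)]
    got[[best]] <- got[[best]] + c(pos = nPos, neg = nNeg)
    assignment[names(units)[u]] <- best
  }
  assignment
}

#' Draw one train/test split under an evaluation scheme
#'
#' Splits the dataset into training and independent test sets at a
#' target 2:1 record-count ratio, keeping the stabilising/destabilising
#' ratio of the test set close to the dataset's.  The atomic unit that
#' may never straddle the two sides is the individual mutation
#' (`unseen_mutation`), the alignment-mapped residue position shared
#' across homologues (`unseen_residue`), or the whole homology cluster
#' (`unseen_protein`).  Units are shuffled with the given seed and
#' assigned greedily to the side with the larger remaining deficit, so
#' the plan is deterministic for a fixed seed.
#'
#' @param dataset a labelled [MutationDataset-class].
#' @param clustering a [HomologyClustering-class] (required for the
#'   residue and protein schemes).
#' @param scheme one of `"unseen_mutation"`, `"unseen_residue"`,
#'   `"unseen_protein"`.
#' @param seed integer RNG seed.
#' @param trainFraction target fraction of records in the training set
#'   (default 2/3).
#' @param replicate replicate number stored on the plan.
#' @return a [SplitPlan-class].
#' @export
makeTrainTest <- function(dataset, clustering = NULL, scheme = .SCHEMES,
                          seed, trainFraction = 2 / 3, replicate = 1L) {
  scheme <- match.arg(scheme)
  rec <- records(dataset)
  if (!nrow(rec)) stop("empty dataset")
  if (anyNA(rec$label)) stop("dataset must be labelled")
  if (scheme != "unseen_mutation" && is.null(clustering))
    stop("scheme '", scheme, "' requires a clustering")
  unitKey <- .unitKeys(dataset, clustering, scheme)
  isPos <- rec$label == "stabilising"
  n <- nrow(rec); nPos <- sum(isPos); nNeg <- n - nPos
  targets <- list(train = c(pos = trainFraction * nPos, neg = trainFraction * nNeg),
                  test = c(pos = (1 - trainFraction) * nPos,
                           neg = (1 - trainFraction) * nNeg))
  biggest <- max(table(unitKey))
  if (biggest > (1 - trainFraction) * n)
    warning("an atomic unit is larger than the test budget; ",
            "split is best-effort")
  assignment <- .withSeed(seed, .allocateUnits(unitKey, isPos, targets))
  side <- assignment[unitKey]
  new("SplitPlan", scheme = scheme, foldScheme = NA_character_,
      replicate = as.integer(replicate), seed = as.integer(seed),
      trainIds = unname(which(side == "train")),
      testIds = unname(which(side == "test")),
      foldOf = integer())
}

#' Assign cross-validation folds to a plan's training records
#'
#' The fold scheme may differ from the plan's train/test scheme (both
#' combinations are meaningful: optimising with unseen-mutation folds
#' while testing on unseen proteins exposes over-fitting).  Atomic units
#' are as in [makeTrainTest()]; units are shuffled and assigned greedily
#' to the fold with the largest per-class deficit, so every fold is
#' non-empty and class ratios stay close to the training set's.
#'
#' @param plan a [SplitPlan-class] from [makeTrainTest()].
#' @param dataset,clustering as in [makeTrainTest()].
#' @param foldScheme scheme governing fold membership.
#' @param k number of folds (default 10).
#' @return the plan with `foldOf` populated.
#' @export
makeCvFolds <- function(plan, dataset, clustering = NULL,
                        foldScheme = .SCHEMES, k = 10L) {
  foldScheme <- match.arg(foldScheme)
  rec <- records(dataset)
  train <- trainIds(plan)
  if (!length(train)) stop("plan has no training records")
  unitKeyAll <- .unitKeys(dataset, clustering, foldScheme)
  unitKey <- unitKeyAll[train]
  nUnits <- length(unique(unitKey))
  if (k > nUnits)
    stop("k = ", k, " exceeds the number of atomic units (", nUnits, ")")
  isPos <- rec$label[train] == "stabilising"
  nPos <- sum(isPos); nNeg <- length(train) - nPos
  targets <- setNames(lapply(seq_len(k), function(f)
    c(pos = nPos / k, neg = nNeg / k)), paste0("fold", seq_len(k)))
  assignment <- .withSeed(plan@seed + 104729L,
                          .allocateUnits(unitKey, isPos, targets))
  foldOf <- match(assignment[unitKey], names(targets))
  names(foldOf) <- as.character(train)
  methods::initialize(plan, foldScheme = foldScheme,
                      foldOf = setNames(as.integer(foldOf), names(foldOf)))
}

#' Check a split plan for train/test or fold leakage
#'
#' Recomputes the atomic units of the declared (or an overriding) scheme
#' and reports every unit that appears on both sides of the train/test
#' split, and every unit that spans more than one cross-validation fold.
#' An empty result means the plan satisfies the scheme.
#'
#' @param plan a [SplitPlan-class].
#' @param dataset,clustering as in [makeTrainTest()].
#' @param scheme scheme whose rules are checked (defaults to the plan's
#'   own; passing a stricter scheme tests the strictness ordering).
#' @param foldScheme scheme checked at fold level (defaults to the
#'   plan's own fold scheme when folds exist).
#' @return data.frame of violations with columns `unit` and `where`
#'   (`"train/test"` or `"folds"`); zero rows when the plan is clean.
#' @export
verifyNoLeakage <- function(plan, dataset, clustering = NULL,
                            scheme = plan@scheme,
                            foldScheme = plan@foldScheme) {
  viol <- data.frame(unit = character(), where = character(),
                     stringsAsFactors = FALSE)
  unitKey <- .unitKeys(dataset, clustering, scheme)
  side <- rep(NA_character_, nrow(records(dataset)))
  side[trainIds(plan)] <- "train"
  side[testIds(plan)] <- "test"
  for (u in unique(unitKey)) {
    s <- unique(side[unitKey == u])
    if (length(setdiff(s, NA)) > 1L)
      viol <- rbind(viol, data.frame(unit = u, where = "train/test"))
  }
  if (length(foldAssignments(plan)) && !is.na(foldScheme)) {
    fKey <- .unitKeys(dataset, clustering, foldScheme)
    fold <- foldAssignments(plan)
    tIdx <- as.integer(names(fold))
    for (u in unique(fKey[tIdx])) {
      f <- unique(fold[fKey[tIdx] == u])
      if (length(f) > 1L)
        viol <- rbind(viol, data.frame(unit = u, where = "folds"))
    }
  }
  viol
}
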