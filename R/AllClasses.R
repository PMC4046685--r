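#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats median qnorm rnorm runif sd setNames t.test cor predict
#' @importFrom stats pnorm dnorm var
#' @importFrom utils read.table write.table head
NULL

## 20 standard amino acids, alphabetical one-letter order used throughout.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.recordColumns <- c("protein_id", "wt_aa", "position", "mut_aa",
                    "ddg", "ph", "temperature", "cluster_id", "label")

#' MutationDataset: a table of single-point stability mutations
#'
#' Container for a set of single amino-acid substitutions with measured
#' changes in unfolding free energy (ddGu, kcal/mol), optionally carrying
#' the parent protein sequences and a homology cluster assignment per
#' record.  Row order of the record table is stable and preserved by all
#' operations that do not explicitly subset.
#'
#' @slot records data.frame with columns `protein_id`, `wt_aa`,
#'   `position` (1-based), `mut_aa`, `ddg`, `ph`, `temperature`,
#'   `cluster_id`, `label` (`"stabilising"`/`"destabilising"` or `NA`).
#' @slot proteins [Biostrings::AAStringSet] of parent sequences (possibly
#'   empty); names are protein ids.
#' @slot provenance free-text description of where the records came from.
#'
#' @seealso [readMutationDataset()], [curateDataset()]
#' @export
setClass("MutationDataset",
         representation(records = "data.frame",
                        proteins = "AAStringSet",
                        provenance = "character"))

setValidity("MutationDataset", function(object) {
  rec <- object@records
  msgs <- character()
  missing_cols <- setdiff(.recordColumns, colnames(rec))
  if (length(missing_cols))
    return(paste("records lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(rec)) {
    if (!all(rec$wt_aa %in% AA20) || !all(rec$mut_aa %in% AA20))
      msgs <- c(msgs, "wt_aa and mut_aa must be standard amino-acid letters")
    if (any(rec$wt_aa == rec$mut_aa))
      msgs <- c(msgs, "wild-type and mutant residues must differ")
    if (any(!is.finite(rec$position)) || any(rec$position < 1L))
      msgs <- c(msgs, "positions must be integers >= 1")
    lab <- rec$label[!is.na(rec$label)]
    if (length(lab) && !all(lab %in% c("stabilising", "destabilising")))
      msgs <- c(msgs, "labels must be 'stabilising' or 'destabilising'")
    ok <- !is.na(rec$label)
    if (any(ok)) {
      expect <- ifelse(rec$ddg[ok] >= 0, "stabilising", "destabilising")
      if (!all(rec$label[ok] == expect))
        msgs <- c(msgs, "labels inconsistent with the sign rule (ddg >= 0 is stabilising)")
    }
    if (length(object@proteins)) {
      unresolved <- setdiff(unique(rec$protein_id), names(object@proteins))
      if (length(unresolved))
        msgs <- c(msgs, paste("records reference proteins without sequences:",
                              paste(head(unresolved, 3), collapse = ", ")))
      if (!length(unresolved)) {
        len <- Biostrings::width(object@proteins)[match(rec$protein_id,
                                                        names(object@proteins))]
        if (any(rec$position > len))
          msgs <- c(msgs, "some positions exceed the attached sequence length")
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PSSMProfile: a position-specific scoring matrix for one protein
#'
#' Stores the integer log-odds block of a PSI-BLAST ASCII PSSM.  Scores
#' are always retrieved by residue letter through the stored column
#' order, so a profile parsed from a file with permuted columns is
#' indistinguishable from the canonical layout.
#'
#' @slot proteinId protein identifier.
#' @slot scores integer L x 20 matrix of log-odds scores; column names
#'   equal `columnOrder`.
#' @slot columnOrder the amino-acid ordering of the score columns as
#'   declared in the source file (a permutation of the 20 letters).
#' @slot sequence residue letters of the profile rows (may be `NA` when
#'   the source file carries no residue column).
#' @export
setClass("PSSMProfile",
         representation(proteinId = "character",
                        scores = "matrix",
                        columnOrder = "character",
                        sequence = "character"))

setValidity("PSSMProfile", function(object) {
  if (ncol(object@scores) != 20L)
    return("scores must have exactly 20 columns")
  if (!setequal(object@columnOrder, AA20) || length(object@columnOrder) != 20L)
    return("columnOrder must be a permutation of the 20 amino-acid letters")
  if (!identical(colnames(object@scores), object@columnOrder))
    return("scores column names must equal columnOrder")
  if (any(object@scores != round(object@scores)))
    return("PSSM log-odds scores must be integers")
  TRUE
})

#' HomologyClustering: single-linkage clusters of homologous proteins
#'
#' @slot assignments named character vector, protein id -> cluster id.
#' @slot representatives named character vector, cluster id -> the id of
#'   the representative protein (the longest sequence in the cluster).
#' @slot threshold percent-identity threshold used to draw edges.
#' @export
setClass("HomologyClustering",
         representation(assignments = "character",
                        representatives = "character",
                        threshold = "numeric"))

setValidity("HomologyClustering", function(object) {
  if (is.null(names(object@assignments)) || anyDuplicated(names(object@assignments)))
    return("assignments must be uniquely named by protein id")
  if (!all(object@representatives %in% names(object@assignments)))
    return("representatives must be clustered proteins")
  own <- object@assignments[object@representatives]
  if (!identical(unname(own), names(object@representatives)))
    return("each representative must belong to its own cluster")
  TRUE
})

#' SplitPlan: one replicate of a scheme-aware train/test split
#'
#' Record ids are row indices into the dataset the plan was built from.
#'
#' @slot scheme one of `"unseen_mutation"`, `"unseen_residue"`,
#'   `"unseen_protein"`; governs the atomic unit of the train/test split.
#' @slot foldScheme scheme governing cross-validation folds (may differ
#'   from `scheme`); `NA` until [makeCvFolds()] is called.
#' @slot replicate replicate number.
#' @slot seed RNG seed the plan was drawn with.
#' @slot trainIds,testIds disjoint integer record-id vectors covering the
#'   dataset.
#' @slot foldOf integer vector of fold numbers named by training record
#'   id (empty until folds are made).
#' @export
setClass("SplitPlan",
         representation(scheme = "character",
                        foldScheme = "character",
                        replicate = "integer",
                        seed = "integer",
                        trainIds = "integer",
                        testIds = "integer",
                        foldOf = "integer"))

setValidity("SplitPlan", function(object) {
  if (!object@scheme %in% c("unseen_mutation", "unseen_residue", "unseen_protein"))
    return("unknown scheme")
  if (length(intersect(object@trainIds, object@testIds)))
    return("train and test ids overlap")
  if (length(object@foldOf)) {
    if (!setequal(names(object@foldOf), as.character(object@trainIds)))
      return("foldOf must cover exactly the training ids")
    tab <- table(object@foldOf)
    if (any(tab == 0L)) return("every fold must be non-empty")
  }
  TRUE
})

#' StabilityModel: a fitted RBF-kernel SVM with its feature scaling
#'
#' @slot fit the underlying [e1071::svm] object.
#' @slot task `"classification"` or `"regression"`.
#' @slot params the winning hyperparameter row (C, gamma, and w or epsilon).
#' @slot center,scale per-dimension affine scaling fitted on training
#'   data only; applied before kernel evaluation at prediction time.
#' @slot encoder encoder identifier used to build the feature matrix.
#' @slot fingerprint training fingerprint (dimensions, data hash, seed).
#' @export
setClass("StabilityModel",
         representation(fit = "ANY",
                        task = "character",
                        params = "data.frame",
                        center = "numeric",
                        scale = "numeric",
                        encoder = "character",
                        fingerprint = "character"))

#' SyntheticConfig: parameters of the synthetic benchmark generator
#'
#' Defaults mirror the statistical structure of curated experimental
#' stability data: 78% of mutations in a multi-record protein agree with
#' the protein's prevailing sign and 74% of all mutations are
#' destabilising.
#'
#' @slot nClusters,proteinsPerCluster,seqLength,mutationsPerProtein
#'   problem-size counts.
#' @slot signAgreement target within-protein sign agreement in [0.5, 1].
#' @slot residueAgreement target within-residue sign agreement in
#'   [0.5, 1]; must be at least `signAgreement` (mutations of one site
#'   are at least as correlated as mutations of one protein).
#' @slot fracDestabilising target overall fraction of destabilising
#'   mutations.
#' @slot signalWeights length-14 linear effect of the EASE-AA feature
#'   vector on ddGu (kcal/mol per feature unit).
#' @slot noiseSd residual standard deviation, kcal/mol.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticConfig",
         representation(nClusters = "integer",
                        proteinsPerCluster = "integer",
                        seqLength = "integer",
                        mutationsPerProtein = "integer",
                        signAgreement = "numeric",
                        residueAgreement = "numeric",
                        fracDestabilising = "numeric",
                        signalWeights = "numeric",
                        noiseSd = "numeric",
                        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (any(c(object@nClusters, object@proteinsPerCluster, object@seqLength,
            object@mutationsPerProtein) < 1L))
    return("all counts must be >= 1")
  if (object@signAgreement < 0.5 || object@signAgreement > 1)
    return("signAgreement must lie in [0.5, 1]")
  if (object@residueAgreement < object@signAgreement ||
      object@residueAgreement > 1)
    return("residueAgreement must lie in [signAgreement, 1]")
  if (object@fracDestabilising < 0 || object@fracDestabilising > 1)
    return("fracDestabilising must lie in [0, 1]")
  if (length(object@signalWeights) != 14L)
    return("signalWeights must have length 14 (EASE-AA layout)")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  TRUE
})

setMethod("show", "MutationDataset", function(object) {
  cat(sprintf("MutationDataset with %d records in %d proteins (%d sequences attached)\n",
              nrow(object@records), length(unique(object@records$protein_id)),
              length(object@proteins)))
  if (nzchar(object@provenance))
    cat("provenance:", object@provenance, "\n")
  n_lab <- sum(!is.na(object@records$label))
  if (n_lab)
    cat(sprintf("labelled: %d (%.1f%% destabilising)\n", n_lab,
                100 * mean(object@records$label == "destabilising", na.rm = TRUE)))
})

setMethod("show", "PSSMProfile", function(object) {
  cat(sprintf("PSSMProfile '%s': %d positions x 20 residues (scores %d..%d)\n",
              object@proteinId, nrow(object@scores),
              min(object@scores), max(object@scores)))
})

setMethod("show", "HomologyClustering", function(object) {
  cat(sprintf("HomologyClustering: %d proteins in %d clusters (threshold %g%% identity)\n",
              length(object@assignments), length(object@representatives),
              object@threshold))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan [%s] replicate %d (seed %d): %d train / %d test",
              object@scheme, object@replicate, object@seed,
              length(object@trainIds), length(object@testIds)))
  if (length(object@foldOf))
    cat(sprintf(", %d folds [%s]", max(object@foldOf), object@foldScheme))
  cat("\n")
})

setMethod("show", "StabilityModel", function(object) {
  cat(sprintf("StabilityModel (%s, encoder %s): C=%g gamma=%g%s\n",
              object@task, object@encoder,
              object@params$C, object@params$gamma,
              if (object@task == "classification")
                sprintf(" w=%g", object@params$w)
              else sprintf(" eps=%g", object@params$epsilon)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: %d clusters x %d proteins x %d mutations ",
                     "(L=%d), agreement %.2f, %.0f%% destabilising, seed %d\n"),
              object@nClusters, object@proteinsPerCluster,
              object@mutationsPerProtein, object@seqLength,
              object@signAgreement, 100 * object@fracDestabilising, object@seed))
})
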