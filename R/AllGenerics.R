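#' Accessors for mutstab S4 containers
#'
#' Small accessor generics in the Bioconductor style: use these instead
#' of reaching into slots.
#'
#' @param x a mutstab S4 object.
#' @return `records()` the record data.frame; `proteins()` an
#'   `AAStringSet`; `provenance()` a character scalar;
#'   `clusterAssignments()` / `clusterRepresentatives()` named character
#'   vectors; `trainIds()` / `testIds()` integer record ids;
#'   `foldAssignments()` a named integer vector; `pssmScores()` the
#'   integer score matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("clusterRepresentatives",
           function(x) standardGeneric("clusterRepresentatives"))
#' @rdname accessors
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))
#' @rdname accessors
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))
#' @rdname accessors
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))
#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))

#' @rdname accessors
setMethod("records", "MutationDataset", function(x) x@records)
#' @rdname accessors
setMethod("proteins", "MutationDataset", function(x) x@proteins)
#' @rdname accessors
setMethod("provenance", "MutationDataset", function(x) x@provenance)
#' @rdname accessors
setMethod("clusterAssignments", "HomologyClustering", function(x) x@assignments)
#' @rdname accessors
setMethod("clusterRepresentatives", "HomologyClustering",
          function(x) x@representatives)
#' @rdname accessors
setMethod("trainIds", "SplitPlan", function(x) x@trainIds)
#' @rdname accessors
setMethod("testIds", "SplitPlan", function(x) x@testIds)
#' @rdname accessors
setMethod("foldAssignments", "SplitPlan", function(x) x@foldOf)
#' @rdname accessors
setMethod("pssmScores", "PSSMProfile", function(x) x@scores)
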