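## Pairwise sequence identity, single-linkage clustering at a 25%
## threshold (a reproducible stand-in for BLASTCLUST), and the
## alignment-mapped residue keys that define the unseen-residue scheme.

.identityMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      mm <- matrix(0L, 20L, 20L, dimnames = list(AA20, AA20))
      diag(mm) <- 1L
      m <<- mm
    }
    m
  }
})

.alignPair <- function(a, b, gapOpening = 5, gapExtension = 1) {
  Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                substitutionMatrix = .identityMatrix(),
                                gapOpening = gapOpening,
                                gapExtension = gapExtension,
                                type = "global")
}

#' Percent sequence identity under global alignment
#'
#' Identity is the number of identical aligned letters over the full
#' alignment length (gap columns included), times 100.  The alignment is
#' global (Needleman-Wunsch) with match +1, mismatch 0, gap open -5, gap
#' extend -1 — parameters chosen for determinism, not to mimic BLAST
#' bitscores.
#'
#' @param a,b amino-acid sequences (character scalars or `AAString`).
#' @param gapOpening,gapExtension positive gap penalties.
#' @return percent identity in [0, 100]; symmetric in its arguments.
#' @export
pairwiseIdentity <- function(a, b, gapOpening = 5, gapExtension = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  pa <- .alignPair(a, b, gapOpening, gapExtension)
  alnLen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  100 * Biostrings::nmatch(pa) / alnLen
}

#' Single-linkage homology clustering at an identity threshold
#'
#' Proteins are joined whenever their pairwise identity exceeds
#' `threshold`; clusters are the transitive closure (connected
#' components) of that graph.  The representative of a cluster is its
#' longest sequence, ties broken by lexicographic id.  Cluster ids are
#' `C1`, `C2`, ... in order of first appearance.
#'
#' @param sequences a named [Biostrings::AAStringSet].
#' @param threshold percent identity above which an edge is drawn
#'   (default 25).
#' @return a [HomologyClustering-class].
#' @export
clusterSequences <- function(sequences, threshold = 25) {
  n <- length(sequences)
  if (!n) stop("at least one sequence is required")
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences must be uniquely named")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (find(i) == find(j)) next
      if (pairwiseIdentity(sequences[[i]], sequences[[j]]) > threshold)
        parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  clusterId <- paste0("C", match(root, unique(root)))
  assignments <- setNames(clusterId, ids)
  reps <- vapply(split(seq_len(n), clusterId), function(members) {
    w <- Biostrings::width(sequences)[members]
    ord <- order(-w, ids[members])
    ids[members[ord[1]]]
  }, "")
  reps <- reps[unique(clusterId)]
  new("HomologyClustering", assignments = assignments,
      representatives = reps, threshold = threshold)
}

## Map positions of one protein onto its cluster representative's
## coordinates through the global alignment; returns a function of
## position for caching.
.positionMapper <- function(seqProt, seqRep) {
  if (identical(as.character(seqProt), as.character(seqRep)))
    return(function(pos) list(pos = pos, mapped = TRUE))
  pa <- .alignPair(as.character(seqProt), as.character(seqRep))
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  pPos <- cumsum(p != "-")
  sPos <- cumsum(s != "-")
  function(pos) {
    col <- match(pos, pPos * (p != "-"))
    if (is.na(col) || s[col] == "-")
      list(pos = pos, mapped = FALSE)   # falls back to the raw position
    else
      list(pos = sPos[col], mapped = TRUE)
  }
}

#' Residue-group keys for the unseen-residue scheme
#'
#' Each record's position is mapped into the coordinate system of its
#' cluster representative via the same global alignment that defines
#' [pairwiseIdentity()], so that the same residue of two homologues
#' shares one key.  When the position aligns to a gap in the
#' representative (or no sequences are attached), the raw position is
#' used and flagged unmapped.
#'
#' @param dataset a [MutationDataset-class].
#' @param clustering a [HomologyClustering-class].
#' @return data.frame with one row per record: `cluster_id`,
#'   `mapped_position`, `mapped` (logical).
#' @export
residueGroupKeys <- function(dataset, clustering) {
  rec <- records(dataset)
  seqs <- proteins(dataset)
  asg <- clusterAssignments(clustering)
  reps <- clusterRepresentatives(clustering)
  cl <- unname(asg[rec$protein_id])
  if (anyNA(cl))
    stop("clustering does not cover protein(s): ",
         paste(unique(rec$protein_id[is.na(cl)]), collapse = ", "))
  mapped_position <- rec$position
  mapped <- rep(FALSE, nrow(rec))
  if (length(seqs)) {
    mappers <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(rec))) {
      pid <- rec$protein_id[i]
      rid <- reps[cl[i]]
      if (!pid %in% names(seqs) || !rid %in% names(seqs)) next
      if (rec$position[i] > Biostrings::width(seqs)[match(pid, names(seqs))])
        stop("position beyond sequence length for record ", i)
      if (is.null(mappers[[pid]]))
        mappers[[pid]] <- .positionMapper(seqs[[pid]], seqs[[rid]])
      m <- mappers[[pid]](rec$position[i])
      mapped_position[i] <- m$pos
      mapped[i] <- m$mapped
    }
  }
  data.frame(cluster_id = cl, mapped_position = mapped_position,
             mapped = mapped, stringsAsFactors = FALSE)
}
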