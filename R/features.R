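## Feature encoders: the 14-input EASE-AA vector (S, M, SS, ASA, D, AAP),
## the 145-input EASE variant with neighbour and substitution identity
## one-hots, the SEQ-NEIGHB / SEQ-FREQ baseline encodings, and the
## conservation-versus-stability profile analysis.

## Seven physicochemical amino-acid parameters: steric parameter (graph
## shape index), polarisability, volume, hydrophobicity, isoelectric
## point, helix probability, sheet probability.  Values are the widely
## used seven-parameter representation from secondary-structure
## prediction work; aapTable() rescales each column to [0, 1].
.AAP_RAW <- matrix(c(
  # steric polar  vol   hydro  iso    helixP sheetP
  1.28, 0.05, 1.00,  0.31, 6.11, 0.42, 0.23,  # A
  1.77, 0.13, 2.43,  1.54, 6.35, 0.17, 0.41,  # C
  1.60, 0.11, 2.78, -0.77, 2.95, 0.25, 0.20,  # D
  1.56, 0.15, 3.78, -0.64, 3.09, 0.42, 0.21,  # E
  2.94, 0.29, 5.89,  1.79, 5.67, 0.30, 0.38,  # F
  0.00, 0.00, 0.00,  0.00, 6.07, 0.13, 0.15,  # G
  2.99, 0.23, 4.66,  0.13, 7.69, 0.27, 0.30,  # H
  4.19, 0.19, 4.00,  1.80, 6.04, 0.30, 0.45,  # I
  1.89, 0.22, 4.77, -0.99, 9.99, 0.32, 0.27,  # K
  2.59, 0.19, 4.00,  1.70, 6.04, 0.39, 0.31,  # L
  2.35, 0.22, 4.43,  1.23, 5.71, 0.38, 0.32,  # M
  1.60, 0.13, 2.95, -0.60, 6.52, 0.21, 0.22,  # N
  2.67, 0.00, 2.72,  0.72, 6.80, 0.13, 0.34,  # P
  1.56, 0.18, 3.95, -0.22, 5.65, 0.36, 0.25,  # Q
  2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25, # R
  1.31, 0.06, 1.60, -0.04, 5.70, 0.20, 0.28,  # S
  3.03, 0.11, 2.60,  0.26, 5.60, 0.21, 0.36,  # T
  3.67, 0.14, 3.00,  1.22, 6.02, 0.27, 0.49,  # V
  3.21, 0.41, 8.08,  2.25, 5.94, 0.32, 0.42,  # W
  2.94, 0.30, 6.47,  0.96, 5.66, 0.25, 0.41), # Y
  nrow = 20, byrow = TRUE,
  dimnames = list(AA20, c("steric", "polarisability", "volume",
                          "hydrophobicity", "isoelectric_point",
                          "helix_prob", "sheet_prob")))

.AAP_ORDER <- c("hydrophobicity", "volume", "polarisability",
                "isoelectric_point", "helix_prob", "sheet_prob", "steric")

.SS_TYPES <- c("helix", "sheet", "coil")

#' The packaged amino-acid parameter (AAP) table
#'
#' Returns the 20 x 7 matrix of scaled physicochemical parameters in the
#' order hydrophobicity, volume, polarisability, isoelectric point, helix
#' probability, sheet probability, steric parameter (graph shape index).
#' Each column is min-max scaled to [0, 1].  Any matrix with the same
#' shape, row and column names can be supplied to the encoders instead,
#' so alternative scalings are injectable.
#'
#' @return numeric matrix, rows named by amino-acid letter.
#' @export
aapTable <- function() {
  raw <- .AAP_RAW[, .AAP_ORDER]
  apply(raw, 2, function(v) (v - min(v)) / (max(v) - min(v)))
}

.checkAapTable <- function(table) {
  if (!is.matrix(table) || !identical(dim(table), c(20L, 7L)) ||
      !setequal(rownames(table), AA20) ||
      !identical(colnames(table), .AAP_ORDER))
    stop("AAP table must be 20 x 7 with amino-acid rows and columns ",
         paste(.AAP_ORDER, collapse = ", "))
  invisible(TRUE)
}

#' PSSM-derived mutation and conservation likelihoods
#'
#' The mutation likelihood M is the PSSM log-odds score of the
#' *introduced* residue at the mutation site, divided by 10 so that most
#' values fall within [-1, 1] (outliers are retained, never clipped).
#' The conservation likelihood C applies the same normalisation to the
#' *wild-type* residue's score.
#'
#' @param profile a [PSSMProfile-class].
#' @param position 1-based mutation site.
#' @param mut_aa,wt_aa introduced / deleted residue letters.
#' @return a real number (score / 10).
#' @export
mutationLikelihood <- function(profile, position, mut_aa) {
  scoreAt(profile, position, mut_aa) / 10
}

#' @rdname mutationLikelihood
#' @export
conservationLikelihood <- function(profile, position, wt_aa) {
  scoreAt(profile, position, wt_aa) / 10
}

#' Physicochemical parameter differences for a substitution
#'
#' The AAP feature block: parameters of the introduced residue minus
#' those of the deleted residue, in table column order.
#'
#' @param wt_aa,mut_aa deleted / introduced residue letters.
#' @param table AAP table as from [aapTable()].
#' @return named length-7 numeric vector.
#' @export
aapDifference <- function(wt_aa, mut_aa, table = aapTable()) {
  .checkAapTable(table)
  if (!wt_aa %in% AA20 || !mut_aa %in% AA20)
    stop("non-standard amino-acid letter: ", wt_aa, "/", mut_aa)
  table[mut_aa, ] - table[wt_aa, ]
}

.ssOneHot <- function(ss) {
  if (!ss %in% .SS_TYPES) stop("unknown secondary-structure type: ", ss)
  setNames(as.numeric(.SS_TYPES == ss), paste0("SS_", .SS_TYPES))
}

.aaOneHot <- function(aa, prefix) {
  v <- setNames(numeric(20), paste0(prefix, "_", AA20))
  if (!is.na(aa)) {
    if (aa == "X") stop("residue 'X' is not accepted by feature encoders")
    if (!aa %in% AA20) stop("non-standard residue letter: ", aa)
    v[paste0(prefix, "_", aa)] <- 1
  }
  v
}

## neighbour letters at offsets -window..-1, 1..window; NA past termini
.neighbours <- function(sequence, position, window = 3L) {
  chars <- strsplit(as.character(sequence), "")[[1]]
  if (position < 1L || position > length(chars))
    stop("position beyond sequence length")
  off <- c(-(window:1), 1:window)
  idx <- position + off
  out <- rep(NA_character_, length(off))
  ok <- idx >= 1L & idx <= length(chars)
  out[ok] <- chars[idx[ok]]
  setNames(out, sprintf("n%+d", off))
}

.substitutionBlock <- function(wt_aa, mut_aa) {
  # single 20-vector: -1 at the deleted residue, +1 at the introduced one
  v <- setNames(numeric(20), paste0("sub_", AA20))
  v[paste0("sub_", wt_aa)] <- -1
  v[paste0("sub_", mut_aa)] <- v[paste0("sub_", mut_aa)] + 1
  v
}

#' Encode one mutation with the 14-input EASE-AA feature vector
#'
#' Block layout: S (SIFT score, 1), M (mutation likelihood, 1), SS
#' (secondary-structure one-hot: helix, sheet, coil; 3), ASA (relative
#' accessible surface area, 1), D (disorder probability, 1), AAP
#' (physicochemical parameter differences, 7).
#'
#' @param wt_aa,mut_aa,position the substitution.
#' @param annotation one-row data.frame (or list) with `sift`, `ss`,
#'   `asa`, `disorder`.
#' @param profile the protein's [PSSMProfile-class].
#' @param table AAP table.
#' @return named length-14 numeric vector.
#' @export
encodeEaseAA <- function(wt_aa, mut_aa, position, annotation, profile,
                         table = aapTable()) {
  for (f in c("sift", "ss", "asa", "disorder"))
    if (is.null(annotation[[f]]) || is.na(annotation[[f]]))
      stop("missing annotation feature: ", f)
  c(S = annotation$sift,
    M = mutationLikelihood(profile, position, mut_aa),
    .ssOneHot(annotation$ss),
    ASA = annotation$asa,
    D = annotation$disorder,
    setNames(aapDifference(wt_aa, mut_aa, table), paste0("AAP_", .AAP_ORDER)))
}

#' Encode one mutation with the 145-input EASE feature vector
#'
#' Blocks: S (1), M (1), SS (3), neighbour identities (6 x 20 one-hots
#' for the three residues on each side of the site; windows reaching past
#' a terminus are all-zero), and the substitution identity block (20
#' inputs: -1 at the deleted residue, +1 at the introduced one).
#'
#' @inheritParams encodeEaseAA
#' @param sequence the protein sequence.
#' @param window neighbours on each side (default 3).
#' @return named length-145 numeric vector.
#' @export
encodeEase <- function(wt_aa, mut_aa, position, annotation, profile,
                       sequence, window = 3L) {
  for (f in c("sift", "ss"))
    if (is.null(annotation[[f]]) || is.na(annotation[[f]]))
      stop("missing annotation feature: ", f)
  nb <- .neighbours(sequence, position, window)
  nbBlock <- unlist(lapply(seq_along(nb), function(i)
    .aaOneHot(nb[i], names(nb)[i])))
  c(S = annotation$sift,
    M = mutationLikelihood(profile, position, mut_aa),
    .ssOneHot(annotation$ss),
    nbBlock,
    .substitutionBlock(wt_aa, mut_aa))
}

#' Baseline sequence-only encoders
#'
#' `encodeSeqNeighb()` (140 inputs) uses the amino-acid identities of the
#' six neighbouring residues (6 x 20 one-hots) plus the 20-input
#' substitution identity block.  `encodeSeqFreq()` (40 inputs) uses the
#' occurrence frequencies of the 20 residue types over the six
#' neighbours (counts / 6) plus the substitution block.
#'
#' @inheritParams encodeEase
#' @return named numeric vector of length 140 / 40.
#' @export
encodeSeqNeighb <- function(wt_aa, mut_aa, position, sequence, window = 3L) {
  nb <- .neighbours(sequence, position, window)
  nbBlock <- unlist(lapply(seq_along(nb), function(i)
    .aaOneHot(nb[i], names(nb)[i])))
  c(nbBlock, .substitutionBlock(wt_aa, mut_aa))
}

#' @rdname encodeSeqNeighb
#' @export
encodeSeqFreq <- function(wt_aa, mut_aa, position, sequence, window = 3L) {
  nb <- .neighbours(sequence, position, window)
  nb <- nb[!is.na(nb)]
  if (any(nb == "X")) stop("residue 'X' is not accepted by feature encoders")
  counts <- setNames(numeric(20), paste0("freq_", AA20))
  for (a in nb) counts[paste0("freq_", a)] <- counts[paste0("freq_", a)] + 1
  c(counts / (2L * window), .substitutionBlock(wt_aa, mut_aa))
}

.ENCODERS <- c("easeAA", "ease", "seqNeighb", "seqFreq")

#' Encode every record of a dataset as a feature matrix
#'
#' @param dataset a [MutationDataset-class] (sequences must be attached
#'   for encoders that use the neighbourhood).
#' @param annotations per-record annotation data.frame aligned with the
#'   records (columns `sift`, `ss`, `asa`, `disorder`); not needed for
#'   the sequence-only baselines.
#' @param profiles named list of [PSSMProfile-class] keyed by protein id;
#'   not needed for the baselines.
#' @param encoder one of `"easeAA"` (14 inputs), `"ease"` (145),
#'   `"seqNeighb"` (140), `"seqFreq"` (40).
#' @param table AAP table for `"easeAA"`.
#' @param window neighbourhood half-width.
#' @return numeric matrix, one row per record, with a `"blocks"`
#'   attribute giving the named block sizes of the layout.
#' @export
encodeFeatures <- function(dataset, annotations = NULL, profiles = NULL,
                           encoder = .ENCODERS, table = aapTable(),
                           window = 3L) {
  encoder <- match.arg(encoder)
  rec <- records(dataset)
  seqs <- proteins(dataset)
  needSeq <- encoder != "easeAA"
  if (needSeq && !length(seqs))
    stop("encoder '", encoder, "' requires attached sequences")
  needAnn <- encoder %in% c("easeAA", "ease")
  if (needAnn && (is.null(annotations) || nrow(annotations) != nrow(rec)))
    stop("encoder '", encoder, "' requires one annotation row per record")
  needPssm <- encoder %in% c("easeAA", "ease")
  if (needPssm && is.null(profiles))
    stop("encoder '", encoder, "' requires PSSM profiles")
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    wt <- rec$wt_aa[i]; mut <- rec$mut_aa[i]; pos <- rec$position[i]
    ann <- if (needAnn) annotations[i, , drop = FALSE]
    prof <- if (needPssm) {
      p <- profiles[[rec$protein_id[i]]]
      if (is.null(p)) stop("no PSSM profile for protein ", rec$protein_id[i])
      p
    }
    sq <- if (needSeq) seqs[[rec$protein_id[i]]]
    switch(encoder,
           easeAA = encodeEaseAA(wt, mut, pos, ann, prof, table),
           ease = encodeEase(wt, mut, pos, ann, prof, sq, window),
           seqNeighb = encodeSeqNeighb(wt, mut, pos, sq, window),
           seqFreq = encodeSeqFreq(wt, mut, pos, sq, window))
  })
  x <- do.call(rbind, rows)
  if (is.null(x)) x <- matrix(numeric(), 0L, featureLength(encoder))
  attr(x, "blocks") <- featureBlocks(encoder, window)
  x
}

#' Declared block layouts of the feature encoders
#'
#' @param encoder encoder id.
#' @param window neighbourhood half-width.
#' @return `featureBlocks()`: named integer vector of block sizes;
#'   `featureLength()`: their sum (14, 145, 140, 40 at the default
#'   window).
#' @export
featureBlocks <- function(encoder = .ENCODERS, window = 3L) {
  encoder <- match.arg(encoder)
  nb <- 2L * window
  switch(encoder,
         easeAA = c(S = 1L, M = 1L, SS = 3L, ASA = 1L, D = 1L, AAP = 7L),
         ease = c(S = 1L, M = 1L, SS = 3L, neighbours = nb * 20L,
                  substitution = 20L),
         seqNeighb = c(neighbours = nb * 20L, substitution = 20L),
         seqFreq = c(frequencies = 20L, substitution = 20L))
}

#' @rdname featureBlocks
#' @export
featureLength <- function(encoder = .ENCODERS, window = 3L) {
  sum(featureBlocks(match.arg(encoder), window))
}

#' Median stability change as a function of PSSM score
#'
#' Bins every record by the raw PSSM score of the introduced residue
#' (mutation likelihood, M) and of the wild-type residue (conservation
#' likelihood, C) and reports the per-bin median ddGu.  Empty bins
#' between the observed extremes are reported with `n = 0` and a missing
#' median, so the table is a ready-made monotone-trend profile.
#'
#' @param dataset a [MutationDataset-class].
#' @param profiles named list of [PSSMProfile-class] keyed by protein id.
#' @param binWidth bin width in PSSM score units (default 1).
#' @return data.frame with columns `score_type` (`"mutation"` /
#'   `"conservation"`), `bin` (left edge), `median_ddg`, `n`.
#' @export
conservationStabilityProfile <- function(dataset, profiles, binWidth = 1) {
  rec <- records(dataset)
  if (!nrow(rec))
    return(data.frame(score_type = character(), bin = numeric(),
                      median_ddg = numeric(), n = integer()))
  sc <- vapply(seq_len(nrow(rec)), function(i) {
    p <- profiles[[rec$protein_id[i]]]
    if (is.null(p)) stop("no PSSM profile for protein ", rec$protein_id[i])
    c(scoreAt(p, rec$position[i], rec$mut_aa[i]),
      scoreAt(p, rec$position[i], rec$wt_aa[i]))
  }, numeric(2))
  oneProfile <- function(score, type) {
    b <- floor(score / binWidth) * binWidth
    edges <- seq(min(b), max(b), by = binWidth)
    out <- lapply(edges, function(e) {
      in_bin <- b == e
      data.frame(score_type = type, bin = e,
                 median_ddg = if (any(in_bin)) median(rec$ddg[in_bin]) else NA_real_,
                 n = sum(in_bin))
    })
    do.call(rbind, out)
  }
  rbind(oneProfile(sc[1, ], "mutation"), oneProfile(sc[2, ], "conservation"))
}
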