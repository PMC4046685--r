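## Readers and writers for the tabular mutation dataset, FASTA sequences,
## PSI-BLAST ASCII PSSMs, per-site annotation tables, and cluster tables.
## Writers emit the same dialect the readers accept, so all formats
## round-trip.

#' Construct a MutationDataset from a record table
#'
#' @param records data.frame with at least `protein_id`, `wt_aa`,
#'   `position`, `mut_aa`, `ddg`; optional `ph`, `temperature`,
#'   `cluster_id`, `label` columns are filled with `NA` when absent.
#' @param proteins optional [Biostrings::AAStringSet] named by protein id.
#' @param provenance free-text metadata.
#' @return a [MutationDataset-class] object.
#' @export
MutationDataset <- function(records,
                            proteins = Biostrings::AAStringSet(),
                            provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("ph", "temperature")) {
    if (is.null(records[[col]])) records[[col]] <- rep(NA_real_, nrow(records))
  }
  for (col in c("cluster_id", "label")) {
    if (is.null(records[[col]])) records[[col]] <- rep(NA_character_, nrow(records))
  }
  if (nrow(records)) {
    records$position <- as.integer(records$position)
    records$ddg <- as.numeric(records$ddg)
  }
  records <- records[, .recordColumns, drop = FALSE]
  rownames(records) <- NULL
  new("MutationDataset", records = records, proteins = proteins,
      provenance = provenance)
}

#' Parse a substitution token such as "A123G"
#'
#' @param token character vector of tokens: wild-type letter, 1-based
#'   position, mutant letter.
#' @return data.frame with columns `wt_aa`, `position`, `mut_aa`.
#' @export
parseMutationToken <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed substitution token(s): ", paste(token[bad], collapse = ", "))
  wt <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  mut <- toupper(vapply(m, `[`, "", 4L))
  if (any(!wt %in% AA20) || any(!mut %in% AA20))
    stop("substitution token contains a non-standard amino-acid letter")
  if (any(wt == mut))
    stop("wild-type and mutant residues are identical in token(s): ",
         paste(token[wt == mut], collapse = ", "))
  if (any(pos < 1L)) stop("positions must be >= 1")
  data.frame(wt_aa = wt, position = pos, mut_aa = mut,
             stringsAsFactors = FALSE)
}

.parseNum <- function(x, what, lines) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x != "NA" & x != "-" & is.na(out)
  if (any(bad))
    stop("non-numeric ", what, " on line(s): ",
         paste(lines[bad], collapse = ", "))
  out
}

#' Read a white-space-delimited mutation dataset
#'
#' The `s1914` dialect has no header and one record per line with columns
#' protein id, substitution token (e.g. `A32G`), ddGu (kcal/mol), then
#' optional pH, temperature (Celsius) and cluster id.  The `generic`
#' dialect carries a header line naming columns (`protein_id`,
#' `mutation`, `ddg`, and optionally `ph`, `temperature`, `cluster_id`).
#'
#' @param path input file.
#' @param dialect `"s1914"` or `"generic"`.
#' @param provenance optional free-text metadata (defaults to the path).
#' @return a [MutationDataset-class]; row order equals input order.
#' @export
readMutationDataset <- function(path, dialect = c("s1914", "generic"),
                                provenance = path) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  header <- NULL
  if (dialect == "generic") {
    if (!length(lines)) stop("generic dialect requires a header line")
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  if (!length(lines))
    return(MutationDataset(data.frame(protein_id = character(),
                                      wt_aa = character(), position = integer(),
                                      mut_aa = character(), ddg = numeric()),
                           provenance = provenance))
  tok <- strsplit(trimws(lines), "\\s+")
  if (dialect == "s1914") {
    nf <- vapply(tok, length, 1L)
    if (any(nf < 3L))
      stop("too few fields on line(s): ", paste(lineno[nf < 3L], collapse = ", "))
    grab <- function(i) vapply(tok, function(t) if (length(t) >= i) t[i] else NA_character_, "")
    sub <- parseMutationToken(grab(2L))
    rec <- data.frame(protein_id = grab(1L), sub,
                      ddg = .parseNum(grab(3L), "ddGu", lineno),
                      ph = .parseNum(grab(4L), "pH", lineno),
                      temperature = .parseNum(grab(5L), "temperature", lineno),
                      cluster_id = grab(6L), stringsAsFactors = FALSE)
  } else {
    need <- c("protein_id", "mutation", "ddg")
    if (!all(need %in% header))
      stop("generic header must name columns: ", paste(need, collapse = ", "))
    nf <- vapply(tok, length, 1L)
    if (any(nf != length(header)))
      stop("field count differs from header on line(s): ",
           paste(lineno[nf != length(header)], collapse = ", "))
    col <- function(nm) {
      i <- match(nm, header)
      if (is.na(i)) rep(NA_character_, length(tok))
      else vapply(tok, `[`, "", i)
    }
    sub <- parseMutationToken(col("mutation"))
    rec <- data.frame(protein_id = col("protein_id"), sub,
                      ddg = .parseNum(col("ddg"), "ddGu", lineno),
                      ph = .parseNum(col("ph"), "pH", lineno),
                      temperature = .parseNum(col("temperature"), "temperature", lineno),
                      cluster_id = col("cluster_id"), stringsAsFactors = FALSE)
  }
  if (any(is.na(rec$ddg)))
    stop("missing ddGu on line(s): ", paste(lineno[is.na(rec$ddg)], collapse = ", "))
  rec$cluster_id[rec$cluster_id %in% c("NA", "-")] <- NA_character_
  MutationDataset(rec, provenance = provenance)
}

#' Write a mutation dataset in the same dialect [readMutationDataset()] reads
#'
#' @param dataset a [MutationDataset-class].
#' @param path output file.
#' @param dialect `"s1914"` (headerless) or `"generic"` (with header).
#' @return `path`, invisibly.
#' @export
writeMutationDataset <- function(dataset, path, dialect = c("s1914", "generic")) {
  dialect <- match.arg(dialect)
  rec <- records(dataset)
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE, scientific = FALSE))
  token <- paste0(rec$wt_aa, rec$position, rec$mut_aa)
  body <- paste(rec$protein_id, token, fmt(rec$ddg), fmt(rec$ph),
                fmt(rec$temperature), fmt(rec$cluster_id))
  if (dialect == "generic")
    body <- c("protein_id mutation ddg ph temperature cluster_id", body)
  writeLines(if (nrow(rec)) body else character(), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased; only the 20 standard letters plus `X` are
#' accepted (`X` is tolerated at parse time but rejected by the feature
#' encoders).  Duplicate identifiers and empty sequences are errors.
#'
#' @param path FASTA file.
#' @return an [Biostrings::AAStringSet] named by the first word of each
#'   header.
#' @export
readProteinSequences <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate protein identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence for: ", paste(ids[Biostrings::width(seqs) == 0L],
                                       collapse = ", "))
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X]"),
               as.character(seqs))
  if (any(bad))
    stop("non-standard residue letters in: ", paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the first (log-odds) score block of the PSI-BLAST ASCII matrix
#' dialect: a header line of 20 amino-acid column labels followed by one
#' row per residue (`index residue s1 ... s20 [...]`).  The column order
#' is taken from the header, never assumed.
#'
#' @param path PSSM file.
#' @param proteinId identifier to store (defaults to the file name).
#' @return a [PSSMProfile-class].
#' @export
readPSSM <- function(path, proteinId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_header <- vapply(toks, function(t)
    length(t) >= 20L && all(t[1:20] %in% AA20) && !anyDuplicated(t[1:20]), TRUE)
  hi <- which(is_header)[1]
  if (is.na(hi)) stop("missing PSSM header line of 20 amino-acid column labels")
  columnOrder <- toks[[hi]][1:20]
  rows <- list(); seqs <- character()
  for (i in seq(hi + 1L, length.out = max(0L, length(lines) - hi))) {
    t <- toks[[i]]
    if (!length(t)) break  # blank line ends the matrix block
    if (!grepl("^[0-9]+$", t[1])) break
    if (length(t) < 22L)
      stop("truncated PSSM row on line ", i)
    sc <- suppressWarnings(as.integer(t[3:22]))
    if (any(is.na(sc)))
      stop("non-integer PSSM score on line ", i)
    rows[[length(rows) + 1L]] <- sc
    seqs <- c(seqs, toupper(t[2]))
  }
  if (!length(rows)) stop("PSSM contains no score rows")
  scores <- do.call(rbind, rows)
  colnames(scores) <- columnOrder
  new("PSSMProfile", proteinId = proteinId, scores = scores,
      columnOrder = columnOrder, sequence = seqs)
}

#' Write a PSSMProfile in the dialect [readPSSM()] reads
#'
#' @param profile a [PSSMProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePSSM <- function(profile, path) {
  sc <- pssmScores(profile)
  hdr <- paste0("        ", paste(sprintf("%4s", colnames(sc)), collapse = ""))
  res <- profile@sequence
  if (!length(res) || all(is.na(res))) res <- rep("X", nrow(sc))
  body <- vapply(seq_len(nrow(sc)), function(i)
    paste0(sprintf("%5d %s", i, res[i]),
           paste(sprintf("%4d", sc[i, ]), collapse = "")), "")
  writeLines(c("", "Last position-specific scoring matrix computed", hdr, body, ""),
             path)
  invisible(path)
}

#' Look up a PSSM score by position and residue letter
#'
#' @param profile a [PSSMProfile-class].
#' @param position 1-based residue position.
#' @param aa one of the 20 standard amino-acid letters.
#' @return the integer log-odds score.
#' @export
scoreAt <- function(profile, position, aa) {
  stopifnot(is(profile, "PSSMProfile"))
  if (length(position) != 1L || !is.finite(position) ||
      position != round(position) || position < 1L ||
      position > nrow(profile@scores))
    stop("position out of range (1-based): ", position)
  if (!aa %in% AA20)
    stop("not a standard amino-acid letter: ", aa)
  unname(profile@scores[as.integer(position), aa])
}

#' Read and write per-site annotation tables
#'
#' White-space-delimited, one row per mutation record, with a header line
#' `protein_id mutation sift ss asa disorder`.  `ss` is one of `helix`,
#' `sheet`, `coil`; `sift`, `asa` and `disorder` lie in [0, 1].  These
#' carry the outputs of the external predictors (SIFT, SPINE-X, SPINE-D),
#' which this package consumes but never runs.
#'
#' @param path annotation file.
#' @param dataset optional [MutationDataset-class]; when given, rows are
#'   matched to its records by protein id and substitution token and
#'   returned in record order (unannotated records are an error).
#' @return data.frame with columns `protein_id`, `mutation`, `sift`,
#'   `ss`, `asa`, `disorder`.
#' @export
readSiteAnnotations <- function(path, dataset = NULL) {
  ann <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein_id", "mutation", "sift", "ss", "asa", "disorder")
  if (!all(need %in% colnames(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  .checkAnnotations(ann)
  if (!is.null(dataset)) {
    rec <- records(dataset)
    key <- paste(rec$protein_id, paste0(rec$wt_aa, rec$position, rec$mut_aa))
    idx <- match(key, paste(ann$protein_id, ann$mutation))
    if (anyNA(idx))
      stop("missing annotation for record(s): ",
           paste(head(key[is.na(idx)], 3), collapse = ", "))
    ann <- ann[idx, , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

.checkAnnotations <- function(ann) {
  if (!all(ann$ss %in% c("helix", "sheet", "coil")))
    stop("ss must be one of helix, sheet, coil")
  for (col in c("sift", "asa", "disorder")) {
    v <- ann[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop(col, " values must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' @rdname readSiteAnnotations
#' @param annotations annotation data.frame as returned by
#'   [readSiteAnnotations()] or [simulateDataset()].
#' @export
writeSiteAnnotations <- function(annotations, path) {
  write.table(annotations[, c("protein_id", "mutation", "sift", "ss",
                              "asa", "disorder")],
              path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write protein-to-cluster tables
#'
#' Two white-space-delimited columns: protein id, cluster id.
#'
#' @param path cluster table file.
#' @param threshold identity threshold recorded on the object.
#' @return a [HomologyClustering-class] (representatives are taken as the
#'   first-listed protein of each cluster).
#' @export
readClusterTable <- function(path, threshold = 25) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("protein_id", "cluster_id"))
  assignments <- setNames(tab$cluster_id, tab$protein_id)
  reps <- setNames(tab$protein_id[!duplicated(tab$cluster_id)],
                   unique(tab$cluster_id))
  new("HomologyClustering", assignments = assignments,
      representatives = reps, threshold = threshold)
}

#' @rdname readClusterTable
#' @param clustering a [HomologyClustering-class].
#' @export
writeClusterTable <- function(clustering, path) {
  a <- clusterAssignments(clustering)
  writeLines(paste(names(a), unname(a)), path)
  invisible(path)
}
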