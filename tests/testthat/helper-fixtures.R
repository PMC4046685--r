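# Fixture builders and independent oracle implementations shared by the
# test files.  Oracles deliberately use brute force / direct formula
# evaluation and never call the package code paths they check.

toyProfile <- function(seq = "MKTAYIAKQR", seed = 1, proteinId = "toy") {
  set.seed(seed)
  L <- nchar(seq)
  sc <- matrix(as.integer(sample(-9:11, L * 20, replace = TRUE)), L, 20,
               dimnames = list(NULL, mutstab:::AA20))
  new("PSSMProfile", proteinId = proteinId, scores = sc,
      columnOrder = mutstab:::AA20, sequence = strsplit(seq, "")[[1]])
}

toyAnnotation <- function(sift = 0.05, ss = "coil", asa = 0.4, disorder = 0.1) {
  data.frame(sift = sift, ss = ss, asa = asa, disorder = disorder,
             stringsAsFactors = FALSE)
}

toyRecords <- function(n = 6, protein = "p1", seed = 1) {
  set.seed(seed)
  data.frame(protein_id = protein,
             wt_aa = "A", position = seq_len(n), mut_aa = "G",
             ddg = round(rnorm(n), 2), ph = 7, temperature = 25,
             stringsAsFactors = FALSE)
}

singletonClustering <- function(ids) {
  new("HomologyClustering",
      assignments = setNames(paste0("C", seq_along(ids)), ids),
      representatives = setNames(ids, paste0("C", seq_along(ids))),
      threshold = 25)
}

# --- independent metric oracles ---

oracleClassificationMetrics <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(mcc = if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0,
    q2 = 100 * (tp + tn) / (tp + tn + fp + fn),
    se = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_)
}

# AUC by exhaustive concordant-pair counting with half credit for ties
oracleAuc <- function(scores, truth) {
  pos <- which(truth == "stabilising")
  neg <- which(truth == "destabilising")
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1
                     else if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force single-linkage components over an explicit edge list
oracleComponents <- function(ids, edges) {
  comp <- setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (e in edges) {
      a <- comp[e[1]]; b <- comp[e[2]]
      if (a != b) { comp[comp == b] <- a; changed <- TRUE }
    }
    if (!changed) break
  }
  split(ids, comp[ids])
}

randomSequences <- function(n, len, seed) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(mutstab:::AA20, len, replace = TRUE), collapse = ""), "")
  Biostrings::AAStringSet(setNames(seqs, sprintf("s%02d", seq_len(n))))
}

smallSyntheticConfig <- function(seed, ...) {
  syntheticConfig(nClusters = 5, proteinsPerCluster = 2, seqLength = 40,
                  mutationsPerProtein = 6, seed = seed, ...)
}
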