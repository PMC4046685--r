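## Dataset curation: sign labelling, same-condition averaging, pH-nearest
## selection within a protein, and within-cluster deduplication of the
## same substitution measured in homologous proteins.

# tolerances defining "same experimental conditions"
.PH_TOL <- 0.05
.TEMP_TOL <- 0.5

#' Sign rule for stability-change labels
#'
#' A mutation is stabilising when ddGu >= 0 (positive class) and
#' destabilising when ddGu < 0.
#'
#' @param ddg numeric vector of ddGu values, kcal/mol.
#' @return character vector of `"stabilising"` / `"destabilising"`.
#' @export
labelSign <- function(ddg) {
  if (any(!is.finite(ddg))) stop("ddGu must be finite")
  ifelse(ddg >= 0, "stabilising", "destabilising")
}

.sameCondition <- function(ph1, t1, ph2, t2) {
  phEq <- (is.na(ph1) & is.na(ph2)) |
    (!is.na(ph1) & !is.na(ph2) & abs(ph1 - ph2) <= .PH_TOL)
  tEq <- (is.na(t1) & is.na(t2)) |
    (!is.na(t1) & !is.na(t2) & abs(t1 - t2) <= .TEMP_TOL)
  phEq & tEq
}

#' Average repeated measurements taken under the same conditions
#'
#' All rows must describe the same substitution of the same protein under
#' equal conditions (pH within 0.05, temperature within 0.5 C; both
#' missing counts as equal).  ddGu values are averaged arithmetically and
#' the label recomputed by the sign rule.
#'
#' @param group data.frame of record rows.
#' @return a single record row.
#' @export
mergeSameCondition <- function(group) {
  if (!nrow(group)) stop("empty group")
  u <- unique(group[, c("protein_id", "wt_aa", "position", "mut_aa")])
  if (nrow(u) != 1L) stop("group mixes different substitutions")
  if (!all(.sameCondition(group$ph[1], group$temperature[1],
                          group$ph, group$temperature)))
    stop("experimental conditions differ beyond tolerance; ",
         "route the group through selectPhNearest instead")
  out <- group[1, , drop = FALSE]
  out$ddg <- mean(group$ddg)
  out$label <- labelSign(out$ddg)
  out
}

#' Keep the measurement closest to physiological pH 7
#'
#' Among measurements of one substitution at different conditions, the
#' record minimising |pH - 7| is kept.  Ties are broken by temperature
#' nearest 25 C, then by input order; a missing pH counts as infinitely
#' far unless every pH is missing.
#'
#' @param group data.frame of record rows (same substitution, conditions
#'   already merged where equal).
#' @return the selected record row.
#' @export
selectPhNearest <- function(group) {
  if (!nrow(group)) stop("empty group")
  dPh <- abs(group$ph - 7); dPh[is.na(dPh)] <- Inf
  dT <- abs(group$temperature - 25); dT[is.na(dT)] <- Inf
  group[order(dPh, dT, seq_len(nrow(group)))[1], , drop = FALSE]
}

.conditionGroups <- function(group) {
  # greedy pass: each row joins the first earlier row with equal conditions
  g <- integer(nrow(group))
  for (i in seq_len(nrow(group))) {
    hit <- 0L
    for (j in seq_len(i - 1L)) {
      if (.sameCondition(group$ph[i], group$temperature[i],
                         group$ph[j], group$temperature[j])) {
        hit <- g[j]; break
      }
    }
    g[i] <- if (hit) hit else max(g, 0L) + 1L
  }
  g
}

#' Curate a mutation dataset
#'
#' Applies the curation pipeline in order: (1) average repeated
#' measurements of the same substitution under the same conditions;
#' (2) among remaining measurements of the same substitution within a
#' protein, keep the one closest to pH 7; (3) among measurements of the
#' same substitution at the same (alignment-mapped) residue within a
#' homology cluster, again keep the one closest to pH 7.  All surviving
#' records are labelled by the sign rule and cluster ids are attached.
#'
#' @param dataset a [MutationDataset-class].
#' @param clustering a [HomologyClustering-class] covering all proteins
#'   in the dataset.
#' @return list with elements `dataset` (curated, input order preserved)
#'   and `report` (named list of curation bookkeeping counts; see
#'   [datasetStats()] for the statistics fields).
#' @export
curateDataset <- function(dataset, clustering) {
  rec <- records(dataset)
  missing <- setdiff(unique(rec$protein_id), names(clusterAssignments(clustering)))
  if (length(missing))
    stop("clustering does not cover protein(s): ",
         paste(head(missing, 3), collapse = ", "))
  n_input <- nrow(rec)
  rec$.id <- seq_len(nrow(rec))
  rec$cluster_id <- unname(clusterAssignments(clustering)[rec$protein_id])

  ## (1) merge measurements under identical conditions
  subKey <- paste(rec$protein_id, rec$wt_aa, rec$position, rec$mut_aa)
  merged <- do.call(rbind, lapply(split(rec, factor(subKey, unique(subKey))),
                                  function(g) {
    g <- g[order(g$.id), , drop = FALSE]
    do.call(rbind, lapply(split(g, .conditionGroups(g)), mergeSameCondition))
  }))
  merged <- merged[order(merged$.id), , drop = FALSE]
  n_merge <- nrow(merged)

  ## (2) pH-nearest within (protein, substitution)
  subKey <- paste(merged$protein_id, merged$wt_aa, merged$position, merged$mut_aa)
  phsel <- do.call(rbind, lapply(split(merged, factor(subKey, unique(subKey))),
                                 selectPhNearest))
  phsel <- phsel[order(phsel$.id), , drop = FALSE]
  n_ph <- nrow(phsel)

  ## (3) pH-nearest within (cluster, mapped residue, substitution)
  tmp <- MutationDataset(phsel[, .recordColumns], proteins = proteins(dataset),
                         provenance = provenance(dataset))
  keys <- residueGroupKeys(tmp, clustering)
  clKey <- paste(keys$cluster_id, keys$mapped_position, phsel$wt_aa, phsel$mut_aa)
  dedup <- do.call(rbind, lapply(split(phsel, factor(clKey, unique(clKey))),
                                 selectPhNearest))
  dedup <- dedup[order(dedup$.id), , drop = FALSE]

  dedup$label <- labelSign(dedup$ddg)
  out <- MutationDataset(dedup[, .recordColumns], proteins = proteins(dataset),
                         provenance = paste0(provenance(dataset),
                                             " [curated]"))
  stats <- datasetStats(out, clustering)
  report <- c(list(n_input = n_input,
                   n_after_same_condition_merge = n_merge,
                   n_after_ph_selection = n_ph,
                   n_after_cluster_dedup = nrow(dedup)),
              stats)
  list(dataset = out, report = report)
}

#' Descriptive statistics of a labelled mutation dataset
#'
#' Computes the bookkeeping quantities used to characterise curated
#' stability datasets: protein/cluster/residue counts, the fraction of
#' destabilising mutations, the fraction of substitutions to alanine, and
#' the within-group sign agreement — the fraction of records (in groups
#' holding more than one record) whose label equals the group's majority
#' label, with majority ties resolved towards destabilising.  Groups are
#' homology clusters (`level = "cluster"`, the default) or individual
#' proteins (`level = "protein"`); residue-level agreement always groups
#' by (cluster, alignment-mapped position).
#'
#' @param dataset a labelled [MutationDataset-class].
#' @param clustering a [HomologyClustering-class].
#' @param level grouping for the protein-level agreement statistic.
#' @return named list (a CurationReport): counts, fractions, and
#'   `sign_agreement_protein` / `sign_agreement_residue` (`NA` when no
#'   group has more than one record).
#' @export
datasetStats <- function(dataset, clustering, level = c("cluster", "protein")) {
  level <- match.arg(level)
  rec <- records(dataset)
  if (!nrow(rec)) stop("empty dataset")
  if (anyNA(rec$label)) stop("dataset must be labelled (run curateDataset)")
  cl <- unname(clusterAssignments(clustering)[rec$protein_id])
  keys <- residueGroupKeys(dataset, clustering)
  resKey <- paste(keys$cluster_id, keys$mapped_position)

  agreement <- function(groupKey) {
    tab <- split(rec$label, groupKey)
    tab <- tab[vapply(tab, length, 1L) > 1L]
    if (!length(tab)) return(NA_real_)
    hits <- vapply(tab, function(lab) {
      nPos <- sum(lab == "stabilising"); nNeg <- length(lab) - nPos
      maj <- if (nPos > nNeg) "stabilising" else "destabilising"
      sum(lab == maj)
    }, 1)
    sum(hits) / sum(vapply(tab, length, 1L))
  }
  protKey <- if (level == "cluster") cl else rec$protein_id
  multi <- sum(vapply(split(rec$label, protKey), length, 1L) > 1L)
  list(n_records = nrow(rec),
       n_proteins = length(unique(rec$protein_id)),
       n_clusters = length(unique(cl)),
       n_unique_residues = length(unique(resKey)),
       fraction_destabilising = mean(rec$label == "destabilising"),
       fraction_to_alanine = mean(rec$mut_aa == "A"),
       n_multi_mutation_groups = multi,
       sign_agreement_protein = agreement(protKey),
       sign_agreement_residue = agreement(resKey))
}
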