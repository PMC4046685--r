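test_that("the sign rule maps ddGu >= 0 to stabilising", {
  expect_equal(labelSign(0.0), "stabilising")
  expect_equal(labelSign(-0.5), "destabilising")
  expect_equal(labelSign(2.3), "stabilising")
  expect_equal(labelSign(c(-1, 0, 1)),
               c("destabilising", "stabilising", "stabilising"))
  expect_error(labelSign(NaN), "finite")
  expect_error(labelSign(Inf), "finite")
})

test_that("same-condition duplicates are averaged, labelled, and guarded", {
  g <- toyRecords(2)
  g$position <- 5L
  g$ddg <- c(1, 2)
  out <- mergeSameCondition(g)
  expect_equal(out$ddg, 1.5)
  expect_equal(out$label, "stabilising")

  g$ddg <- c(-1, 1)
  out <- mergeSameCondition(g)
  expect_equal(out$ddg, 0)
  expect_equal(out$label, "stabilising")  # mean 0 then the sign rule

  single <- toyRecords(1)
  expect_equal(mergeSameCondition(single)$ddg, single$ddg)

  g$ph <- c(5, 8)
  expect_error(mergeSameCondition(g), "selectPhNearest")
})

test_that("pH-nearest selection follows the 7 / 25C / input-order tie-breaks", {
  g <- toyRecords(2); g$position <- 5L
  g$ph <- c(6.5, 8.0)
  expect_equal(selectPhNearest(g)$ph, 6.5)
  g$ph <- c(7.0, 5.0)
  expect_equal(selectPhNearest(g)$ph, 7.0)
  g$ph <- c(6.5, 7.5); g$temperature <- c(40, 25)
  expect_equal(selectPhNearest(g)$ph, 7.5)   # forced by the temperature tie-break
  g$ph <- c(NA, 9)
  expect_equal(selectPhNearest(g)$ph, 9)     # missing pH is infinitely far
  g$ph <- c(NA, NA); g$temperature <- c(25, 25)
  expect_equal(selectPhNearest(g)$ddg, g$ddg[1])  # all missing: input order
  expect_error(selectPhNearest(g[0, ]), "empty")
})

test_that("the curation pipeline collapses a hand-traced 6-row toy to 3 records", {
  # p1 and p2 are identical homologues (one cluster); p3 is unrelated.
  # rows 1+2: same substitution, same conditions       -> averaged
  # rows 3+4: same substitution, different pH          -> pH 7 wins
  # row 5:    same substitution as rows 1-2 but in p2  -> cluster dedup
  # row 6:    independent substitution in p3           -> survives
  rec <- data.frame(
    protein_id = c("p1", "p1", "p1", "p1", "p2", "p3"),
    wt_aa = c("A", "A", "K", "K", "A", "W"),
    position = c(4L, 4L, 2L, 2L, 4L, 1L),
    mut_aa = c("G", "G", "E", "E", "G", "F"),
    ddg = c(1.0, 2.0, -0.4, -0.9, 0.2, 0.3),
    ph = c(7, 7, 7, 5, 6, 7),
    temperature = 25, stringsAsFactors = FALSE)
  seqs <- Biostrings::AAStringSet(c(p1 = "MKTAYIAKQR", p2 = "MKTAYIAKQR",
                                    p3 = "WGGSSPPHHC"))
  ds <- MutationDataset(rec, proteins = seqs)
  cl <- clusterSequences(seqs)
  expect_equal(length(clusterRepresentatives(cl)), 2L)

  res <- curateDataset(ds, cl)
  out <- records(res$dataset)
  expect_equal(nrow(out), 3L)
  expect_equal(out$ddg, c(1.5, -0.4, 0.3))     # mean, pH-7 winner, untouched
  expect_equal(out$label, labelSign(out$ddg))
  expect_equal(res$report$n_input, 6L)
  expect_equal(res$report$n_after_same_condition_merge, 5L)
  expect_equal(res$report$n_after_ph_selection, 4L)
  expect_equal(res$report$n_after_cluster_dedup, 3L)
})

test_that("curation is idempotent and never increases record counts", {
  sim <- simulateDataset(smallSyntheticConfig(seed = 21))
  once <- curateDataset(sim$dataset, sim$clustering)
  twice <- curateDataset(once$dataset, sim$clustering)
  expect_equal(records(twice$dataset)[, 1:7], records(once$dataset)[, 1:7])
  r <- once$report
  expect_true(r$n_input >= r$n_after_same_condition_merge)
  expect_true(r$n_after_same_condition_merge >= r$n_after_ph_selection)
  expect_true(r$n_after_ph_selection >= r$n_after_cluster_dedup)
})

test_that("an input without duplicates passes through unchanged", {
  rec <- toyRecords(4)
  rec$mut_aa <- c("G", "E", "F", "W")
  ds <- MutationDataset(rec)
  res <- curateDataset(ds, singletonClustering("p1"))
  expect_equal(records(res$dataset)$ddg, rec$ddg)
})

test_that("sign agreement uses the cluster majority with ties to destabilising", {
  rec <- toyRecords(3)
  rec$ddg <- c(1, 2, -1)
  rec$label <- labelSign(rec$ddg)
  ds <- MutationDataset(rec)
  st <- datasetStats(ds, singletonClustering("p1"))
  expect_equal(st$sign_agreement_protein, 2 / 3)

  # 2 vs 2 tie: majority is destabilising, agreement 1/2
  rec4 <- toyRecords(4); rec4$ddg <- c(1, 1, -1, -1)
  rec4$label <- labelSign(rec4$ddg)
  st4 <- datasetStats(MutationDataset(rec4), singletonClustering("p1"))
  expect_equal(st4$sign_agreement_protein, 1 / 2)

  # singletons only: agreement undefined, multi-group count zero
  rec1 <- toyRecords(2)
  rec1$protein_id <- c("p1", "p2")
  rec1$label <- labelSign(rec1$ddg)
  st1 <- datasetStats(MutationDataset(rec1), singletonClustering(c("p1", "p2")))
  expect_true(is.na(st1$sign_agreement_protein))
  expect_equal(st1$n_multi_mutation_groups, 0L)

  expect_error(datasetStats(MutationDataset(toyRecords(2)),
                            singletonClustering("p1")), "labelled")
})

test_that("a generator with full agreement yields unanimous protein signs", {
  sim <- simulateDataset(smallSyntheticConfig(seed = 5, signAgreement = 1,
                                              fracDestabilising = 0.74))
  st <- datasetStats(sim$dataset, sim$clustering, level = "protein")
  expect_equal(st$sign_agreement_protein, 1.0)
})
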