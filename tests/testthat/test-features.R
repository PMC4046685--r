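test_that("the AAP table is 20 x 7, column-scaled to [0, 1], and injectable", {
  tab <- aapTable()
  expect_equal(dim(tab), c(20L, 7L))
  expect_equal(colnames(tab)[1:2], c("hydrophobicity", "volume"))
  expect_equal(unname(apply(tab, 2, min)), rep(0, 7))
  expect_equal(unname(apply(tab, 2, max)), rep(1, 7))
  # glycine has the smallest volume, tryptophan the largest
  expect_equal(unname(tab["G", "volume"]), 0)
  expect_equal(unname(tab["W", "volume"]), 1)
})

test_that("AAP differences are antisymmetric with a zero diagonal", {
  tab <- aapTable()
  for (wt in mutstab:::AA20) {
    expect_equal(unname(aapDifference(wt, wt, tab)), rep(0, 7))
    for (mut in mutstab:::AA20) {
      expect_equal(aapDifference(wt, mut, tab), -aapDifference(mut, wt, tab))
    }
  }
  # G -> W is the largest-magnitude volume change involving G
  dGW <- abs(aapDifference("G", "W", tab)[["volume"]])
  others <- vapply(setdiff(mutstab:::AA20, c("G", "W")), function(m)
    abs(aapDifference("G", m, tab)[["volume"]]), 1)
  expect_true(all(dGW >= others))
  expect_error(aapDifference("X", "A"), "non-standard")
})

test_that("mutation and conservation likelihoods divide the raw score by 10", {
  prof <- toyProfile(seed = 2)
  sc <- pssmScores(prof)
  expect_equal(mutationLikelihood(prof, 4, "G"), unname(sc[4, "G"]) / 10)
  expect_equal(conservationLikelihood(prof, 4, "M"), unname(sc[4, "M"]) / 10)
  # values beyond [-1, 1] are retained, never clipped
  prof2 <- toyProfile()
  prof2@scores[3, "W"] <- 12L
  expect_equal(mutationLikelihood(prof2, 3, "W"), 1.2)
  prof2@scores[3, "W"] <- 0L
  expect_equal(mutationLikelihood(prof2, 3, "W"), 0)
})

test_that("the EASE-AA vector has the documented 14-input block layout", {
  prof <- toyProfile()
  prof@scores[4, "G"] <- -3L
  ann <- toyAnnotation(sift = 0.05, ss = "coil", asa = 0.4, disorder = 0.1)
  v <- encodeEaseAA("A", "G", 4, ann, prof)
  expect_length(v, 14L)
  expect_equal(unname(v[1:7]),
               c(0.05, -0.3, 0, 0, 1, 0.4, 0.1))
  expect_equal(unname(v[8:14]), unname(aapDifference("A", "G")))
  # the SS block is a one-hot over (helix, sheet, coil)
  vh <- encodeEaseAA("A", "G", 4, toyAnnotation(ss = "helix"), prof)
  expect_equal(unname(vh[3:5]), c(1, 0, 0))
  expect_error(encodeEaseAA("A", "G", 4, toyAnnotation(sift = NA), prof),
               "sift")
})

test_that("the EASE vector has 145 inputs with one-hot windows and a +/-1 block", {
  prof <- toyProfile()
  seq <- "MKTAYIAKQR"
  v <- encodeEase("A", "G", 4, toyAnnotation(), prof, seq)
  expect_length(v, 145L)
  # each interior neighbour window sums to 1
  for (off in c("n-3", "n-2", "n-1", "n+1", "n+2", "n+3")) {
    block <- v[startsWith(names(v), paste0(off, "_"))]
    expect_equal(sum(block), 1)
  }
  # substitution block: sums to 0 with exactly two nonzero entries
  sub <- v[grep("^sub_", names(v))]
  expect_equal(sum(sub), 0)
  expect_equal(sum(sub != 0), 2L)
  expect_equal(unname(sub["sub_A"]), -1)
  expect_equal(unname(sub["sub_G"]), 1)
  # windows past the terminus are all-zero
  v1 <- encodeEase("M", "G", 1, toyAnnotation(), prof, seq)
  expect_equal(sum(v1[startsWith(names(v1), "n-")]), 0)
  # the shared S, M, SS block equals EASE-AA's for the same record
  vaa <- encodeEaseAA("A", "G", 4, toyAnnotation(), prof)
  expect_equal(unname(v[1:5]), unname(vaa[1:5]))
})

test_that("the sequence-only baselines have their declared layouts", {
  seq <- "MKTAYIAKQR"
  vn <- encodeSeqNeighb("A", "G", 4, seq)
  expect_length(vn, 140L)
  vf <- encodeSeqFreq("A", "G", 4, seq)
  expect_length(vf, 40L)
  expect_equal(sum(vf[grep("^freq_", names(vf))]), 1)  # full window
  # an all-alanine neighbourhood concentrates the frequency mass
  vfa <- encodeSeqFreq("G", "W", 4, "AAAGAAA")
  expect_equal(unname(vfa[["freq_A"]]), 1)
  # identical substitutions in different contexts encode differently
  vn2 <- encodeSeqNeighb("A", "G", 4, "WWWAWWWKQR")
  expect_false(all(vn == vn2))
})

test_that("block registries match the encoder dimensionalities", {
  for (enc in c("easeAA", "ease", "seqNeighb", "seqFreq")) {
    expect_equal(sum(featureBlocks(enc)), featureLength(enc))
  }
  expect_equal(featureLength("easeAA"), 14L)
  expect_equal(featureLength("ease"), 145L)
  expect_equal(featureLength("seqNeighb"), 140L)
  expect_equal(featureLength("seqFreq"), 40L)
  sim <- simulateDataset(smallSyntheticConfig(seed = 2))
  for (enc in c("easeAA", "ease", "seqNeighb", "seqFreq")) {
    x <- encodeFeatures(sim$dataset, sim$annotations, sim$profiles, enc)
    expect_equal(ncol(x), featureLength(enc))
    expect_equal(nrow(x), nrow(records(sim$dataset)))
  }
})

test_that("conservation-stability profiles bin medians by PSSM score", {
  sim <- simulateDataset(smallSyntheticConfig(seed = 13))
  rec <- records(sim$dataset)
  # constant ddGu: every non-empty bin has that median
  flat <- rec; flat$ddg <- -1; flat$label <- NULL
  dsFlat <- MutationDataset(flat, proteins = proteins(sim$dataset))
  prof <- conservationStabilityProfile(dsFlat, sim$profiles)
  expect_true(all(prof$median_ddg[prof$n > 0] == -1))
  expect_true(all(is.na(prof$median_ddg[prof$n == 0])))

  # ddGu = 0.2 * M-score + noise: medians rise with the mutation bin
  set.seed(4)
  msc <- vapply(seq_len(nrow(rec)), function(i)
    scoreAt(sim$profiles[[rec$protein_id[i]]], rec$position[i], rec$mut_aa[i]),
    1)
  slope <- rec
  slope$ddg <- 0.2 * msc + rnorm(nrow(rec), 0, 0.1)
  slope$label <- NULL
  dsSlope <- MutationDataset(slope, proteins = proteins(sim$dataset))
  prof2 <- conservationStabilityProfile(dsSlope, sim$profiles)
  mprof <- prof2[prof2$score_type == "mutation" & prof2$n > 0, ]
  expect_true(cor(mprof$bin, mprof$median_ddg, method = "spearman") > 0.9)

  empty <- MutationDataset(rec[0, ])
  expect_equal(nrow(conservationStabilityProfile(empty, sim$profiles)), 0L)
})
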