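---
title: "Homology-aware evaluation of stability-change predictors"
author: "mutstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-aware evaluation of stability-change predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutstab)
```

## The model

`mutstab` treats a single amino-acid substitution as either a binary
classification target (stabilising, ΔΔGu ≥ 0, against destabilising,
ΔΔGu < 0) or a regression target (the real-valued ΔΔGu in kcal/mol).
The predictor is an RBF-kernel support vector machine over a compact,
sequence-derived feature vector of 14 inputs:

| block | size | meaning | range |
|-------|------|---------|-------|
| S     | 1 | SIFT tolerance score of the substitution | [0, 1] |
| M     | 1 | PSSM log-odds of the *introduced* residue at the site, ÷ 10 | mostly [−1, 1], unclipped |
| SS    | 3 | one-hot secondary-structure type (helix, sheet, coil) | {0, 1} |
| ASA   | 1 | predicted relative accessible surface area | [0, 1] |
| D     | 1 | predicted disorder probability | [0, 1] |
| AAP   | 7 | physicochemical parameter differences, introduced − deleted | scaled |

The AAP block uses seven parameters (hydrophobicity, volume,
polarisability, isoelectric point, helix probability, sheet
probability, steric/graph-shape index), each min–max scaled to [0, 1]
over the 20 residues before differencing.  The exact scaling of this
table is a packaged constant, and every encoder accepts an alternative
table of the same shape, so other scalings can be injected without
touching code.

Three baseline encoders reproduce the feature sets this design is
compared against: `ease` (145 inputs: S, M, SS plus 6×20 neighbour
one-hots and a 20-input substitution-identity block), `seqNeighb`
(the 140 identity inputs alone) and `seqFreq` (20 neighbourhood
occurrence frequencies plus the substitution block, 40 inputs).  The
substitution-identity block is realised as a single 20-vector with −1
at the deleted and +1 at the introduced residue; windows reaching past
a terminus are all-zero, and the non-standard letter `X` is tolerated
by the parsers but rejected by every encoder.

## Why evaluation schemes matter

Experimental stability datasets are heavily structured: one protein
contributes many mutations, residues are mutated repeatedly, and the
signs of those changes are correlated.  A random train/test split
therefore leaks information — a model can recognise a residue
neighbourhood it has seen during training and recall the prevailing
sign instead of generalising.  The package implements three schemes
whose atomic units may never straddle a split: individual mutations
(`unseen_mutation`), residue positions shared across homologues via
alignment mapping (`unseen_residue`), and whole homology clusters
(`unseen_protein`).  The schemes are strictly nested: every valid
unseen-protein plan is a valid unseen-residue plan, and every
unseen-residue plan a valid unseen-mutation plan; `verifyNoLeakage()`
audits any plan against any scheme's rules.

Homology clusters are built by single-linkage over pairwise global
alignments (match +1, mismatch 0, gap open −5, gap extend −1; identity
is identical columns over the full alignment length), with an edge
whenever identity exceeds 25%.  These alignment parameters were chosen
for determinism and reproducibility, not to mimic BLAST statistics;
single linkage is conservative in that it merges generously, which only
makes the unseen-protein evaluation stricter.  A cluster id column
supplied with the input data overrides recomputation, so a published
clustering can be used verbatim.

## Dataset curation

`curateDataset()` applies, in order: (1) arithmetic averaging of
repeated measurements of one substitution under equal conditions (pH
within 0.05, temperature within 0.5 °C — measurement-precision scales,
since the convention is not standardised); (2) among measurements of
one substitution at different conditions, keeping the one nearest
physiological pH 7, ties broken by temperature nearest 25 °C and then
input order; (3) the same pH-nearest rule applied within a homology
cluster at the alignment-mapped residue, so the same substitution
measured in two homologues collapses to one record.  The pipeline is
idempotent, never increases record counts, and labels every survivor by
the sign rule.  Sign-agreement statistics group by cluster by default
(with a protein-level option), and majority ties resolve towards
destabilising — the prevailing class — to keep the statistic
deterministic.

## SVM protocol

Hyperparameters are tuned by exhaustive dyadic grid search
(`defaultGrid()`: 495 classification candidates, 1024 regression
candidates) using k-fold cross-validation on the training set only.
Held-out predictions from all folds are pooled into a single confusion
matrix or residual vector before scoring (pooling is more stable than
per-fold averaging when stabilising records are rare); the winner
maximises MCC or minimises RMSE, with ties broken towards smaller C,
then γ, then w/ε, making the winner independent of candidate
enumeration order.  Features are standardised per dimension with
statistics fitted on the training records only; the scaling is stored
in the model and applied at prediction time.  MCC rather than accuracy
is the classification objective because ~74% of records are
destabilising, and the positive-class weight w lets the SVM trade
specificity for sensitivity under that imbalance.

The replicate protocol (`runReplicates()`) repeats the whole procedure
R times — split, grid search, refit, independent test — and averages
the per-replicate metrics; `comparePerformance()` runs a two-sided
paired t-test across replicates for two runs sharing splits (identical
runs report p = 1, single replicates report a missing p-value).

## Evaluation measures

`classificationMetrics()` reports MCC and the percent measures Q2, Se,
Sp, PPV, NPV; rates with zero denominators are reported missing rather
than zero, while an MCC with a vanishing denominator is defined as 0.
`rocAuc()` computes AUC by rank statistics with half-credit for ties,
so it equals both the Mann–Whitney statistic and trapezoidal
integration of the curve.  Strata for performance breakdowns follow the
conventions for this problem: exposed means relative ASA ≥ 0.25,
`small` means ΔΔGu ∈ [−1, 1] kcal/mol (boundaries inclusive), and the
secondary-structure stratum is taken from whatever annotation source is
supplied.

## The synthetic benchmark

`simulateDataset()` generates everything the rest of the package needs,
so no external predictor output or database is required for testing.
Its defaults are the package's study conditions: 30 clusters × 2
homologues × 17 mutations (≈1,020 records, each residue site mutated
about twice, sequence length 60), 78% within-protein sign agreement,
82% within-residue agreement, 74% destabilising records, and alanine as
by far the most common introduced residue (drawn with probability 0.26
per mutation; since a site hosts each mutant at most once, roughly a
fifth of records end up as substitutions to alanine).  The generative model is

ΔΔGu = b<sub>protein</sub> + u<sub>site</sub> + **w**·**x** + ε,

where **x** is the record's 14-input feature vector, **w** a
configurable weight vector (defaults put most signal on S, M, ASA and D
and a modest amount on AAP), ε Gaussian noise, b a per-protein bias of
magnitude solved from the requested protein-level agreement under a
Gaussian residual model, and u a per-site bias whose standard deviation
is solved numerically (1-D root finding on a Gaussian integral) from
the residue-level agreement target.  The two-level bias is essential:
site annotations alone do not make mutations of one residue much more
correlated than mutations of one protein, whereas experimental data
show exactly that ordering, and it is this residue-level correlation
that random splits exploit.  Protein bias signs are assigned as an
exact shuffled proportion rather than an iid draw so the realised class
balance stays within ±0.02 of the target even with only ~160 proteins.
Homologues are point-mutated copies of a cluster ancestor (identity
65–95%, comfortably above the 25% threshold; unrelated clusters are
independent sequences, far below it), and synthetic PSSM scores reward
residues present in the cluster so the mutation-likelihood feature
genuinely carries signal and the conservation-versus-stability trend of
`conservationStabilityProfile()` is reproducible.

What the generator does *not* emulate: real biophysics (no epistasis,
no temperature/pH dependence of ΔΔGu), SIFT's alignment-based scoring
(S is uniform noise plus signal weight), realistic PSSM score
distributions, or sequence composition biases.  Passing tests therefore
demonstrate that the machinery — curation, clustering, splitting,
tuning, scoring — behaves correctly and that the evaluation-gap
phenomenon follows from the data structure; they do not certify
predictive accuracy on real proteins, which additionally requires the
external predictors this package deliberately treats as inputs.

## Numerical and design choices

* Positions are 1-based in the supplied sequence; no PDB-numbering
  translation is attempted.
* Missing pH/temperature are stored missing at parse time; only the
  curation rules interpret them (missing pH sorts last in the pH-7
  rule).
* When a mutated position aligns to a gap in the cluster
  representative, the residue key falls back to the raw position and is
  flagged unmapped rather than dropped.
* Split construction shuffles atomic units with the plan's seed and
  assigns each unit greedily to the side (or fold) with the largest
  remaining per-class deficit; this meets the 2:1 ratio and class-ratio
  targets within ±3 percentage points deterministically.  Fold seeds
  are offset from the plan seed by a fixed large prime so train/test
  and fold shuffles are decoupled.
* The SIFT 0.05 deleterious convention is metadata only and never
  applied as a filter.
* Degenerate regression targets with zero variance are fitted as the
  constant they are (every point lies inside the ε-tube).
* Problem sizes in the tests and the acceptance script are desk-scale
  by design: ~1,000-record benchmarks, 5 replicates, 3 folds, and a
  4–8 point `compactGrid()` spanning the informative C/γ region; the
  full 495/1024-point grids remain the defaults for real analyses.

## Known limitations

Curation assumes each input row is a valid ΔΔGu of the native
unfolding transition; sign errors against primary literature are out of
scope.  The identity-based clustering is not BLASTCLUST and will not
reproduce a published clustering exactly from raw sequences (supply the
published cluster ids to use them).  Pearson r of a model optimised for
RMSE, three-state (neutral) classification, and modelling stability as
a function of experimental conditions are all out of scope.
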