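---
title: "Methods: a similarity-gated expert system for sweetness prediction"
author: "sweetgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a similarity-gated expert system for sweetness prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Taste is a receptor-mediated percept: whether a molecule activates the sweet
receptor depends on global shape and on local pharmacophoric features, and
neither a purely similarity-based nor a purely descriptor-based classifier
captures both regimes well. Sweeteners concentrate in a few tight regions of
chemical space (sugar-like and aspartyl-like scaffolds) where structural
similarity alone is almost conclusive, while the rest of chemical space
mixes sweet and non-sweet structures and needs a fitted decision boundary.

`sweetgate` therefore stacks two decision stages.

**Stage 1 — similarity gate.** Molecules are encoded as hashed circular
fingerprints: atom neighbourhoods of radius 0, 1, 2 are canonicalized into
feature strings from iterated atom invariants (element, heavy-atom degree,
bond-order sum, formal charge) and each feature sets two positions of a
2,048-bit vector through two independent hashes. Similarity is the
Jaccard–Tanimoto coefficient on the bit sets. A query whose *average*
distance to the members of reference cluster S1 falls below 0.6, or below
0.8 for the looser cluster S2, is classified sweet outright. Averaging over
the whole cluster (rather than a nearest neighbour) makes the gate a
prototype test: it fires only for molecules that resemble the cluster as a
whole, which is what justifies skipping the statistical models.

**Stage 2 — strict consensus.** The remaining molecules are classified by
two models of different character fitted on the gate-uncovered training
molecules ("C3"): N3, a local similarity-rank-weighted neighbour method on
range-scaled descriptors, and PLSDA, a global linear method on autoscaled
descriptors. A prediction is issued only when both agree. The rejection
option is the point: the two models err differently, and demanding
agreement trades coverage for reliability, which is the right trade for
prioritizing synthesis candidates.

All performance numbers use the non-error rate NER = (Sn + Sp)/2 computed
over assigned molecules only, with the not-assigned percentage reported
alongside — with a rejection option, folding rejections into the error rate
would conflate two different costs.

## Parameters that matter

* **Fingerprints** — `nBits = 2048`, `maxOrder = 2` (radius),
  `bitsPerPattern = 2`. The radius-2 default follows the common circular
  fingerprint convention; the printed "pattern length" of the reference
  configuration could also be read as a diameter, so the parameter is
  exposed. Bit identity with any particular commercial implementation is
  not a goal; only the similarity structure matters here.
* **Gate thresholds** — fixed constants `S1 = 0.6`, `S2 = 0.8` (average
  Tanimoto distance, dimensionless in [0, 1]) by default, matching the
  published configuration. `deriveThreshold()` offers a data-driven
  alternative: the midpoint of the widest empty gap in the distribution of
  average distances, at or above the reference members' own distances, with
  a fallback when no gap of width ≥ 0.1 exists. Fixed constants are the
  shipped default because the derivation depends on the training
  distribution being cleanly bimodal.
* **Gate rule** — the published step description can be read as requiring
  both thresholds (AND) while its rationale speaks of similarity to either
  cluster (OR). The OR reading (`gateRule = "any"`, S1 checked first) is
  the default since the clusters describe disjoint scaffold families; AND
  is available as `"all"`. Boundary convention: strict inequality, so a
  distance exactly at the threshold goes to the consensus.
* **N3 alpha** — rank-damping exponent, optimized on the grid 0.5–3.0 in
  steps of 0.5 by venetian-blind CV error; ties prefer the larger value
  (stronger damping, more local model). Large alpha approaches 1-NN.
* **PLSDA latent variables** — grid 1–10, ties prefer fewer (simpler
  model). Scores are NIPALS-orthogonal by construction and checked to
  1e-8.
* **V-WSP threshold** — |r| = 0.95; retained descriptors are pairwise below
  it, every removed descriptor correlates at or above it with some retained
  one. The walk starts at the descriptor with the highest mean absolute
  correlation (removing the densest redundancy first); ties break
  lexicographically so the result is column-order invariant.
* **GA-VSS** — population 30, 100 generations, crossover 0.5, per-gene
  mutation 0.01, chromosome cap 15, elitism 1, fitness = CV NER under
  5-group venetian blinds. Because per-gene mutation flips many more
  off-genes than on-genes, the search drifts toward the size cap; a final
  greedy backward-elimination pass (`refine = TRUE`) therefore drops
  descriptors whose removal does not lower the CV fitness, in the spirit of
  the hybrid GA/stepwise selection strategies of the QSAR literature. Among
  final chromosomes tied on NER, the one with the smallest |Sn − Sp| is
  reported, mirroring the "balanced sensitivity/specificity" criterion.
* **Applicability domain** — consensus-path molecules must pass both
  branches by default: leverage h = tᵀ(TᵀT)⁻¹t in PLSDA score space with
  h* = 3·nLV/n (the usual QSAR convention; mean training leverage is
  nLV/n), and average N3 similarity above the 5th percentile of the
  training self-similarity distribution (percentile configurable).
  Gate-path molecules are in-domain by definition.

## Scaling and coding conventions

Autoscaling uses the sample (n − 1) standard deviation. Range scaling maps
the training range to [0, 1] and clips new values into it, which keeps the
N3 average Euclidean distance — and hence the similarity s = 1 − d — inside
[0, 1]. PLSDA codes classes as two centred dummy columns; a sample at the
training centroid receives the class priors as predicted responses, which
under balanced classes is an exact tie and a rejection. Exact ties
(similarity ranks, class scores, predicted responses) are never broken
arbitrarily: tied ranks get the average rank of the tied block, and tied
class decisions become not-assigned.

## Validation machinery

Venetian-blind CV assigns sample i (0-based, stored order) to cancellation
group i mod G, G = 5 by default. The stratified train/test split allocates
per-class test counts by largest-remainder rounding of the proportional
shares — for 649 molecules split 435/214 with a 161-molecule test set this
gives exactly 108 sweet and 53 non-sweet test molecules. Monte Carlo
validation repeats stratified 80/20 splits (1,000 iterations in the
reference analysis; the test suite and acceptance script use 100 to keep
runs short), refits per iteration and pools all out-of-sample predictions
into a single cumulative report. The refit scope keeps the cluster
references and gate thresholds fixed from the initial analysis and refits
only the consensus classifiers, because the thresholds are part of the
frozen system definition; a full-refit mode exists for studying gate
stability.

## The synthetic generator

`generateSyntheticDataset()` emulates exactly the features the method
relies on: (i) two planted clusters whose members share a scaffold block of
200 bits plus 50 private bits, giving within-cluster average distances well
inside the 0.6/0.8 gates while unrelated molecules (250 random bits) stay
far outside; (ii) a sweet-majority class balance (150 sweet / 150 non-sweet
by default across clusters and remainder); (iii) a descriptor table with 6
informative descriptors shifted by 1.5 SD in the sweet class among 94
nuisance descriptors generated in correlated blocks (ρ = 0.7, block size
10) to exercise V-WSP and block-wise selection. Defaults were chosen once
to represent a realistic planted-signal regime at a desk-scale n = 300.

What the generator does **not** emulate: real fingerprints are sparse and
hierarchically correlated rather than uniformly random; real descriptors
are heavy-tailed, collinear across blocks and carry nonlinear class
structure; and real taste labels are noisy (concentration-dependent,
panel-dependent). Passing tests on the fixture therefore demonstrate that
the machinery is implemented correctly — cluster recovery, selection
recovery, estimator agreement — not that any particular accuracy will be
achieved on real molecules.

## Numerical choices

* Distances for N3 are computed from explicit coordinate differences, not
  the inner-product expansion, so that geometrically tied neighbours remain
  exactly tied and receive the same average rank as a direct computation.
* Classical MDS clips negative eigenvalues to zero for explained-variance
  accounting; eigenvalues below 1e-8 of the largest count as zero rank, and
  requesting more dimensions than the rank pads zero coordinates with a
  warning.
* The feature hash is a polynomial string hash modulo 2³¹ − 1, exact in
  double arithmetic and platform-independent.
* Curation is idempotent; within a duplicate group the first record is
  retained and every merge/removal is written to the curation log.
* V-WSP duplicate detection at threshold 1.0 uses a 1e-12 tolerance on
  |r|, below which double-precision correlations of distinct columns are
  not distinguishable from 1 anyway.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen as
representative rather than exhaustive: n = 300 molecules, 100 descriptors,
2,048-bit fingerprints, 30 GA generations for the recovery experiment, 100
Monte Carlo iterations, 200 random fixtures for the N3 1-NN limit, 100
random matrices for the V-WSP post-conditions. Every quantity the
acceptance script reports is computed at run time from these inputs.

## Known limitations

* Molecular descriptors are consumed as input; the package does not compute
  the thousands of constitutional/topological descriptors of commercial
  packages, and fingerprints are not bit-compatible with any of them.
* The gate references require a training set in which sweet clusters are
  discoverable (k-medoids on a 2-D MDS embedding with silhouette-chosen k);
  on small or homogeneous training sets no reference qualifies and the
  system degrades, by design, to the pure consensus.
* Two-class output only: tasteless and bitter are merged into non-sweet,
  and relative sweetness magnitude is out of scope.
* Protein sweeteners and 3D/conformational effects are out of scope; the
  representation is deliberately conformation-independent.
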