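---
title: "Gene-set binary networks for single-cell potency: models, choices and limits"
author: "scPotency maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set binary networks for single-cell potency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by **scPotency**,
the tunable parameters and the rationale behind every numerically open
choice. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The problem and the model

Developmental potency — how many distinct cell fates a cell can still
reach — is an *absolute* property, unlike pseudotime, which is only
meaningful within one dataset. scPotency predicts, per cell, one of six
ordered broad categories (differentiated, unipotent, oligopotent,
multipotent, pluripotent, totipotent) and a continuous potency score on
[0, 1], from nothing but a genes × cells expression matrix.

The classifier is a bank of six *gene-set binary networks* (GSBNs), one
per category. The defining constraint is that the first layer's weights
are binarized on every forward pass, so each hidden unit **is** a gene
set: interpretability is architectural, not post hoc.

### Input encodings

Input counts (or CPM/TPM) are mapped to a fixed feature space via a gene
dictionary (ortholog pairs plus ortholog-less singletons; aliases
resolved first, features absent from the input zero-filled), then
converted to two complementary encodings:

* `L = log2(1 + x/colsum * 1e6)` — retains magnitude information;
* `R` — per-cell ordinal ranks, rank 1 for the highest-expressed gene.
  Ranks are invariant to per-cell scaling, dampen outliers and batch
  effects, and regularize the model.

Open numerical choices here, fixed once:

* **log pseudocount = 1**, so zeros stay exactly 0;
* **rank ties broken by ascending feature index** (ordinal ranks); every
  column of `R` is then a full permutation of 1..N and all-zero genes
  deterministically fill the deepest rank block. Any tie rule would do
  statistically; this one is reproducible across platforms;
* duplicate input symbols (and post-alias collisions) are **summed**,
  which conserves total signal;
* CPM vs TPM are both treated as "scale each cell to 1e6": gene-length
  correction is upstream of this package.

### Enrichment scores

Each module holds M gene sets in the binarized matrix `W^B`. Two scores
are computed per cell and set:

* **Rank-based score.** With per-set size `S` and trimmed ranks
  `T = min(R, τ)`:
  `Score_U = 1 + [S(S+1) − 2 Σ_i T_i W^B_i]/(2τS)`.
  It equals 1 exactly when the set occupies the top S ranks and attains
  its minimum `(S+1)/(2τ)` when every set gene is trimmed. The cutoff is
  parametrized as `τ = 10 + max_j S_j + 1000·max(0, τ_m)` with learnable
  `τ_m`, which guarantees at least ten informative ranks beyond the
  largest set; τ is rounded to the nearest integer since it is used as a
  rank.
* **Background-subtracted score.** Mean `L` of the set genes minus the
  mean `L` of their expression-matched background genes. The background
  map ranks genes by reference mean log expression, partitions them into
  24 equal bins, and for each gene samples `~Normal(n_sample,
  n_sample(s_bin − n_sample)/s_bin)` same-bin genes (rounded, clamped to
  [1, s_bin − 1], self excluded) without replacement. Background genes
  are counted with multiplicity when shared between set members. One
  subtlety: the map's rows list the backgrounds *of* each gene, and the
  score must aggregate the backgrounds of the *set* genes — i.e. the
  transpose of the map acts on `W^B`. The package uses the orientation
  that satisfies the defining property "set genes at expression 2, their
  backgrounds at 1, score = 1", which the test suite asserts.

At the reference scale the background size is n_sample = 100; for small
fixture feature spaces the package scales it down (N/48, keeping bins
larger than the sample size) so the variance formula stays positive.

Scores are standardized per column. During training the batch mean and
biased variance are used and running statistics are updated with
momentum 0.1 (ε = 1e−5, no affine parameters); at inference the stored
statistics are applied unchanged, so predictions are dataset-independent
and deterministic.

### Integration and outputs

Normalized scores pass through a per-module linear enrichment layer
(weights `V`, length 2M; a scalar bias initialized at 0 — the shared
output layer is plain concatenation of the six module logits, with no
extra mixing weights). Softmax (with max subtraction) yields the
likelihood matrix `P`; `ŷ = argmax`; and the raw potency score is
`RPS = P·t` with `t = [0, 0.2, 0.4, 0.6, 0.8, 1]`. RPS is a convex
combination of the anchors, hence always in [0, 1].

## Training

* **Loss** `J = J_S + Σ_w v_w CE_w`. The size penalty
  `J_S = aλ Σ_p ||(1/N)(W^B)ᵀW^B ⊙ I||_F`, `a = √12/√M`, shrinks gene
  sets; its diagonal entries are `S_j/N`, and the √12/√M factor makes
  equally sized sets contribute independently of M.
* **Hierarchical weights** `v` give equal total mass to every broad
  category, to every phenotype within a category, and to every dataset
  within a phenotype; `Σv = 1`. Batches are also *sampled* with these
  probabilities (both mechanisms are used, per the method's design);
  within a batch the weights are renormalized so the loss magnitude does
  not depend on batch size.
* **Binarized backprop.** Gradients w.r.t. `W^B` pass straight through
  to `W` inside the hardtanh linear region (|W| ≤ 1) and are zeroed
  outside. All other gradients (through both enrichment scores, the
  set sizes, τ, the batch normalization and the enrichment layer) are
  derived analytically; the test suite verifies them against central
  finite differences on a continuous relaxation of `W^B`.
* **Optimizer.** NAdam at lr = 0.001 with library-default parameters
  (β = 0.9/0.999, ε = 1e−8, momentum decay 0.004). The optimizer state
  persists across epochs; this is the package's reading of "cross-epoch
  gradient accumulation" — the momentum memory is what dampens binary
  weight flips.
* **Initialization.** `W ~ Normal(−0.1, 0.055²)` (≈3.45% of genes start
  selected, ≈500 of 14,271 features per set); `τ_m ~ Uniform(0, 1)` per
  module; `V ~ Uniform(±1/√(2M))`.
* **Schedule.** Batch size 1024, up to 100 epochs, checkpoint with the
  best hierarchically weighted validation F1 after epoch 15. An epoch
  contains `max(ceil(C/batch), 5)` optimizer steps: when the training
  set fits inside a single batch the floor keeps the total update count
  meaningful (500 instead of 100 steps at desk scale) while changing
  nothing for data spanning many batches.
* **Validation split.** One held-out dataset by default; any labelled
  split (e.g. a held-out clade) can be passed instead. Granular 24-level
  labels are carried through for evaluation only; the loss uses broad
  categories.
* Dropout (rate 0.5) is applied to the normalized scores, after
  standardization and before the enrichment layer, in training mode only.

Ensembles average member likelihood matrices entrywise and recompute
`ŷ` and RPS from the average.

## Postprocessing

1. **Markov diffusion.** Pearson similarity between cells over the
   top-1000 highest-dispersion genes (dispersion = variance/mean of `L`
   per gene; genes with zero mean excluded), negative similarities
   clipped to 0, rows normalized; then Jacobi iteration of
   `s ← 0.9·P_M·s + 0.1·RPS` to L∞ tolerance 1e−5 (cap 10,000
   iterations). The result is elementwise bounded by the RPS range.
   Zero-variance cells keep an identity row; fully constant input falls
   back to RPS with a warning. For very large datasets block-wise
   diffusion over ≤10,000-cell blocks is available (off by default).
2. **Binning.** Within each predicted category p, cells are ranked
   ascending by smoothed score (ties by cell index) and placed at
   `(p−1)/6 + r/((r_max+1)·6)` — strictly inside the category's sixth,
   so the implied category is unambiguous and the within-category order
   is preserved exactly.
3. **Adaptive k-NN smoothing** (only when C > 100). Cells are
   standardized per cell, projected to the top 30 PCs (deterministic
   sign convention: the largest-magnitude loading of each component is
   positive), and Euclidean distances to each cell's 30 nearest
   neighbours are rescaled to unit maximum — so the 30th neighbour gets
   weight 0. Neighbourhood size: compare group A = {self, c1..cm} with
   group B = {c(m+1)..c(2m+1)} by the category implied by their
   unweighted mean scores; the first concordant pair sets k = 2m+1; if
   none occurs before the group size reaches 15, k falls back to 3. The
   final score is `Σ s_c (1−d_c)² / Σ (1−d_c)²` with the centre cell at
   d = 0, and the category is re-read from the final score.

Score-to-category intervals are left-closed, right-open sixths, with a
score of exactly 1 mapping to totipotent.

The small-k bias towards the centre cell is what preserves rare states:
a five-cell island of high-potency cells inside a differentiated
background keeps its category because concordance is reached within the
island (the suite verifies this fixture). When states rarer than five
cells matter, skip the k-NN step by raising `knnConfig(minCells = ...)`
above the dataset size (or set `postprocess = FALSE` to inspect raw
scores).

## Evaluation metrics

* **Weighted Kendall τ** with τ-b tie correction; pair weight = product
  of cell weights. Ground truth is maturity-coded (less mature = lower
  rank), so predictions are negated before comparison. The default
  "balanced" scheme gives each truth level equal total weight split
  uniformly among its cells — a stated substitute for dataset-specific
  weight tables that are not part of this package. P-values use the
  classical normal approximation with the unweighted pair count; treat
  them as a guide, not an exact test, under heavy weighting.
* **Mean multiclass F1**: one-vs-rest F1 per truth category, averaged
  over categories present.
* **MAE** on category codes 1..6, averaged within truth categories and
  then across them.
* The early-stopping metric is different by design: F1 per
  (phenotype, dataset) pair, averaged up the hierarchy.

## The synthetic-data generator

The generator emulates the structure the model assumes: six categories,
each with a disjoint planted marker program (default 20 genes,
4-fold up-shift in its own category only), two phenotypes per category
with milder private programs (10 genes, 2-fold) nested in two datasets,
lognormal library sizes (mean 2000, sdlog 0.3), negative-binomial counts
(size 2) and 20% extra dropout — realistic magnitudes for a
droplet-based experiment at desk scale. The default fixture is 1200
cells × 500 genes; the marker count satisfies 0.8 × markers ≤ 0.05 × N
so that top-5% recovery checks are well-posed.

What the generator does **not** emulate: continuous differentiation
trajectories (categories are discrete), batch effects beyond library
size, doublets and ambient RNA, correlated marker modules, or any real
organism's marker identities. Passing tests therefore demonstrate
correct mechanics and recoverability of planted structure — not
performance on real atlases, which requires the real training corpus.

Robustness utilities implement the perturbations used to probe such
models: Gaussian rank-distance label noise (`P(i|j) ∝
exp(−(j−i)²/2σ²)`, rows normalized; σ calibrated by root-finding so the
expected changed-label fraction hits 5/10/20/50/80% targets — the
uniform-kernel ceiling is 5/6; the label distribution π defaults to
uniform, which the method leaves open), per-cell gene-count and UMI
downsampling (seeded tie-breaking at the threshold; cells below the UMI
target untouched), and phenotype rarity titration.

## Problem sizes and determinism

The test suite trains one default-configuration model on the 1200-cell
fixture (~2–3 minutes on one CPU) and several miniature models
(200 genes, ≤20 epochs); the acceptance script trains one default model.
These sizes were chosen as the smallest at which the planted structure
is comfortably recoverable. Every stochastic step — simulation,
initialization, batch sampling, dropout, background sampling,
perturbations — derives from a single user seed; training twice with the
same seed reproduces checkpoints bitwise, and inference is seed-free
deterministic. Model archives are JSON with 17-significant-digit
numbers, so save/load round-trips are exact.

## Known limitations

* The shipped dictionary builder is exercised with synthetic fixtures;
  the full curated human/mouse dictionary is an external asset and is
  not downloaded by this package.
* Single-nucleus data, batch integration and trajectory inference are
  out of scope.
* The adaptive k-NN iteration is a reconciliation of a heuristic whose
  published description is ambiguous between two group layouts; the
  implemented scheme matches both printed anchor cases (k = 3 fallback,
  maximum group size 15). Whether group means should be weighted is
  likewise unstated; unweighted means are used.
* Negative markers are ranked by ascending signed importance (not by
  magnitude), a choice the interpretation functions document.
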