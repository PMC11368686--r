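---
title: "Contrastive spatial reconstruction: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive spatial reconstruction: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dissociated single-cell RNA-seq (SC) measures expression but destroys
position. Spatial transcriptomics (ST) keeps position, but single-cell
platforms profile few genes and sequencing platforms pool several cells per
spot. `spatialcontrast` trains an encoder on an ST reference so that
physically proximate cells receive similar latent representations, then
applies that encoder to SC queries to reconstruct their spatial
relationships: who neighbors whom, a 2-D pseudo-space, and an assignment of
each query cell to a reference coordinate with a confidence score.

The core assumption is *not* that nearby cells have similar raw expression
— in real SC data, cell-state programs unrelated to position (cycle,
metabolism) dominate raw similarity. The assumption is weaker: a
representation exists under which spatial proximity implies similarity, and
it can be learned from an ST reference by contrastive training.

## Model and training objective

The network is an encoder–projector pair, both multilayer perceptrons. Each
encoder layer is linear → batch normalization → leaky ReLU (slope 0.01);
default widths (1024, 512). The projection head is linear → ReLU → linear,
widths (256, 128); it exists only to host the training loss and is
discarded afterwards, because the encoder output generalizes better than
the projection that was optimized to be invariant.

A training batch of size $N$ (default 64) holds $N/2$ anchors drawn without
replacement and, for each anchor, one positive partner sampled uniformly
from its $k$ spatial nearest neighbors in the reference ($k$ = 80 for
single-cell-resolution references, 20 for spot references, reflecting their
spatial granularity). Every batch member serves once as the query $q$; its
partner is the positive key $k_+$ and the remaining $N-2$ members are
negatives. With row-wise L2 normalization (so dot products are cosines) the
per-sample infoNCE loss is

$$
L_q \;=\; -\log
\frac{\exp(q \cdot k_+/\tau)}{\sum_i \exp(q \cdot k_i/\tau)},
\qquad \tau = 0.05 .
$$

Two denominator conventions circulate: summing over the negatives *and*
the positive (the standard form, bounded below by 0) or over the $N-2$
negatives alone (in which case the loss can be negative when the positive
dominates). The package defaults to `with_positive` and exposes
`denominator_mode = "negatives_only"` as an explicit flag, so either
reading is reproducible; the choice does not change the optimum's location,
only the loss scale near it.

Optimization is plain SGD (momentum 0.9, weight decay 5e-4) with a cosine
learning-rate schedule from 0.1, for `epochs` epochs (default 3000). One
epoch partitions all reference cells into anchor sets of size $N/2$ in a
seeded random order, so every cell anchors exactly once per epoch; the
reference paperwork does not pin down an epoch, and this is the least
arbitrary choice. Positive-pair collisions (a sampled positive equal to
another anchor) are allowed — excluding them would bias sampling toward
sparse regions. All randomness (initialization, anchor order, positive
draws) flows from one integer seed; two runs with the same seed on the same
machine are bit-identical. Batch-normalization statistics are frozen at
inference, and no dropout is used.

The encoder/projector, backpropagation and the SGD loop are implemented
directly in base-R matrix algebra. Gradients of every parameter group were
verified against central finite differences (relative error below 2e-7);
the vectorized infoNCE is tested against a naive double-loop implementation
to 1e-6 on full-size batches.

Two practical notes. Inputs are library-size log-normalized
(`log_normalize()`: per-cell scaling to the median library, then
`log1p`); pooling-based size-factor estimation is treated as an upstream
concern, and pre-normalized data pass through with `is_lognorm = TRUE`.
When the input panel has fewer genes than the first encoder layer is wide,
that layer is shrunk to `min(1024, 4 * n_genes)` — a 100-gene panel does
not need a 1024-unit first layer; the shrink is logged.

## Inference

Given representations $R$, the package offers:

* **Query–query neighbors** (`predict_neighbors()`): the $k$ highest
  cosine similarities per cell, self excluded, ties to the lower index.
* **Pseudo-space** (`mds_embed()`): metric MDS on $d_{ij} = 1 -
  \cos(R_i, R_j)$ by SMACOF stress majorization. The configuration starts
  from classical scaling, which is deterministic and essentially optimal
  for near-Euclidean dissimilarities; a seeded random start is kept only as
  a fallback for degenerate inputs. This deviates from a random
  seeded start on purpose: determinism comes for free and the stress is
  never worse.
* **Reference alignment** (`weighted_similarity()`,
  `map_to_reference()`): the query-to-reference similarity
  $s_{i,j} = \cos(R_i,R_j) + \tfrac1K \sum_{k=1}^{K}
  e^{-(1-\cos(R_i,R_k))^2} \cos(R_k,R_j)$, where $R_k$ runs over the $K$
  nearest query-side neighbors of cell $i$, the cell itself counting as its
  first neighbor. $K=1$ therefore uses no smoothing and reduces to twice
  the plain cosine — the per-row argmax is unchanged, which is why $K=1$ is
  the benchmark default; larger $K$ trades clumping against global-rank
  fidelity. Each cell is assigned the argmax location (ties to the lower
  index); several cells may share a location ("clumping"), which is
  reported, not repaired — point-repulsion post-processing is out of scope.
* **Confidence scores** (`confidence_scores()`): for each query cell, up
  to `n_top` (20) reference locations are selected greedily in descending
  similarity under a mutual-exclusion rule — a candidate inside the spatial
  `m_exclude` (80) nearest-neighborhood of an already selected location is
  skipped, and vice versa. The similarity softmax over the selected
  locations gives probabilities $p$, the Shannon entropy $H = -\sum p\log p$
  (natural log), and the confidence $C = 1 - H/\max(H)$ with the maximum
  over the current query batch. A cell with all plausible locations in one
  spatial pocket scores high; the most ambiguous cell scores 0. If every
  entropy is zero all confidences are set to 1; cells with fewer than two
  selectable locations get `NA` and a flag. The printed index conventions
  for this score are internally inconsistent in the source description; the
  implemented reading — softmax over selected ST locations for a fixed SC
  cell — is the only one consistent with assigning SC cells to ST
  locations.
* **Gene contributions** (`gene_contribution()`): the sensitivity
  $C_{ij} = \lVert R_i - R_i^{(j)}\rVert_2 / \varepsilon$ where
  $R_i^{(j)}$ encodes the cell with $\varepsilon = 0.01$ added to gene $j$
  only. For a linear encoder this is exactly the per-gene weight norm,
  which is the closed form the tests assert.

## Evaluation metrics

* **Neighbor hit**: per cell, the overlap between predicted and true
  spatial $k$-neighborhoods (true neighbors by Euclidean distance, self
  excluded), averaged over cells, for $k = 20, 40, \dots, 200$. A uniformly
  random predictor scores $k^2/(n-1)$ in expectation (hypergeometric mean),
  which the package uses as the analytic baseline. The "average hit ratio"
  is reported as mean hit divided by $k$.
* **Neighborhood JSD** ($k=20$): Jensen–Shannon *distance* between the
  cell-type composition of predicted and true neighborhoods, natural log,
  so values lie in $[0, \sqrt{\ln 2}]$ (a base-2 option rescales to
  $[0,1]$). Per-type summaries group by the focal cell's type, matching the
  one-value-per-type presentation convention.
* **Global Spearman**: per cell, the rank correlation between its
  predicted and true distance vectors to all other cells; invariant under
  rotation, translation and uniform scaling of either coordinate set.
  Cells with constant distance vectors are excluded and counted.
* **Shuffled-location null** (`shuffled_null()`): any of the above
  recomputed under seeded random permutations of the true locations — the
  no-signal baseline a real effect must beat.

## The synthetic tissue generator

`generate_spatial_dataset()` builds the test bed the pipeline is validated
on: cells uniform in the unit square; `n_zones` Voronoi regions around
seeded centers provide discrete cell-type programs (about 30% of genes per
zone carry a log-scale effect of ~1.2); eight Gaussian bumps with
length-scale `smoothness` (default 0.15) provide continuous gradients on
half the genes; three dense non-spatial latent factors (default loading SD
`nuisance = 1`) model cell-state variation unrelated to position; and
per-entry noise follows a gaussian (relative SD `dispersion = 0.8`,
truncated at zero), Poisson, or negative-binomial model. `make_query()`
redraws factor scores and noise at the same (optionally jittered) positions
— an independent section of the same tissue — and `bin_to_spots()` pools
cells on a regular grid into spot-resolution references, conserving counts.

The nuisance factors deserve emphasis. Without them, raw log-expression is
spatially smooth enough that even a randomly initialized encoder recovers
many true neighbors, and "training helps" would be untestable. With
non-spatial variation on the order of the spatial signal — the realistic
regime for dissociated cells — a random encoder sits near the analytic
random baseline (hit@20 ≈ 1 at $n=800$) while the trained encoder reaches
≈ 10 on the reference and ≈ 3 on an independent replicate. Defaults were
fixed once at this realistic operating point. What the generator does
*not* emulate: platform-specific noise (optics, segmentation errors,
spatial capture bias), batch effects between reference and query, and
unshared cell types; conclusions from passing tests are about the
machinery, not about any particular tissue or platform.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run desk-scale versions of the
study conditions: an 800-cell, 100-gene, 5-zone tissue trained for 300
epochs (the full-scale default is 3000), which takes a few minutes on one
CPU and is already an order of magnitude above the random baseline.
Batch-norm uses eps 1e-5 and momentum 0.1 with unbiased running variance;
linear layers use uniform $\pm 1/\sqrt{fan_{in}}$ initialization; SMACOF
iterates to a relative stress change of 1e-9 (max 300 iterations); cosine
values are clipped to $[-1,1]$ before arccos-free downstream use; zero
expression cells, zero-norm representations, non-finite losses, duplicate
gene ids and gene-order mismatches are hard errors, never silent repairs.

## Known limitations

* SC–ST mapping copies reference coordinates, so clumping compresses
  predicted distances; use the MDS route when the reference is sparse or
  poorly matched.
* The confidence normalization is relative to the current query batch
  ($\max H$), so scores are comparable within one mapping call, not across
  calls.
* Training cost is quadratic in batch size and linear in epochs and cells;
  the base-R implementation is practical to a few thousand reference cells
  at full epoch counts.
* h5ad I/O shells out to the local `python` interpreter with `anndata`;
  CSV and MatrixMarket layouts are native.
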