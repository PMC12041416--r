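---
title: "Identifying spatial domains with multi-view graph fusion"
author: "SpaGraphFusion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying spatial domains with multi-view graph fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpaGraphFusion)
```

# The problem

Spatial transcriptomics assays measure a spot-by-gene count matrix together
with the planar position of every spot. A central analysis task is *spatial
domain identification*: partitioning the spots into spatially coherent
regions with a shared expression identity (cortical layers, tumor regions,
anatomical compartments). Two difficulties dominate: spot-level counts are
sparse and overdispersed, with many technical zeros; and neither spatial
proximity alone nor expression similarity alone delineates domains — layers
are thin and neighboring, while transcriptionally similar spots may sit far
apart.

SpaGraphFusion addresses both by training a multi-view graph convolutional
encoder over two complementary graphs, reconstructing the raw counts with a
zero-inflated negative binomial (ZINB) decoder, and clustering the learned
embedding.

# The model

## Graphs

Two symmetric binary graphs are built over the $N$ spots:

* the **spatial graph** $A^s$ links spots within a radius $r$ of one
  another (Euclidean distance in the platform's coordinate units);
* the **feature graph** $A^f$ links each spot to its $k$ nearest
  neighbors by cosine similarity of normalized expression ($k = 15$ by
  default), symmetrized by union. Cosine similarity ranks the neighbors;
  the stored weights are binary.

Each graph additionally carries an **adaptive adjacency**: a free weight
per stored index (edges plus self-loops) initialized at 1 and updated by
gradient descent while the sparsity pattern stays fixed. This lets the
model strengthen or attenuate individual links as training progresses
instead of trusting the predefined neighborhoods.

## Encoder

All branches use the self-loop-augmented symmetric normalization
$\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$. The spatial and feature
branches propagate with the adaptive reweighting
$H^{(l+1)} = \mathrm{ReLU}\big((A^{adapt} \odot \hat A)\, H^{(l)} W^{(l)}\big)$,
producing $H_s$ and $H_f$. A third, **joint** branch applies one shared
weight stack to both graphs without adaptive reweighting, giving $H_{sj}$
and $H_{fj}$ and the joint embedding $H_j = (H_{sj} + H_{fj})/2$; a
consistency penalty
$L_{con} = \lVert \tilde H_{sj}\tilde H_{sj}^\top -
\tilde H_{fj}\tilde H_{fj}^\top \rVert_2^2$ (rows L2-normalized, so the
Gram entries are cosine similarities) pulls the two views of the shared
branch toward a common spot-similarity structure.

## Fusion

$H_j$, $H_s$ and $H_f$ are combined twice. An **attention head** scores
each view per spot as $e_{iv} = q^\top \tanh(W h_{iv} + b)$, with the
projection and query shared across views, softmaxes the three scores and
maps the weighted sum through one linear layer. A **bounded weighted sum**
$\tanh(c_j)H_j + \tanh(c_s)H_s + \tanh(c_f)H_f$ provides a stable global
counterpart. The final embedding is the mean of the two.

## Decoder and objective

A shared ReLU hidden layer followed by three linear heads maps the final
embedding to per-entry ZINB parameters: $\mu = \exp(\cdot)$,
$\theta = \mathrm{softplus}(\cdot)$ (floored at $10^{-4}$, capped at
$10^4$), $\pi = \mathrm{logistic}(\cdot)$. The reconstruction loss is the
mean negative ZINB log-likelihood of the **raw** highly-variable-gene
counts plus the ridge $\lambda\,\overline{\pi^2}$ that stops the zero
component from absorbing every zero. A **spatial contrastive** term uses
logistic-regression-style attraction/repulsion on cosine similarities of
the final embedding: adjacent pairs are pushed toward similarity, an
equal number of uniformly re-sampled non-adjacent pairs per epoch pushed
away. The total objective is
$L = \alpha L_{ZINB} + \beta L_{con} + \gamma L_{reg}$ with
$\alpha = 1,\ \beta = 10,\ \gamma = 0.1$.

Training is full batch with Adam. The package implements the required
reverse-mode differentiation natively (R/autograd.R): a tape of matrix
operations — including fused ops for sparse adaptive propagation, the
Gram-difference consistency (computed through $d \times d$
cross-products, never materializing an $N \times N$ matrix) and the ZINB
likelihood with analytic $\partial/\partial(\mu, \theta, \pi)$ — each
validated against central finite differences in the test suite.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `radius` | 15 (platform units) | spatial neighborhood; 560 for DLPFC-style full-resolution pixel coordinates, 1.5 on the simulator's unit lattice (8-neighborhood) |
| `k` | 15 | expression-similarity neighbors per spot |
| `hidden_dim`, `embed_dim` | 128, 64 | two-layer encoder widths, each branch |
| `alpha`, `beta`, `gamma` | 1, 10, 0.1 | loss weights |
| `lambda_pi` | 1 | zero-inflation ridge weight |
| `epochs`, `learning_rate`, `weight_decay` | 300, 1e-3, 1e-4 | Adam schedule (full batch) |
| `n_top_genes` | 3000 | highly variable genes retained |

# Design choices where the design was open

* **Adaptive reweighting** (`adaptive_mode`): the adaptive weights multiply
  the normalized adjacency *entrywise* over its own sparsity pattern
  (default `"hadamard"`). Since the adaptive matrix is defined by the same
  non-zero positions as the adjacency, the elementwise product preserves
  that pattern, whereas a sparse-times-sparse matrix product would densify
  it; the `"matmul"` reading is available as a configuration switch. The
  two adaptive matrices (spatial, feature) are independent parameters; at
  initialization (all ones) either mode reproduces the standard normalized
  propagation exactly.
* **Encoder output activation** (`last_activation`): ReLU on hidden
  layers per the propagation rule, linear on the last layer of each
  branch so embeddings are not constrained non-negative.
* **Consistency normalization**: "normalized" embeddings are read as
  row-wise L2 normalization, making the Gram entries cosine similarities
  (bounded and scale-free); the penalty is the squared Frobenius norm
  itself (`consistency_reduction = "sum"`), with a mean (per-$N^2$)
  variant available.
* **Attention granularity**: one coefficient triple per spot (default),
  realizing the shared-query construction at spot-level adaptivity; a
  global (single triple) variant is available.
* **ZINB target and aggregation**: the decoder models *raw* counts (ZINB
  is a count distribution; the encoder input is normalized and
  log-transformed separately), aggregated as the mean over entries for
  size-invariance; dispersion is per spot-and-gene by default with a
  per-gene option.
* **Negative pairs**: the contrastive term needs non-adjacent pairs; they
  are drawn uniformly (excluding edges and self-pairs), as many as there
  are adjacent pairs, re-sampled every epoch from the seeded RNG stream.
* **HVG ranking**: mean-binned normalized dispersion (dispersion =
  variance/mean of depth-normalized expression, z-scored within 20 bins
  of similar mean; at most `M/5` bins so every bin holds several genes),
  ties broken toward the lower gene index.
* **log1p**: whether normalized expression is log-transformed before the
  encoder is a config switch, on by default — the standard choice for
  count-derived GCN inputs, and harmless to the decoder, which consumes
  raw counts.
* **Epochs**: the default is 300 epochs of full-batch Adam. The
  consistency term converges quickly; with much longer schedules the
  contrastive term increasingly compresses the embedding's similarity
  structure, which can blur cluster boundaries, so the default stops once
  the dominant terms have flattened. The schedule is fully configurable
  and the per-epoch component losses are exposed in the returned loss
  trace.
* **Clustering**: Gaussian mixture with equal-shape covariances (EEE), the
  convention of this model family's lineage, with k-means as the
  alternative; $k$ is supplied by the user. Rows are first projected onto
  their top 20 whitened principal components (configurable, 0 disables):
  embeddings trained with a reconstruction likelihood and no size factors
  carry a dominant depth-like direction, and whitening keeps it from
  dominating the mixture's distance geometry — the usual
  reduce-then-cluster practice of this literature.

# What the simulator emulates — and what it does not

`simulateSlide()` produces a unit-spaced lattice partitioned into $K$
spatially contiguous domains (horizontal bands by default, Voronoi
patches optionally). Each domain owns a disjoint set of marker genes
whose negative binomial mean is `fold_change` times the background inside
the domain; all counts are NB-distributed and independently zeroed with
probability `pi_sim`. The defaults — 30×30 spots, $K = 3$, 200 genes, 10
markers per domain, background mean 1, fold change 3, dispersion 1,
dropout 0.4 — give sparsity (≈70% zeros) and overdispersion in the range
of real spot-level data while remaining tractable on one CPU.

The simulator does **not** emulate: spatially smooth within-domain
expression gradients, cell-type mixtures within spots, library-size
variation across spots, histology, or platform-specific spot geometry.
Passing the recovery test therefore demonstrates that the pipeline
recovers planted, contiguous, marker-driven domains under realistic
sparsity — not that it attains any particular accuracy on real tissue.

# Numerical choices

* $\theta$ floored at $10^{-4}$ and capped at $10^4$; decoder linear
  predictors clamped before $\exp$ (±15) and the logistic (±10), with
  pass-through gradients inside the interval.
* Zero expression rows: cosine similarity is treated as −1 (with a
  warning) when building the feature graph; row normalization leaves
  all-zero rows at zero.
* The $x = 0$ branch of the ZINB likelihood mixes the zero mass with
  NB(0) in a numerically safe form; `log σ` terms of the contrastive loss
  are evaluated through `softplus`.
* Ties in neighbor ranking and gene ranking always resolve toward the
  lower index, making every graph and gene selection deterministic.
* All randomness (initialization, negative sampling, clustering restarts)
  derives from a single integer seed; two runs with the same seed
  reproduce the loss trace and labels bit for bit.

# A short run

```{r example, eval = FALSE}
slide <- simulateSlide(sgfSimConfig(seed = 1))
slide <- preprocessSlide(slide)
fit <- trainModel(slide, config = sgfConfig(radius = 1.5, seed = 1))
labels <- clusterEmbedding(fit, k = 3, seed = 1)
scoreClustering(labels, domainLabels(slide))
```

The package's README shows the numbers such a run prints; the test suite
(`tests/testthat/test-acceptance.R`) re-derives them from scratch, and
`scripts/acceptance.R` writes them as a JSON report.

# Known limitations

* Full-batch training holds dense $N \times d$ intermediates and the
  spot-by-gene decoder outputs in memory; it is appropriate up to tens of
  thousands of spots, not for mini-batch or multi-GPU regimes.
* Single slides only: no cross-slice integration, no image features.
* The feature graph costs $O(N^2)$ cosine similarities at construction.
* Metrics assume hard reference labels on the same spot set; spots
  without annotation should be filtered before scoring.
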