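# SpaGraphFusion

Spatial domain identification for spatial transcriptomics by multi-view
graph convolution with learnable adaptive adjacencies, two-strategy
embedding fusion and a zero-inflated negative binomial (ZINB)
reconstruction decoder.

## What it does, for whom

Spatial transcriptomics slides measure a spot × gene count matrix together
with each spot's planar position. Analysts want *spatial domains*:
contiguous tissue regions with a coherent expression identity (cortical
layers, tumor compartments). SpaGraphFusion learns a per-spot embedding
that blends two complementary neighborhood structures and then clusters
it:

* a **spatial graph** `A^s` (spots within radius *r*) and a **feature
  graph** `A^f` (*k* nearest neighbors by cosine similarity of expression,
  *k* = 15), each carrying a **learnable adaptive adjacency** — one free
  weight per edge and self-loop on a fixed sparsity pattern;
* a three-branch GCN encoder: spatial and feature branches propagate with
  `H^(l+1) = ReLU((A_adapt ⊙ D̃^{-1/2}ÃD̃^{-1/2}) H^(l) W^(l))`
  (`Ã = A + I`), while a joint branch applies one shared weight stack to
  both graphs, giving `H_j = (H_sj + H_fj)/2` with the consistency
  penalty `L_con = ‖H̃_sj H̃_sjᵀ − H̃_fj H̃_fjᵀ‖²`;
* fusion of `H_j, H_s, H_f` by a per-spot attention head
  (`e_iv = qᵀ tanh(W h_iv + b)`, softmax over views, linear output layer)
  averaged with the bounded weighted sum
  `tanh(c_j)H_j + tanh(c_s)H_s + tanh(c_f)H_f`;
* a ZINB decoder `(μ, θ, π)` over the raw highly-variable-gene counts,
  trained with the negative log-likelihood of
  `f(x) = π δ₀(x) + (1−π) NB(x | μ, θ)` plus a `λ·mean(π²)` ridge;
* a spatial contrastive regularizer on cosine similarities of the final
  embedding (adjacent pairs attracted, sampled non-adjacent pairs
  repelled);
* total objective `L = α·L_ZINB + β·L_con + γ·L_reg` with
  `α = 1, β = 10, γ = 0.1`, optimized full-batch with Adam. Gradients
  flow through a reverse-mode autodiff tape implemented in the package
  and validated against finite differences.

Embeddings are clustered with a Gaussian mixture (or k-means) and scored
against reference labels with ARI, NMI, homogeneity, completeness and
V-measure.

## Worked example

A synthetic 30 × 30 slide with three planted banded domains, 200 genes
(10 markers per domain at 3-fold enrichment), negative binomial counts
and 40 % dropout — then the full pipeline:

```r
library(SpaGraphFusion)

slide <- simulateSlide(sgfSimConfig(seed = 1))   # 900 spots, 3 domains
slide <- preprocessSlide(slide)                  # filter, HVGs, normalize
fit   <- trainModel(slide, config = sgfConfig(radius = 1.5, seed = 1))
labels <- clusterEmbedding(fit, k = 3, seed = 1)
round(scoreClustering(labels, domainLabels(slide)), 3)
#>   ARI   NMI    HS    CS     V
#> 0.870 0.840 0.840 0.841 0.840
```

The embedding recovers the planted domains closely (ARI 0.870; 41 of 900
spots misassigned). For contrast, the same clusterer applied directly to
the normalized log expression finds essentially no structure at this
noise level (Gaussian mixture ARI 0.031, k-means 0.017) — the graph
structure and the count-aware decoder, not the clusterer, supply the
signal. `lossTrace(fit)` exposes the per-epoch
component losses, `attentionCoefficients(fit)` the per-spot view weights,
and `reconstructExpression(fit)` the denoised (ZINB mean) expression
matrix.

The same pipeline is scriptable from a shell:

```sh
inst/exec/spagraphfusion simulate   --out slide/ --seed 1
inst/exec/spagraphfusion preprocess --in slide/ --out slide.rds
inst/exec/spagraphfusion train      --in slide.rds --out-dir run/ --radius 1.5
inst/exec/spagraphfusion cluster    --embedding run/embedding.csv --k 3 \
                                    --truth slide/labels.csv --out-dir run/
```

Real 10x Visium-style directories (MTX + barcodes/features +
tissue-positions CSV) are read with `readVisium()`; use `radius = 560`
for DLPFC-style full-resolution pixel coordinates and the default
`radius = 15` for other platforms.

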