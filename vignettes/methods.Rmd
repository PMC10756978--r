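---
title: "Methods: PaCMAP gene-similarity-network images for multi-omics classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PaCMAP gene-similarity-network images for multi-omics classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsgsn)
```

## Overview

`omicsgsn` classifies tumour samples from three omics layers — gene
expression, DNA methylation and copy-number alteration (CNA) — by turning
each sample into a small RGB image and training a convolutional neural
network on those images. The key idea is a *gene-similarity network* (GSN):
genes, not samples, are embedded into two dimensions, so that genes with
similar expression profiles across the cohort sit near one another. That 2-D
layout becomes a fixed image template; for every sample, a circular zone
around each gene's position is coloured by that sample's three omics values
for the gene (red = expression, green = methylation, blue = CNA). The CNN
then learns class structure — e.g. Gleason-grade groups in prostate
adenocarcinoma — from the resulting images.

The pipeline is

1. **Preprocess** (`read_omics_table()`, `filter_low_variance()`,
   `normalize_matrix()`, `filter_symbols()`, `assemble_dataset()`),
2. **Embed** the selected genes with PaCMAP (`pacmap_embed()`),
3. **Render** one RGB image per sample (`fit_template()`,
   `render_dataset()`),
4. **Train** the three-block CNN (`build_cnn()`, `train_cnn()`),
5. **Evaluate** (`evaluate_predictions()`: accuracy, precision, recall, F1,
   one-vs-rest AUC).

`run_pipeline()` executes all five stages from one `pipeline_config()`.

## Preprocessing model and choices

Inputs are cBioPortal-style TSV matrices (first column `Hugo_Symbol`, one
column per sample). Only samples present in *all three* omics and in the
label table are analysed; genes are restricted to a supplied
significant-gene list (in the motivating design this list comes from a
mutation-significance analysis such as MutSigCV, which this package does not
re-implement; a fallback selects the top genes of the filtered expression
matrix by variance).

Three decisions here were genuinely open and are worth recording:

* **Variance filter scale.** "Variance below 0.2%" is read as absolute
  variance < 0.002 on a \[0, 1\]-scaled data layer. The filter runs on the
  raw values *before* min-max normalization: per-gene min-max rescaling
  stretches every non-constant row to full \[0, 1\] span and would erase
  exactly the low-variance structure the filter is meant to remove. The
  threshold is a config knob (`variance_threshold`).
* **Normalization.** The three heterogeneous omics are brought onto one
  dimensionless scale with min-max normalization, per gene by default (a
  constant row maps to 0.5); a global variant is available. The rendering
  stage requires values in \[0, 1\] because channel intensity is
  `round(255 * value)`.
* **Symbol validation.** Gene identifiers are validated against a
  user-supplied approved-symbol file rather than a live HUGO service, for
  reproducibility and offline operation.

Missing cells default to dropping the gene row (`drop_gene`), matching a
complete-case design; `impute_zero` is available.

## The PaCMAP embedding

PaCMAP (pairwise controlled manifold approximation) optimizes 2-D
coordinates through three classes of point pairs.

**Graph construction.** For each point \(i\) (a gene, represented by its
row vector across samples), the local scale is
\(\sigma_i = \operatorname{mean}\) of the distances to its 4th–6th nearest
Euclidean neighbours, and neighbour pairs are chosen by the scaled squared
distance
\[
d^2_{ij,\text{select}} = \frac{\lVert X_i - X_j\rVert^2}{\sigma_i \sigma_j},
\]
which adapts the neighbourhood definition to regions of different density.
Scaled distances are used *only* for selection, never during optimization.
Mid-near pairs are sampled per anchor by drawing six distinct points
uniformly and keeping the second closest; further pairs are uniform draws
excluding the anchor's neighbours.

**Losses.** With \(\tilde d_{ab} = \lVert y_a - y_b\rVert^2 + 1\) in the
embedding,
\[
\text{Loss}_{NB} = \frac{\tilde d}{10 + \tilde d},\qquad
\text{Loss}_{MN} = \frac{\tilde d}{10000 + \tilde d},\qquad
\text{Loss}_{FP} = \frac{1}{1 + \tilde d},
\]
summed per class and combined with weights \(w_{NB}, w_{MN}, w_{FP}\).
Neighbour and mid-near losses attract (strictly increasing in \(\tilde d\));
the further-pair loss repels (strictly decreasing). The tests verify the
closed-form values (e.g. \(\text{Loss}_{NB} = 1/11\) at coincident points)
and check the analytic gradient against central finite differences.

**Initialization and optimization.** Coordinates start from the top-2 PCA
projection shrunk by 0.01, and are updated by adaptive-moment (Adam-style)
gradient steps through three phases designed to avoid local optima: phase 1
weights mid-near pairs heavily (decaying 1000 → 3) to establish global
structure, phase 2 holds a minimal-but-nonzero mid-near weight (3), phase 3
sets it to zero to polish local structure.

Several constants are the package's own calibration, since only the
qualitative phase goals are prescribed by the method: per-anchor pair counts
`n_nb = 10`, `n_mn = 5`, `n_fp = 20` (proportionate to the original PaCMAP
description; automatically capped for very small gene sets); phase lengths
`t1 = 100`, `t2 = 100`, `t3 = 250`; constant weights `w_nb = 2`,
`w_fp = 1`; Adam step size 1.0 with decay rates 0.9/0.999 and epsilon 1e-7.
All are arguments of `phase_schedule()` / `pacmap_embed()`. Ties in
neighbour ranking break toward the smaller point index, and the random pair
classes are seeded, so the embedding is bitwise reproducible. The
before/after loss comparison reported by `pacmap_embed()` is evaluated under
the final phase's weights (mid-near weight zero), the objective the
optimizer ends on.

Exact \(O(n^2)\) neighbour search is used deliberately: the embedded objects
are a curated gene panel (tens of genes; at most a few thousand), where an
approximate index would add dependency weight without benefit.

## Image rendering

`fit_template()` maps the embedding into the pixel rectangle inset by
`radius + margin` on every side with one common scale for both axes
(aspect-preserving); a single gene degenerates to the image centre. The
template is fixed once per dataset, so all samples share gene positions.
`render_sample()` paints every pixel within Euclidean distance `radius` of a
gene centre with `round(255 * value)` per channel; pixels covered by
several zones combine channel-wise with `blend = "max"` (default) or
`"mean"`; everything else is background (black). Pixels beyond `radius`
from every gene centre deliberately receive no omics colour — the zone
boundary is a hard cutoff, with no anti-aliasing or distance weighting.

Default geometry is a 32 x 32 px image with radius 3 and margin 2. A small
panel of ~14 genes carries no more spatial information than this, and the
raster size directly drives CNN cost; both are config knobs recorded in the
run manifest, and the CNN accepts any size from 10 px up.

## The CNN

Three convolutional blocks, each with 32 filters of size 3 x 3 (valid
padding, so spatial size shrinks by 2) and ReLU, followed by 2 x 2 max
pooling — stride 1 x 1 in blocks 1 and 2, stride 2 x 2 in block 3 — a
batch-normalization layer, and dropout of rate 0.20 / 0.20 / 0.50; then
flatten and a single dense softmax layer. For a 64-px input the spatial
sizes run 62 → 61 → 59 → 58 → 56 → 28; in general each axis ends at
\(\lfloor (h - 10)/2\rfloor + 1\), so inputs need at least 10 px.

Reading choices where the architecture description is silent: the
"normalized layer" is batch normalization (epsilon 1e-3, running-statistic
momentum 0.9); the loss is categorical cross-entropy over one-hot labels
(softmax classification is the only consistent reading); the dense head is
a single fully connected softmax layer; batches of 32. Training uses Adam
(moment decays 0.9/0.999) at the reference learning rate 0.05 for 80
epochs on a 70/30 split — stratified by class by default, with a flag for
plain random splitting. The per-epoch history reports loss and accuracy
from a clean inference-mode pass (dropout off, running batch-norm
statistics) over the training set and over the validation set; the pipeline
passes the held-out 30% as validation, so the "validation" curves describe
the same samples later summarized by the test metrics.

The conv/pool kernels are implemented as compiled code (im2col + GEMM via
RcppArmadillo) with seeded R-side weight initialization, shuffling and
dropout, making training deterministic for a fixed seed and thread count.

## Evaluation

One-vs-rest confusion counts feed the standard formulas
\(\text{recall} = TP/(TP+FN)\), \(\text{precision} = TP/(TP+FP)\),
\(\text{accuracy} = (TP+TN)/(TP+TN+FP+FN)\),
\(F_1 = 2pr/(p+r)\). *Micro* averaging pools counts across classes before
applying the formulas — for single-label multi-class data this makes
precision = recall = accuracy, which is consistent with a report quoting
one identical figure for all four metrics, so micro is the default, with
macro reported alongside. AUC is the macro-averaged one-vs-rest ROC area
computed from the rank (Mann–Whitney) statistic, ties receiving half
credit; 0/0 divisions are defined as 0 and warned about. The test-suite
oracles are brute-force recounts and exhaustive pair counting, plus an
independent ROC implementation (pROC).

## The synthetic-data generator

Because the motivating cohort (TCGA prostate adenocarcinoma, 499 samples
reduced to 387 complete cases, three Gleason-grade classes, 14 selected
genes) cannot be shipped, `generate_multiomics()` emulates its *shape*: 387
samples in 3 balanced classes; 2000 raw genes per omic of which 14 signal
genes carry class structure; 10% of genes near-constant (to exercise the
variance filter), 5% given non-approved identifiers (to exercise the symbol
filter); and 5% of samples missing from the methylation table so the
complete-case intersection path always runs.

Signal gene \(g\) in omic \(o\) has class-\(c\) mean
\(\text{base}_{g,o} + c\cdot\text{effect}\), Gaussian noise, truncated to
\[0, 1\]; base means are drawn so all class means stay inside the unit
interval. Defaults: `effect_size = 0.25` and `noise_sd = 0.08`, i.e. a
class shift of about three within-class standard deviations per gene per
omic — a strong, clearly recoverable signal, the regime the end-to-end
recovery checks are meant to probe (42 informative gene-channel
combinations make the Bayes error essentially zero). `noise_sd = 0.08`
also puts background-gene variance (0.0064) safely above the 0.002
variance-filter cutoff while near-constant genes (sd 0.005) fall safely
below, so filter counts are deterministic. Class sizes use largest-remainder
apportionment (387 balanced → 129/129/129).

What the generator does *not* model: CNA discreteness, methylation
beta-value distributions, batch structure, gene–gene correlation, or
class-imbalanced noise. Passing the end-to-end checks therefore shows the
machinery is correct and leak-free — not that real-cohort accuracy figures
transfer.

## Reproducibility and numerical conventions

* One global pipeline seed fans out to per-stage seeds via a fixed string
  hash (`stage_seed()`), so stages are stochastically isolated.
* All RNG use is wrapped, leaving the caller's RNG state untouched.
* Ties: neighbour ranking by smaller index; `max.col(ties = "first")` for
  predicted classes; average ranks (half credit) in AUC.
* Degenerate inputs: constant normalization rows map to 0.5; coincident
  embedding points give \(\tilde d = 1\) and finite losses; all-identical
  points fail PCA initialization with a validation error; divergent
  optimization (non-finite loss) aborts naming the iteration or epoch.
* Rendering, embedding and training are bitwise reproducible given the
  config; the run manifest records every effective parameter and per-stage
  seed, and a rerun from the same manifest reproduces the artifacts
  byte-identically.

## Problem sizes used in the checks

The embedding checks run at 10–60 points; the gradient check at 10 points;
the end-to-end recovery and null-control runs use the full default cohort
(387 samples, 2000 raw genes, 14 signal genes, 32 x 32 images, 80 epochs),
sizes chosen to mirror the motivating study's shape at desk scale. The null
control (effect size 0) verifies that test accuracy stays at the
majority-class rate — the standard guard against information leaking from
training to evaluation through the shared template or normalization.

## Known limitations

* The significant-gene selection step is external by design; the fallback
  (top-k by variance) is a convenience, not a mutation-significance method.
* Min-max normalization is sensitive to single outliers per gene; rank or
  quantile scaling could be added behind `normalize_matrix()`.
* The CNN is single-threaded CPU code sized for small rasters and cohorts
  of hundreds; it is not a general deep-learning framework.
* Overlapping gene zones lose per-gene identity under either blend rule;
  with very crowded panels a larger raster (or smaller radius) is the
  remedy.
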