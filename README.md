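# omicsgsn

Image-based integration of three omics layers — gene expression, DNA
methylation and copy-number alteration (CNA) — for tumour-grade
classification, in R.

## The problem and the approach

Multi-omics classifiers must combine data layers with very different scales
and distributions; naive concatenation biases the model toward whichever
layer dominates numerically. `omicsgsn` instead embeds **genes** into two
dimensions with a from-scratch implementation of **PaCMAP** (pairwise
controlled manifold approximation), producing a *gene-similarity network*:
genes with similar expression profiles across the cohort lie near one
another. The embedding defines a fixed image template, and every sample is
rendered as a small RGB image — a circular zone around each gene position is
coloured by that sample's values, **red** = expression, **green** =
methylation, **blue** = CNA. A compact three-block CNN then classifies the
images (the motivating application is Gleason-grade groups in prostate
adenocarcinoma).

PaCMAP selects neighbour pairs by the locally scaled distance

$$d^2_{ij,\mathrm{select}} = \frac{\lVert X_i - X_j\rVert^2}{\sigma_i\,\sigma_j},$$

with $\sigma_i$ the mean distance from $i$ to its 4th–6th nearest
neighbours, and optimizes 2-D coordinates $y$ under three pair losses with
$\tilde d_{ab} = \lVert y_a-y_b\rVert^2 + 1$:

$$\mathrm{Loss}_{NB} = \frac{\tilde d}{10+\tilde d},\quad
\mathrm{Loss}_{MN} = \frac{\tilde d}{10000+\tilde d},\quad
\mathrm{Loss}_{FP} = \frac{1}{1+\tilde d},$$

combined as $w_{NB}\sum \mathrm{Loss}_{NB} + w_{MN}\sum \mathrm{Loss}_{MN} +
w_{FP}\sum \mathrm{Loss}_{FP}$ through a three-phase weight schedule
(mid-near weight 1000 → 3, then 3, then 0) with adaptive-moment gradient
updates from a PCA initialization.

The CNN: three blocks of 32 conv filters (3×3, ReLU) + 2×2 max-pool
(strides 1, 1, 2) + batch normalization + dropout (0.2, 0.2, 0.5), then a
dense softmax; trained with Adam at learning rate 0.05 for 80 epochs on a
stratified 70/30 split. Evaluation reports accuracy, precision, recall and
F1 (micro and macro averaged) and macro one-vs-rest AUC.

Everything is seeded and bitwise reproducible; a synthetic three-omics
generator (`generate_multiomics()`) emulates the shape of the motivating
cohort (387 complete samples, 3 classes, 14 signal genes among 2000 raw
genes) so the whole pipeline is testable offline.

## Worked example

```r
library(omicsgsn)

dir <- tempfile()
sim <- generate_multiomics(synthetic_spec(seed = 101), out_dir = dir)

cfg <- pipeline_config(
  expression       = file.path(dir, "expression.tsv"),
  methylation      = file.path(dir, "methylation.tsv"),
  cna              = file.path(dir, "cna.tsv"),
  labels           = file.path(dir, "labels.tsv"),
  gene_list        = file.path(dir, "gene_list.txt"),
  approved_symbols = file.path(dir, "approved_symbols.txt"),
  out_dir          = file.path(dir, "out"),
  seed             = 202)

report <- run_pipeline(cfg)
report
#> <evaluation_report> (micro) accuracy 1.0000 | precision 1.0000 | recall 1.0000 | F1 1.0000 | AUC 1.0000
glance(report)
#> # A tibble: 1 × 6
#>   accuracy precision recall    f1   auc averaging
#>      <dbl>     <dbl>  <dbl> <dbl> <dbl> <chr>
#> 1        1         1      1     1     1 micro
```

The synthetic cohort plants a class-mean shift of ~3 standard deviations
per signal gene per omic, so a correct implementation separates the three
classes essentially perfectly on the held-out 30%: the report above says
all 111 test samples were classified correctly (accuracy, and therefore
micro precision/recall/F1, equal 1) and every class's one-vs-rest ranking
is perfect (AUC 1). With `effect_size = 0` the same pipeline stays at the
majority-class rate — the null control for leakage. Intermediate artifacts
(embedding TSV, template JSON, per-sample PNGs, training-history CSV,
evaluation JSON, run manifest with all effective parameters and per-stage
seeds) land under `out_dir`.

Each stage is also callable on its own — `read_omics_table()`,
`filter_low_variance()`, `normalize_matrix()`, `assemble_dataset()`,
`pacmap_embed()`, `fit_template()`, `render_dataset()`, `build_cnn()`,
`train_cnn()`, `evaluate_predictions()` — with `tidy()`/`glance()`
accessors and `autoplot()` methods for embeddings, training histories and
rendered images. A thin CLI lives at `inst/cli/omics-gsn.R`
(`simulate` / `run` / `embed` subcommands).

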