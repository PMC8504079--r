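---
title: "Artificial image objects for transcriptome classification: models and methods"
author: "aiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artificial image objects for transcriptome classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk transcriptome profiling yields tens of thousands of gene-level
measurements per sample, far more variables than samples, and the variables
are strongly correlated because co-regulated genes move together
(multicollinearity). Classical biomarker models respond by selecting a
small gene panel, which discards information and makes results sensitive to
the selection step. The artificial image object (AIO) approach sidesteps
selection entirely: every gene becomes a pixel at a fixed coordinate, its
rescaled expression becomes the pixel intensity, and the whole transcriptome
is handed to a convolutional classifier as an image. Because the
gene-to-pixel map is fixed, the same gene occupies the same coordinate in
every sample, so the correlation structure of the data is preserved on the
image plane, and any learned feature can be traced back to the exact genes
under its pixels.

`aiomics` implements this encoding and the protocol around it: expression
preprocessing, deterministic and invertible pixel maps, native 2D and 1D
convolutional classifiers, stratified cross-validation with weighted
multiclass metrics, a dataset-shift diagnostic, survival-based comparison of
classifier calls, and a synthetic cohort generator that makes the whole
pipeline testable at desk scale.

## Preprocessing

Expression is expected as gene-level FPKM (non-negative). The pipeline is:

1. **log2 transform**: `x -> log2(x + pseudocount)`. FPKM matrices contain
   exact zeros, so a pseudocount is required; the default is 1, which maps
   zero expression to zero and is exactly invertible. The pseudocount is
   configurable because no single convention is universal.
2. **Shared gene order**: when several cohorts are combined, only genes
   present in all of them are used. Genes are sorted by chromosome
   (numerically: 1..22, then X, Y, MT, then other contigs alphabetically),
   then transcription start site, then symbol as a deterministic
   tie-break. The sorted list is truncated to the pixel capacity of the
   chosen image layout (for example 16,384 genes for 128x128).
3. **Per-gene min-max rescaling** to the 1-byte intensity range:
   `round(255 * (x - min) / (max - min))` with R's half-even rounding.
   The min/max are fit per gene on the training cohort; external cohorts
   are scaled with the training scaler by default (out-of-range values clip
   to 0..255), or independently if requested, since cross-cohort scaling is
   a genuine design choice. Constant genes map to intensity 0. Per-gene
   scaling means every gene uses the full dynamic range regardless of its
   absolute expression level.

## The pixel map

The gene at 0-based position `i` of the sorted list maps to channel
`i div (H*W)`, then row-major within the channel: row
`(i mod H*W) div W`, column `i mod W`. With 16,384 genes this produces
either one 128x128 grayscale plane (the first 128 genes form the first row)
or four 64x64 channels (the first 4096 genes form the first channel). The
map is injective by construction, `gene_at()` inverts it, and under-full
layouts pad trailing pixels with intensity 0 (`pad_policy = "zero"`;
`"error"` refuses). Flattening any layout in (channel, row, column) order
recovers the same gene-ordered intensity vector, so layout choice changes
only the neighborhood geometry seen by the convolutions, not the content.

## Classifier architecture

The classifier has two branches joined by concatenation:

* a **modified VGG branch**: exactly six 3x3 convolutional stages
  (`conv -> ReLU -> optional pooling`) followed by one 1x1 convolutional
  stage;
* an **embedding branch** over the discrete pixel intensities: each value
  0..255 is embedded in `embed_dim` dimensions and the embeddings are
  average-pooled over the image, which amounts to multiplying the sample's
  intensity histogram by the embedding table. It contributes a cheap
  global summary of the intensity distribution and can be switched off.

After concatenation come exactly four fully connected layers (three hidden,
one output). Binary problems end in a single sigmoid unit (the call is 1
iff p > 0.5, strictly, so p = 0.5 is called 0); multiclass problems end in
a K-way softmax (argmax call, ties to the lowest class index). The 1D
variant applies the same design to the gene sequence directly, with
length-3 1D kernels, treating genes laid out along chromosomes as a
one-dimensional signal.

The stage counts (6 + 1 convolutional, 4 dense) are fixed structural
invariants; everything else is a `model_spec()` parameter. The defaults are
deliberately lean and were chosen for single-CPU training on desk-scale
cohorts:

* filters `4, 4, 4, 4, 4, 4` and a 4-filter 1x1 stage;
* **one average-pooling step after the first stage**, none later;
* dense widths 256, 128, 64;
* embedding dimension 8;
* L2 weight decay 5e-3 (decoupled from the adaptive optimizer update).

Two of these defaults depart from image-classification habit and deserve
their rationale:

* **Pooling is minimal and average, not pyramidal max.** In a natural
  image, objects can appear anywhere, and pooling buys translation
  invariance. In an AIO, position *is* identity: pixel (r, c) is always
  the same gene. Translation invariance is therefore not a virtue but a
  loss of exactly the position-specific information the encoding
  guarantees. Aggressive pooling pyramids collapse distinct genes into
  shared cells before the position-aware dense head ever sees them;
  empirically this costs substantial held-out performance on cohorts whose
  signal lives in specific gene blocks. One 2x2 average-pool keeps compute
  manageable while halving resolution only once; averaging (not max)
  preserves the mean-shift signals that distinguish expression classes.
* **Identity-preserving (Dirac) initialization.** Convolution weights
  start as signed center-tap pass-through filters (+/- pairs across the
  filter bank) plus small noise, so at initialization the convolutional
  branch transmits the image essentially linearly (the +/- pairs survive
  ReLU), and the dense head starts from a ridge-like linear view of all
  genes. Gradient descent then moves the filters away from identity only
  where nonlinear structure helps. With hundreds rather than thousands of
  training samples this markedly improves sample efficiency over random
  initialization, which tends to memorize the training set through random
  features before any coordinated filter structure can emerge.

## Training

Training uses minibatch Adam (configurable learning rate and epsilon,
defaults 1e-3 and 1e-7), batch size 96, 12 epochs, fixed-seed shuffling,
and decoupled L2 weight decay. Inputs are scaled to [-0.5, 0.5]
(intensity / 255 - 0.5) for conditioning. An optional validation split
monitors validation loss and stops early after a configurable patience.
Identical (spec, seed, data, config) reproduce identical weights; a
non-finite loss aborts with a suggestion to lower the learning rate;
single-class training labels are rejected. `repeated_runs()` wraps any
evaluation under a list of slightly perturbed configurations (by default,
consecutive seeds) and reports each metric as mean +- sd, the convention
used for all headline numbers.

## Evaluation protocol

`stratified_kfold()` deals samples class-by-class into k folds (default 5,
the 80-20 split), so folds are disjoint and exhaustive, fold sizes differ
by at most one, and per-class counts per fold differ by at most one.
`cross_validate()` trains a fresh model per fold and **pools** the held-out
predictions before computing metrics once -- every sample is predicted
exactly once, and pooling avoids the small-denominator noise of per-fold
averaging (per-fold accuracies are logged alongside; whether to pool or
average is a genuine protocol choice and pooling is ours).

Binary metrics evaluate the textbook confusion-count formulas exactly, and
AUC is the normalized Mann-Whitney statistic (midranks; ties count 1/2),
which equals exhaustive positive-negative pair counting. Ratios with zero
denominators are reported as `NA`, never silently 0. Multiclass problems
are reported one-vs-rest: per-class "accuracy" is the class recall (the
fraction of true class-c samples called c), class AUC uses the class-c
probability column, and the weighted rows are class-frequency-weighted
averages -- with the consequence, verified algebraically in the tests, that
weighted recall equals categorical accuracy, and that for binary problems
the weighted average equals the overall metric.

`external_test()` implements the generalizability protocol: fit on all
labeled training samples, evaluate on an independent cohort that must share
the training gene order (checked before any training), with the
training-fit scaler applied to the external cohort by default. Alongside
the metrics it reports `diagnose_consistency()`: the Pearson correlation,
across shared genes, of per-gene mean log2 expression in the two cohorts.
Matched cohorts sit near r = 1; values far below 1 indicate platform or
sample-treatment shift and predict degraded transfer.

## Survival comparison

Kaplan-Meier curves are computed from the product-limit estimator and the
log-rank test from observed-vs-expected event counts with hypergeometric
variance (K-group case via the quadratic form over K-1 groups, p-value from
chi-square with K-1 df). Events precede censorings at tied times, the
standard convention. `compare_call_sources()` reproduces the design in
which reference calls (e.g. pathologist consensus) are evaluated on one
subject set and model-produced calls on a disjoint subject set, one
log-rank test each; overlapping sets are a design error. No multiplicity
correction is applied. The implementations are checked exactly against
hand-computed tables and against the survival package on random data.

## The synthetic cohort generator

Clinical breast-cancer cohorts large enough to train these models are not
reproducible at desk scale, so the package ships a generator that emulates
the statistical structure the method assumes, with known ground truth:

* **Block-correlated expression**: genes belong to contiguous blocks
  (default 32 blocks over 4096 genes, i.e. co-expression modules of 128
  genes); each sample draws one standard-normal factor per block and gene
  g in block b has log2 expression
  `mu_g + sigma_g * (alpha * f_b + sqrt(1 - alpha^2) * eps)`, so
  within-block correlation is alpha^2 (default alpha = 0.6) and
  across-block correlation is 0. Baseline means are N(5, 2) on the log2
  scale with per-gene sds uniform on [0.5, 1.5], FPKM-like magnitudes.
* **Planted labels**: a fraction of blocks (default 20%) is informative;
  the latent severity is `s = delta * sum(informative f_b) / sqrt(k)`
  (default delta = 2). The binary label is drawn from a steep logistic
  link on s (default steepness 25, so label noise is about 1%; steepness
  is configurable and delta = 0 degenerates to coin-flip labels); the
  3-class ordinal label thresholds s at delta * qnorm(1/3), delta *
  qnorm(2/3) for balanced classes. All latents and the uniform draws are
  stored, so labels are exactly recomputable -- the generator is testable
  against itself.
* **FPKM synthesis** as `max(2^x - 1, 0)`, so the default preprocessing
  `log2(x + 1)` recovers the Gaussian scale exactly wherever x >= 0,
  making the whole pipeline verifiable end-to-end.
* **Dataset shift**: per-gene means are perturbed with independent
  Gaussian noise calibrated through the attenuation formula
  `sd_noise = sd_mu * sqrt(1 / r^2 - 1)` so that the consistency
  diagnostic between original and shifted cohort lands at a requested
  r (default 0.8, emulating a discordant external cohort; 0.99 emulates a
  matched one), plus a global log2 offset (sd 0.25 by default) emulating
  the coherent library-scaling component of a platform change, which
  leaves the correlation diagnostic untouched. Labels are untouched.
  Replicate cohorts for transfer experiments come from
  `simulate_replicate()`, which reuses the gene population (means, sds,
  blocks) and redraws only the samples -- two cohorts simulated from
  scratch have unrelated gene populations and would disagree at r near 0.
* **Survival**: event times are exponential with hazard
  `lambda * HR^label` (defaults: median ~5 years for label 0, HR = 3);
  censoring is an independent exponential whose rate is solved numerically
  so the expected censored fraction hits the configured rate; times are
  rounded to whole days.
* **Annotation**: genes are assigned to chromosomes in contiguous runs
  with increasing TSS, and both annotation rows and expression columns are
  returned shuffled, so genome ordering is non-trivial but exactly
  recoverable.

What the generator does **not** emulate: realistic co-expression network
topology (blocks are disjoint and equally sized), PAM50-like subtype
structure, count noise or library-size effects, batch effects beyond a
mean shift, or informative censoring. Passing tests on these cohorts
therefore demonstrates that the machinery is correct and that the protocol
detects planted structure at realistic noise levels -- not that any
particular clinical accuracy will be attained on real data.

## Problem sizes used in tests

The end-to-end checks run a 600-sample, 4096-gene cohort (64x64 grayscale
AIOs, or the equivalent 4096-length sequence for the 1D model) through
five-fold cross-validation, a label-permuted control, and the 1D/2D parity
comparison; the dataset-shift experiment trains the
3-class grade model on 300-sample, 1024-gene cohorts over ten seeds and
evaluates transfer on 1000-sample replicates (the ordinal task is the
structurally shift-sensitive one: a coherent latent offset pushes samples
across one of the two grade boundaries); survival calibration uses 200 null replicates
(n = 200) and 100 power replicates (n = 1000). These sizes were chosen so
the full suite trains some two dozen networks in well under half an hour
on a single CPU while keeping the statistical margins of every check
comfortable.

## Numerical choices and degenerate inputs

* Half-even rounding for intensity quantization (R's `round`).
* Constant genes rescale to 0; prefit scalers clip to [0, 255].
* Undefined metric ratios surface as `NA`, and empty confusion tables are
  an error.
* The log-rank variance sum skips event times with a single subject at
  risk; a singular K-group covariance falls back to a pseudo-inverse.
* Probability rows are validated to the simplex within 1e-6 before
  multiclass reporting.
* All randomness (simulation, initialization, shuffling, folds) is
  seed-controlled; there is no hidden global state beyond R's RNG, and
  every public object records the seed that produced it.

## Known limitations

* The native training engine is single-threaded R/C++ and is meant for
  desk-scale cohorts (hundreds of samples, thousands of genes), not for
  the full-size cohorts of the original analyses.
* Only exponential survival and independent censoring are simulated.
* The embedding branch summarizes the intensity histogram; it carries no
  positional information and is of secondary importance on synthetic
  cohorts.
* `read_expression_table()` loads the full matrix into memory; no
  out-of-core path is provided.
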