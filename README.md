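# aiomics

Transcriptome profiles carry tens of thousands of strongly co-regulated
gene measurements per sample — far more variables than samples — so
classical biomarker classifiers start by selecting a small gene panel, at
the cost of discarding most of the data. `aiomics` implements an
alternative that needs no selection at all: the **artificial image object
(AIO)** encoding. Every gene is assigned a fixed pixel coordinate (genes
sorted by chromosome and transcription start site, laid out row-major,
channel-major), its per-gene min–max–rescaled log2 expression becomes the
pixel intensity (0–255), and whole transcriptomes become images that
convolutional neural networks can classify. Because the map is fixed and
invertible, the same gene sits at the same coordinate in every sample, and
any learned feature traces back to the genes under its pixels.

The package is aimed at computational biologists who want to classify
clinical labels — a binary marker such as Ki67 status (dichotomized at the
clinical 20% staining cutoff) or a 3-class ordinal grade such as
Nottingham histologic grade — from bulk RNA-seq, and to evaluate such
classifiers honestly.

For an AIO of height H, width W and C channels, the gene at 0-based
position *i* of the genome-sorted list maps to

    channel = i div (H·W),   row = (i mod H·W) div W,   col = i mod W

so 16,384 genes fill a 128×128 grayscale image (first 128 genes = first
row) or a 64×64×4 color image (first 4,096 genes = first channel). The
classifier is a two-branch CNN: a modified VGG branch of six 3×3
convolution stages plus one 1×1 stage, an embedding branch over the 256
discrete intensities, concatenation, and four fully connected layers
(sigmoid or softmax output). Training, stratified five-fold
cross-validation with pooled held-out predictions, one-vs-rest and
class-frequency-weighted metrics, repeated runs reported as mean ± sd, a
per-gene mean-expression correlation diagnostic for dataset shift,
Kaplan–Meier/log-rank comparison of model calls against reference calls,
and a ground-truth synthetic cohort generator are all included; see the
methods vignette (`vignettes/aio-methods.Rmd`) for the models and the
reasoning behind every default.

## Worked example

Simulate a 200-sample cohort with a planted binary effect, encode it as
32×32 grayscale AIOs, cross-validate the default 2D CNN, and compare the
prognostic value of the model's calls against the true labels on disjoint
subject sets:

```r
library(aiomics)

cfg <- synthetic_config(n_samples = 200, n_genes = 1024, n_blocks = 16,
                        missing_frac = 0, include_survival = TRUE, seed = 7)
cohort <- simulate_cohort(cfg)

ord    <- shared_gene_order(cohort$annotation,
                            list(colnames(cohort$expression$values)),
                            n_selected = 1024)
scaled <- rescale_per_gene(log2_transform(cohort$expression), ord)
pmap   <- make_pixel_map(ord, aio_config(32, 32, 1))
aios   <- build_aios(scaled$scaled, pmap)
gene_at(pmap, c(0, 1, 0))        # which gene sits at row 1, column 0?

spec <- model_spec(input_shape = c(1, 32, 32))
cv <- cross_validate(aios, cohort$truth$binary,
                     function(seed) build_2d_classifier(spec, seed),
                     train_config(seed = 1), k = 5)
cv

lab <- cohort$labels
records <- data.frame(sample_id = lab$sample_id, time = lab$survival_days,
                      event = lab$event)
half <- seq_len(100)
compare_call_sources(records,
  calls_ref   = setNames(lab$ki67[half], lab$sample_id[half]),
  calls_model = setNames(cv$predictions$call[-half], lab$sample_id[-half]))
```

This prints:

```
[1] "G00033"
5-fold cross-validation (pooled held-out predictions)
binary metrics report (n = 200): acc 0.870, AUC 0.969, prec 0.815, rec 0.960, F1 0.882
reference calls (n = 100): chi-square = 18.733, p = 1.503e-05
model calls     (n = 100): chi-square = 13.515, p = 0.0002366
```

Reading the output: pixel (channel 0, row 1, col 0) holds gene `G00033`,
i.e. position 33 of the genome-sorted list — the map is invertible.
The pooled five-fold accuracy of 0.87 and AUC of 0.97 show the CNN
recovering the planted block signal from a 200-sample cohort. In the
survival comparison, both the true labels (on subjects 1–100) and the
model's cross-validated calls (on the disjoint subjects 101–200) separate
the survival curves decisively (log-rank p = 1.5e-5 and 2.4e-4); the
model's calls retain most, though not all, of the prognostic separation of
the reference labels.

A thin command-line front-end (`exec/aiomics`) exposes the same pipeline as
`simulate`, `prep`, `build-aio`, `cv`, `diagnose` and `survival`
subcommands over delimited-text files.

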