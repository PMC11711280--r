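---
title: "Task-relevant autoencoding for multivoxel pattern analysis"
author: "TRACEkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-relevant autoencoding for multivoxel pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TRACEkit)
```

## The problem

Functional MRI decoding datasets are feature-rich and sample-poor: a few
thousand trials over a few thousand voxels, with most of the signal variance
driven by processes that have nothing to do with the experimental task —
scanner drift, physiology, arousal, attention. Unsupervised dimensionality
reduction (PCA, autoencoders) compresses toward whatever explains the most
variance, which in this regime is exactly the task-irrelevant structure.
The result is low-dimensional embeddings, and reconstructions, that are
faithful to the nuisance rather than to the mental states under study.

TRACEkit implements a *supervised autoencoder* that counteracts this: a
fully connected autoencoder with a single tanh hidden layer on each of the
encoding and decoding arms, and a softmax logistic-regression classifier
attached to the bottleneck. The network minimises

$$L = \underbrace{\frac{1}{mn}\sum_{i,j}(\hat X_{ij} - X_{ij})^2}_{L_R}
  \; + \; \alpha \,
  \underbrace{\Big(-\frac{1}{m}\sum_{i}\sum_{c} y_{ci}\log\hat
  y_{ci}\Big)}_{L_{CE}}$$

so the bottleneck must simultaneously support reconstruction of the input
and linear decodability of the class — the classifier term steers the
compression toward task-relevant directions. With $\alpha = 0$ the model
*is* a standard autoencoder, and the implementation guarantees this
reduction exactly: the two families share bit-identical weight
initialisation and batch schedules under a common seed, and the test suite
asserts the loss traces agree bit for bit.

Three matched comparators are provided behind the same
`fitModel()` / `encode()` / `reconstruct()` interface:

* **AE** — the same architecture minimising $L_R$ alone;
* **VAE** — the same layer sizes with a diagonal-Gaussian bottleneck,
  reparameterised sampling during training, posterior mean at evaluation;
* **PCA** — projection onto the top-$d$ principal components of the
  centered training data.

## Outcome metrics

Four test-split metrics quantify what each representation preserves:

1. **Reconstruction fidelity** — mean per-trial Pearson correlation between
   input and reconstruction rows.
2. **Bottleneck classifier accuracy** — top-1 accuracy of an L2-penalised
   multinomial logistic regression trained *after and independently of* the
   main model on the bottleneck activations.
3. **Reconstruction class specificity** — mean within-class minus mean
   between-class pairwise Pearson correlation among reconstructed trials
   (self-pairs excluded). This is the criterion used to pick the optimal
   bottleneck width: it rewards reconstructions that are similar within a
   class and dissimilar across classes.
4. **Reconstruction classifier accuracy** — the same probe trained on
   reconstructions.

Both probe-based metrics have *input-space baselines* (the same probe and
specificity computed on the raw features): a reconstruction that beats its
own input on these measures has actively removed task-irrelevant variance
rather than merely preserved the signal.

Cluster tightness is summarised by a per-class Cohen's d comparing mean
pairwise within-class against between-class Euclidean distances,
standardised by the pooled SD of the two distance samples. Tight clusters
make the signed value negative; summaries report magnitudes (with the
signed values retained) to match the usual presentation of such tables.
The pooled SD is the standard two-sample pooled SD — the source
presentation leaves pooling unspecified, and this is the textbook choice.
Same-class/different-class pair sets exclude self-pairs: including the
trivial self-correlation of 1 would inflate within-class similarity by an
amount that depends on class size.

## Numerical and design choices

* **Optimiser**: Adam, learning rate 1e-3, batch size 128, up to 100 epochs
  with loss-plateau early stopping (relative improvement below `tol = 1e-5`
  over 10 epochs). These are deliberately ordinary, stable settings for
  networks of this size; all are overridable through `modelConfig()`.
* **Hidden width**: 512 for 784-dimensional inputs, `min(n, 1024)`
  otherwise, identical across TRACE/AE/VAE so the comparison is
  complexity-matched.
* **Classifier weight** $\alpha$: default 1 — reconstruction and
  classification on equal footing; it is the single knob trading fidelity
  against task relevance.
* **Output activation**: linear for z-scored tabular data, logistic for
  [0, 1] image data, matching the output range to the input range.
* **VAE KL term**: weight 1, with the KL divergence scaled by $1/(mn)$ so
  it lives on the same per-entry scale as the MSE term; the posterior mean
  is used deterministically at evaluation.
* **Probability clipping**: predicted probabilities are clipped at 1e-12
  inside logarithms, so cross-entropy is never infinite.
* **Post-hoc probe**: multinomial ridge logistic regression (glmnet) with a
  fixed penalty $\lambda = 1$ on $\lambda\sum w^2$, never tuned, identical
  across all models and spaces — metric differences must come from the
  representations. The probe z-scores its inputs with training-split
  moments before fitting (an unconstrained bottleneck can sit at arbitrary
  scale, and a fixed penalty is only meaningful on a common scale), and the
  fit follows a warm-started decreasing lambda path because single-lambda
  multinomial fits are numerically fragile. On very small or unbalanced
  fixtures this fixed penalty is deliberately conservative (it can shrink
  toward the majority class); the tests that verify probe *correctness*
  against a brute-force boundary therefore use a weak penalty explicitly.
* **Degenerate inputs**: zero-variance trials are excluded from fidelity
  with a warning; a zero pooled SD yields an undefined (NA) effect size,
  never an infinity; ties in top-$q$ ranking break by class index; ties in
  optimal-width selection break toward the smaller width (more
  compression).
* **Normalisation**: image data are scaled to [0, 1] by dividing by 255;
  tabular voxel-pattern data are z-scored per feature using training-split
  moments only (`standardizeFeatures()`), the common MVPA practice, which
  also keeps tanh units in their sensitive range.

## The synthetic generator

`generateSynthetic()` produces the class-structured data on which the whole
harness runs offline. Each trial is

$$x = s_p\,\mu_c + s_u\,B u + \varepsilon,$$

a Gaussian class prototype ($s_p$, default 1) plus a shared low-rank
task-irrelevant component (rank 10, scale $s_u = 3$) plus i.i.d. Gaussian
noise (SD 1). The defaults deliberately put most of the variance into the
shared nuisance subspace — with $s_u = 3$ and rank 10 the nuisance carries
roughly 90 times the per-feature variance of the prototypes — because that
is the regime the method targets: purely unsupervised compression at small
$d$ latches onto the nuisance factors, while the supervised objective finds
the class directions. Labels are exactly balanced and the same seed gives
bit-identical output.

What the generator does *not* emulate: spatial autocorrelation between
voxels, temporal drift, heteroscedastic noise, class imbalance, or
non-Gaussian response distributions. Passing tests on this generator
demonstrate the machinery and the ordering of the methods in a controlled
separable-signal + shared-nuisance regime; they do not certify performance
on any particular real dataset.

## Study protocol

`runSweep()` fits every (family, width) cell of a grid — the standard width
grid is 2, 5, 10, 15, 20, 30, 50, 60, 100, 150, 200, 250, 500, 784, capped
at the input dimensionality — and computes all four metrics, both input
baselines (once per dataset; they are width-independent), and the Cohen's d
summaries for bottleneck and reconstruction. `selectOptimalDim()` picks the
width maximising reconstruction class specificity. `runTruncationStudy()`
then removes 10–98% of the training trials by class-stratified uniform
sampling — stratified so the chance level stays fixed and no class empties
at 98% — with 50 independent jack-knife sub-samples at the deepest level,
every family training on the identical retained sample per replicate.
`compareModelsRmAnova()` runs the one-way repeated-measures ANOVA (factor:
model family; units: replicates) per metric with Greenhouse–Geisser
correction — four within-factor levels over 50 matched units make the
sphericity assumption worth correcting — and planned paired contrasts of
the supervised model against each comparator. `runShuffleControl()` trains
the supervised model on label-shuffled data and evaluates effect sizes
under independently shuffled test labels; the expectation is zero, and a
non-zero result would mean the model imposes structure that is not there.
The control is undefined for the unsupervised families, whose losses never
see a label.

The "jack-knife" replicates are independent random sub-samples of the
retained fraction, not leave-one-out: with 50 replicates of 2% of the data,
independent resampling is the only reading that yields a meaningful
between-replicate SD.

## Problem sizes used by the tests and the acceptance script

The packaged checks run at desk scale, chosen once as conditions a
practitioner could re-run on a laptop: the ordering claim uses 10 classes ×
784 features × 120 exemplars per class (~1200 training trials, the deep
truncation regime of the image benchmarks), hidden width 256 and 25 Adam
epochs, over 10 training seeds; the shuffle control uses 200 features with
300 test exemplars per class so the null effect size is estimated with
small bias; oracle checks enumerate all pairs on fixtures of at most 30
trials. The full image-benchmark tier (IDX files, 60k/10k split) is
exercised by the same code paths when the files are present locally.

## Known limitations

* The networks are single-hidden-layer and fully connected by design; no
  convolutional or deeper variants, and no adversarial or mutual-information
  objectives.
* The probe penalty is fixed rather than cross-validated; this is a
  deliberate comparability choice, not an accuracy-maximising one.
* The exact hyperparameters used in the original image/fMRI studies are not
  published in the main text; the defaults here are explicit, ordinary
  stand-ins, and conclusions should rest on within-run model orderings, not
  absolute metric values.
* `classSpecificity()` and `cohensD()` build full pairwise matrices
  (O(m^2) memory); at 10k test trials this is ~800 MB, fine on a
  workstation but worth knowing.

## A worked run

```{r, eval = FALSE}
ds <- generateSynthetic(10, 784, 120, testExemplarsPerClass = 200,
                        seed = 101)
s <- standardizeFeatures(ds$train, ds$test)
grid <- sweepGrid(dims = c(2L, 5L, 10L), seed = 1L, inputDim = 784L)
res <- runSweep(grid, s$train, s$test, hiddenDim = 256L, epochs = 25L)
sweepMetrics(res)
selectOptimalDim(res, "TRACE")
```

The command-line wrapper (`inst/scripts/trace_cli.R`) exposes the same
pipeline as `generate` / `sweep` / `report` subcommands driven by a YAML
configuration; every run persists its configuration and seeds into the
results directory so it can be reproduced exactly.
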