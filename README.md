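# TRACEkit

Supervised autoencoding for multivoxel pattern analysis: extract
low-dimensional, *task-relevant* representations from feature-rich,
sample-poor data — a few thousand noisy voxels, a few thousand trials —
and push the denoised signal back into native input space.

## Who this is for

Researchers decoding cognitive states from fMRI activity patterns (and
anyone working with wide, noisy, labeled matrices) who need dimensionality
reduction that does not chase nuisance variance. Unsupervised compression
(PCA, plain autoencoders) keeps whatever explains the most variance; in
within-subject neuroimaging that is mostly drift, physiology and other
task-irrelevant structure. The model here — TRACE, a *task-relevant
autoencoder via classifier enhancement* — attaches a softmax
logistic-regression head to the bottleneck of a one-hidden-layer
autoencoder and trains on the weighted objective

    L  =  L_R + α · L_CE
    L_R  = (1/mn) Σᵢⱼ (X̂ᵢⱼ − Xᵢⱼ)²          (reconstruction MSE)
    L_CE = −(1/m) Σᵢ Σ_c y_ci log(ŷ_ci)      (categorical cross-entropy)

so the bottleneck must stay linearly decodable while still reconstructing
the input. With α = 0 the model reduces exactly (bit-for-bit in this
implementation) to a standard autoencoder.

The package ships the complete evaluation harness around the model:

* matched comparators — standard autoencoder (AE), variational autoencoder
  (VAE), PCA — behind one `fitModel()` / `encode()` / `reconstruct()` S4
  interface;
* four outcome metrics (reconstruction fidelity, bottleneck classifier
  accuracy, reconstruction class specificity, reconstruction classifier
  accuracy) plus input-space baselines and per-class Cohen's d cluster
  separation;
* bottleneck-width sweeps with optimal-width selection, class-stratified
  data-truncation studies with jack-knife replicates, a shuffled-label
  null control, and repeated-measures ANOVA with planned contrasts;
* IO for IDX image files (MNIST layout) and delimited voxel-pattern
  tables, plus a seeded synthetic generator so everything runs offline;
* a YAML-driven command line (`inst/scripts/trace_cli.R`) with
  `generate` / `sweep` / `report` subcommands.

## Worked example

Ten classes, 784 features, 120 exemplars per class — the sparse regime
where unsupervised compression fails — with most variance placed in a
shared task-irrelevant subspace:

```r
library(TRACEkit)

ds <- generateSynthetic(10, 784, 120, testExemplarsPerClass = 200,
                        seed = 101)
s  <- standardizeFeatures(ds$train, ds$test)

cfg   <- modelConfig("TRACE", 784, 2, classCount = 10,
                     hiddenDim = 256, epochs = 25, seed = 1)
model <- fitModel(cfg, s$train)
model
#> TRACE model: 784 -> 256 -> 2 (+10-class head, alpha=1)
#>   trained 25 epochs, final loss 1.33887

postHocClassifierAccuracy(encode(model, s$train), labels(s$train),
                          encode(model, s$test),  labels(s$test))
#> [1] 0.742

cohensD(encode(model, s$test), labels(s$test))
#> EffectSizeReport (bottleneck): |d| = 2.575 ± 0.458 over 10 classes

classSpecificity(reconstruct(model, s$test), labels(s$test))
#> [1] 0.821
classSpecificity(s$test)
#> [1] 0.016
```

Read: a 2-dimensional supervised bottleneck decodes the 10 classes at 74%
(chance 10%) where AE/VAE/PCA stay near chance on the same data; its
class clusters are separated by |d| ≈ 2.6 pooled-SD units; and its
*reconstructions* are far more class-specific (0.82) than the raw inputs
(0.016) — the model has actively removed task-irrelevant variance, not
just preserved the signal. Sweeps over bottleneck widths, truncation
studies and the shuffled-label control run the same way through
`runSweep()`, `runTruncationStudy()` and `runShuffleControl()`.

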