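---
title: "Screening fluorescence microscopy images for artifacts with a convolutional autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening fluorescence microscopy images for artifacts with a convolutional autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Quantitative single-molecule assays such as sFIDA (surface-based
fluorescence intensity distribution analysis) read out protein-oligomer
concentrations from TIRF microscopy images: 1000 x 1000 pixel, 14-bit
frames in which authentic analyte signals are sparse, sub-resolution point
emitters of widely varying brightness. Any structure that is not such a
point signal -- glue or dust autofluorescence, scratches, motion streaks,
dense agglomerates of otherwise authentic-looking spots -- distorts the
readout, and with hundreds of images per sample manual screening is the
bottleneck. Because the space of possible artifacts is effectively
unbounded, a classifier trained on known artifact classes will miss new
ones. `caeqc` instead learns only what *authentic* images look like: a
small convolutional autoencoder (CAE) is trained exclusively on
artifact-free images to reproduce its input through a bottleneck. Whatever
the model has never seen, it reconstructs poorly, so per-image
reconstruction error becomes an anomaly score and no artifact ever needs
to be labeled at the pixel level.

```{r setup}
library(caeqc)
```

## Preprocessing

Raw counts pass through four deterministic stages
(`preprocess_image()`):

1. **Gaussian blur**, 5 x 5 kernel. Aligns single-pixel intensities with
   their neighborhood, shrinking background variance while multi-pixel
   signals survive. Only the kernel *size* is canonical; the sigma is the
   size-derived convention of the common image libraries,
   `0.3 * ((k - 1)/2 - 1) + 0.8` = 1.1 px for k = 5, and is a parameter.
   Borders are reflective (symmetric padding) so the frame edge gains no
   artificial dark rim that the next stage would interpret as structure.
2. **Background zeroing** at `mean + 5 * SD`, both computed over all
   pixels of the *blurred* image (the blur exists precisely to make this
   threshold stable). Pixels strictly below the threshold become zero;
   pixels at or above it are kept unchanged, so the degenerate constant
   image passes through intact. The SD is the population form (divisor
   *n*); over ~10^6 pixels the choice is immaterial but must be fixed for
   reproducibility.
3. **2 x 2 block-mean reduction**, 1000 x 1000 to 500 x 500. Signals
   survive because the threshold has already zeroed their surroundings.
4. **Normalization to [0, 1]** by the fixed sensor full scale
   `2^14 - 1 = 16383`, *not* the per-image maximum: a per-image divisor
   would rescale every image differently and break the single
   model-plus-threshold applied across a dataset. Non-14-bit sensors are
   handled by the `bit_depth` parameter.

Each stage is checked against a brute-force oracle (dense convolution
loop, two-pass mean/SD, nested-loop block means) to 1e-9 in the test
suite.

## The autoencoder

`cae_config()` defaults to the full-scale architecture:

| layer | kernel, stride | output |
|---|---|---|
| Conv2D, 126 filters, ReLU | 2 x 2 | 500 x 500 x 126 |
| MaxPooling | 2 x 2 | 250 x 250 x 126 |
| Conv2D, 256 filters, ReLU | 5 x 5 | 250 x 250 x 256 |
| MaxPooling | 2 x 2 | 125 x 125 x 256 |
| Conv2DTranspose, 256, ReLU | 5 x 5, stride 2 | 250 x 250 x 256 |
| Conv2DTranspose, 126, ReLU | 2 x 2, stride 2 | 500 x 500 x 126 |
| Conv2D, 1 filter, ReLU | 2 x 2 | 500 x 500 x 1 |

All layers use "same" padding -- the printed shapes (500 -> 500 for a
k = 2 convolution, 125 -> 250 for a stride-2 transpose with k = 5) are
only attainable that way -- and stride 1 wherever no stride is listed,
which the shape arithmetic forces. The 125 x 125 x 256 bottleneck is what
obliges the network to learn the structure of authentic point signals
rather than copying pixels.

Because no deep-learning framework is part of the package's dependency
set, the conv-net engine is implemented in the package itself:
im2col/col2im kernels in C++ with BLAS matrix products, max-pooling with
argmax routing, and Adam. The transposed convolution is implemented as the
exact adjoint of the corresponding strided convolution, a relationship the
test suite verifies directly (`<conv(u), v> = <u, tconv(v)>`), and every
analytic gradient is checked against central finite differences.

Training choices the architecture description leaves open are fixed as:
MSE loss (which makes the training objective coherent with the validation
metric), Adam with learning rate 1e-3, batch size 8, Glorot-uniform
initialization from the configuration seed. Training runs a fixed 8
epochs -- the small model and training set saturate quickly -- and records
per epoch the mean MSE over artifact-free validation images and the
percent difference between artifact-laden and artifact-free mean MSE.
Because the minimal clean MSE does not necessarily give the best
separation, `train_cae(select = "best_pct_diff")` optionally restores the
epoch with the largest percent difference instead of the last one.

## The score and the threshold

The image reproduction error of an image `I` with reconstruction `O` is

> IRE = 99.99th percentile of (I - O)^2 over all pixels,

with linear interpolation between order statistics at rank
`(n - 1) * 0.9999` (`quantile type = 7`, the dominant convention of the
scientific-computing ecosystems). The high percentile is deliberate: a
mean over 250,000 pixels would dilute a small artifact to nothing, while
the 99.99th percentile reacts to ~25 bad pixels yet ignores a handful of
noisy ones. The interpolation convention matters at this rank and is
therefore fixed and documented; with 250,000 pixels, 26 deviating pixels
move the score but 25 do not.

Images are flagged per dataset with an adaptation of the 1.5 x IQR
outlier rule:

> threshold = q50 + 3 * (q50 - q25)

over the IREs of *all* images in the dataset, clean and laden together.
The lower half-spread `q50 - q25` is untouched by the upper tail, so the
threshold stays put no matter how extreme the artifact scores are (the
rule only assumes artifacts are a minority, i.e. below half the dataset);
the usual 1.5 multiplier is doubled because the half-spread is half an
IQR. Classification is strict: an image is artifact-laden only *beyond*
the threshold. A precomputed assay-specific threshold can be supplied
instead, the natural variant when many experiments of one assay share an
IRE level.

## Evaluation

`evaluate_dataset()` reproduces the screening evaluation: a two-tailed
t-test between clean and artifact-laden IREs (Welch by default, since
group sizes and variances differ strongly in practice; the pooled Student
variant is a flag), confusion-matrix metrics with artifact-laden as the
positive class (sensitivity is reported as `NA`, not 0, when the truth
contains no positives), and a balanced-bootstrap ROC analysis: 10,000
subsets by default, each drawing `min(n_clean, n_artifact)` images per
class with replacement, a one-feature logistic regression of label on IRE
fitted per subset, and the trapezoidal AUC of its fitted probabilities
averaged over subsets. The AUC is computed on the subset the regression
was fitted on; for a single monotone feature the fitted probabilities are
a monotone transform of the IRE itself, so the per-subset AUC coincides
with the Mann-Whitney rank statistic whenever the fitted slope is
positive -- a coincidence the tests exploit as an independent oracle. The
regression is unpenalized: with one feature, shrinkage would only distort
the scores.

## The synthetic image generator

Full-scale datasets are microscope images; the package instead ships
a seeded generator (`scene_spec()`, `generate_clean_image()`,
`generate_artifact_image()`, `generate_dataset()`) that emulates their
essential statistics so that the entire pipeline is testable desk-side:

* i.i.d. Gaussian background noise (mean 500, SD 50 counts by default),
  rounded and clipped to the 14-bit range -- background is characterized
  only by mean and SD in the screening procedure itself, so a Gaussian is
  the minimal faithful model; a Poisson variant is a flag.
* sparse point emitters: continuous sub-pixel positions, isotropic
  Gaussian PSF of sigma 1 px, peak amplitudes log-uniform over
  2,000-8,000 counts to mimic the large brightness variability of real
  targets. The amplitude parameterizes the *peak* height, keeping the
  configured range on the intensity scale of the stored image. Default
  density is 150 emitters per 1000 x 1000 frame.
* four artifact classes spanning the qualitative range seen on real
  plates: smooth bright `blob`s (glue/contamination), hard-edged
  `scratch` lines, tapered motion `streak`s, and `agglomerate`s --
  `round(density * extent^2)` individually authentic-looking emitters
  crowded into a small box. Artifacts are rendered additively on the
  noiseless scene *before* noise, so the recorded mask of altered pixels
  is exact. No quantitative size/intensity distributions exist for real
  artifacts; the defaults span the qualitative "small" to "large" range
  and every one is a parameter, not a constant.

`scaled_scene_spec(side)` density-matches these reference conditions to a
smaller frame (emitters scale with area, artifact extents with side,
intensities unchanged). What the generator does *not* emulate: optics-
accurate TIRF physics, camera-specific noise, illumination gradients,
multi-channel data. Passing tests therefore demonstrate that the method
recovers planted artifacts under the stated statistical model of sFIDA
images -- not performance on any particular microscope's data.

## Desk-scale problem sizes

The default test and acceptance configuration runs the whole pipeline at
reduced scale: raw side 256 (so 128 x 128 autoencoder inputs), filters
16/32, 200 clean training images, 8 epochs, 50 clean + 50 artifact-laden
held-out images, 1,000-2,000 bootstrap subsets. These sizes were chosen as
the smallest at which the screening behaves like its full-scale
counterpart -- the model reliably beats the zero-predictor and separates
the held-out classes -- while a complete run stays in the minutes range on
one CPU. The full-scale configuration (500 x 500, filters 126/256) is the
package default and drives the same code paths.

Note one genuine scale effect: at 128 x 128 = 16,384 pixels the 99.99th
percentile sits between the second- and third-largest squared error, so
the desk-scale IRE behaves almost like a per-image maximum; at the native
250,000 pixels it tolerates ~25 deviant pixels. This is inherent to
shrinking the image, not a tunable.

## Numerical and degenerate-input choices

* Constant images pass `background_threshold()` unchanged (SD 0 means no
  pixel is strictly below the threshold).
* `normalize_image()` rejects values above full scale rather than
  silently clipping: upstream clipping is a contract.
* Quantile/percentile routines are `type = 7` everywhere; scores exactly
  at the classification threshold are clean ("beyond" is strict).
* The ReLU output layer can represent the all-zero image exactly, so a
  zero target is trivially learnable -- used as a smoke oracle in tests.
* With very sparse targets and aggressive learning a ReLU output can die
  (collapse to the zero map); at the desk-scale training size of 200
  images this does not occur, but it is the reason the zero-predictor
  comparison is part of the test surface.
* All randomness flows from explicit seeds: per-image seeds derive from a
  dataset master seed, the training shuffle from the model seed, and the
  bootstrap from its own seed, so every published number is replayable.

## Limitations

* Artifacts dimmer than the background threshold are erased in
  preprocessing and cannot be detected downstream -- inherent to the
  background-removal design.
* Agglomerates of well-separated authentic signals may reconstruct well
  and go unflagged; the score grows with the strength and size of the
  deviation, so the misses are the least damaging cases.
* More than 50% artifact-laden images in a dataset would shift the median
  and break the adaptive threshold; use an assay-specific fixed threshold
  in that regime.
* The dataset-level bootstrap AUC is an in-sample statistic per subset;
  it describes separability of the observed IREs, not generalization of a
  classifier.
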