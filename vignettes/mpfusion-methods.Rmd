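---
title: "Methods: quantitative mpMRI mapping and image-clinical fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative mpMRI mapping and image-clinical fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, its tunable
parameters, the design choices that were genuinely open, and what the
synthetic phantom experiments do and do not demonstrate.

## The problem

After a median of roughly twelve months of androgen deprivation therapy,
most advanced prostate cancers progress to castration-resistant disease
(CRPC), with sharply worse prognosis. The package implements a
non-invasive predictor of that progression from data available *before*
therapy: multiparametric MRI (T2-weighted, diffusion-weighted and dynamic
contrast-enhanced series) plus four baseline clinical variables (age,
PSA, Gleason score, clinical TNM stage). The design is a two-stage
multimodal fusion: an image classifier learns from quantitative parameter
maps, and a gradient-boosted classifier fuses its output with the encoded
clinical vector.

## Quantitative parametric mapping

**Enhancement kinetics.** Per voxel of the DCE series, the percentage
signal enhancement is `PSE(t) = 100 (S(t) - S0) / S0`; `S0` is estimated
as the mean of the declared pre-contrast frames (the baseline estimator
is not standardized in the literature; the mean is the obvious unbiased
choice and is documented as such). The empirical mathematical model
`PSE(t) = A (1 - exp(-alpha t)) exp(-beta t)` is fitted per voxel. The
optimizer, starting values and bounds are implementation choices (no
standard exists): bounded Levenberg-Marquardt with an analytic Jacobian;
`A` started at the curve maximum, `alpha` from the time to 90% of
maximum, `beta` from the terminal log-slope floored at 1e-3 /min; bounds
`A` in [0, 10 max(PSE)], `alpha` in [0, 50] /min, `beta` in [0, 10] /min.
A fit whose `alpha` lands on its upper bound is flagged non-converged: a
pinned rate is an artifact, not an estimate. Times are in minutes
throughout, so rates are per minute, the convention of the enhancement-
kinetics literature.

**Relaxometry and diffusion.** T2 (`S = S0 exp(-TE/T2)`, ms) and ADC
(`S = S0 exp(-b ADC)`, mm²/s) are fitted by log-linear least squares with
weights proportional to the squared signal — the variance-stabilizing
weighting that makes log-domain fitting nearly equivalent to nonlinear
least squares at moderate SNR, and exactly equal to the closed form when
only two samples are given. Voxels with non-positive signal, a
non-decaying echo profile, or a negative fitted ADC are flagged invalid
and carry `NA`; invalid voxels are excluded from ROI averages and from
texture inputs so that fit failures never propagate silently.

## Run-length texture mapping

The texture channel is the long-run high gray-level emphasis (LRHGLE) of
the gray-level run-length matrix, computed in a 5x5 sliding window and
assigned to the center pixel. Choices the texture literature leaves open,
fixed here:

- **Quantization**: 16 equal-width bins over the image's observed range.
  Finer binning starves a 25-pixel window (few runs per level); 16 is the
  common radiomics default at this window size. The map is invariant to
  monotone affine relabeling of the input because the binning is.
- **Directions**: runs are counted along 0° and 90° by default and the
  run-length matrix is accumulated over directions before the statistic
  is evaluated (45°/135° available). Accumulation (rather than averaging
  per-direction statistics) keeps the mass-conservation identity
  `sum_j j P(i,j) = pixels x directions` exact and is what the
  brute-force oracle in the tests implements independently.
- **Normalization**: LRHGLE = `(1/Nr) sum P(i,j) i^2 j^2`, the standard
  Galloway-family definition, since no variant is singled out.
- **Borders**: symmetric reflect padding by default so the map keeps the
  input shape (ROI crops are small and border pixels matter); a shrink
  mode maps interior pixels only.

## ROI preparation

Reader agreement is checked with the Dice coefficient; contours with
Dice strictly below 0.80 are flagged for consensus. Masks are drawn on
the T2-weighted grid and transferred to the other (co-registered)
sequences by nearest-neighbor grid resampling only — the prostate's
relatively fixed position makes deformable registration unnecessary for
this purpose, and it is deliberately out of scope.

Samples are assembled per axial slice: bounding-box crop (2-pixel
context margin), per-channel min-max normalization to [0, 1] *within the
crop*, bilinear resize to 224x224, channel stacking. Whether
normalization precedes or follows resizing is unspecified in the
literature this follows; crop-then-normalize-then-resize is fixed here
because it makes the normalization exact (min 0, max 1) on the native
grid and leaves interpolation to the last step. The separate train-time
standardization (per-channel mean/variance of the training set) is kept
distinct and is stored on the trained model.

## The SE-SPP classifiers

The default backbone is a DenseNet-121-style network: 7x7/2 stem with
3x3/2 max pooling, dense blocks of 6/12/24 bottleneck layers (growth
rate 32), each block followed by a squeeze-and-excitation gate
(reduction 16, the original SE-Net default) and a halving transition.
The spatial pyramid pooling layer replaces the final pooling at the
512-channel stage reached after the third transition, with levels
1x1, 2x2, 4x4. That tap point is *derived*, not quoted: 512 x (1+4+16) =
10752 is the only standard DenseNet-121 configuration consistent with
the published feature-vector length, and the acceptance suite measures
exactly that length on a forward pass. The head maps the SPP vector to
two class scores trained with binary cross-entropy (two-score softmax
parameterization). An SE-SPP-ResNet18 with the same head is provided.

All layers and their gradients are implemented in the package
(im2col/col2im convolution kernels in C++, batch normalization, SE, SPP,
dense concatenation, residual blocks); the test suite verifies the whole
backward pass against central finite differences to ~1e-8 relative
error. Optimization is SGD with momentum 0.9 and weight decay 1e-4
(applied to weight matrices, not to biases or normalization parameters),
batch size 48, 50 epochs, initial learning rate 1e-4 (DenseNet) or 1e-3
(ResNet18); the learning rate is halved after 10 epochs without
validation improvement and training stops after 20, retaining the
best-validation weights. Augmentation (a bank of 6 photometric and 8
spatial label-preserving transformations, randomly composed) is applied
to training images only; the minority class is oversampled through the
same bank to parity. Pretrained weights are deliberately not used: the
package favors reproducibility without downloads, and the phantom
studies do not need them.

## Split plan

Patients are shuffled into five near-equal subsets. Each round trains on
four subsets and holds out the fifth, split at patient level between
test (`ceiling(k/2)`) and validation (`floor(k/2)`), i.e. a
0.8:0.1:0.1 ratio. Over the five rounds every patient is held out
exactly once, so test sets are disjoint across rounds and the union of
test and validation patients covers the cohort exactly — for 96 patients,
50 ever tested and 46 ever validated. The even test/validation split of
the held-out subset is a documented choice where the protocol wording is
ambiguous; it is the one that reproduces those published subset totals.

## Two-stage fusion

Stage 1 trains the image classifier alone. Stage 2 freezes it, extracts
each sample's image feature vector — by default the fully connected
head's class-score vector, the literal reading of the protocol; a
pre-head SPP-vector mode is provided because the 2-vector is
information-poor — concatenates the encoded clinical vector
`[age, log10(PSA + 1), Gleason, TNM ordinal]`, and fits an XGBoost
classifier (depth 3, learning rate 0.1, up to 200 rounds, early stopping
on validation log-loss; unstated in the protocol, so fixed defaults with
overrides). PSA is log-transformed because it spans orders of magnitude.
The TNM ordinal is `T + 0.25·[N≥1] + 0.5·[M≥1]`: summing the raw digits
is not invertible (T3N0M0 would equal T2N1M0), while this weighting is
strictly monotone in each component and uniquely decodable. The two
stages must share the identical patient split; a mismatch is an error.
Metrics are reported at image (slice) level by default, matching how
test sets are counted in this setting, with mean-probability aggregation
to patient level available.

## The phantom generator

The generator emulates exactly what the downstream stages consume:
per-voxel DCE curves following the enhancement model with additive
Gaussian noise on the magnitude signal (a Rician option exists but is
off by default — at the SNRs simulated the difference is negligible and
the Gaussian model keeps the noiseless identity exact), monoexponential
echo and diffusion decays, elliptical tumor masks tapering across
slices, and class-conditional clinical covariates and exponential event
times censored at 36 months. DCE sampling follows the acquisition
protocol: 7-s frames spanning 4.3 min (37 post-injection time points)
plus 5 baseline frames.

Inter-patient distributions are not published anywhere; the defaults are
field-plausible values for prostate at 3T, stated once and not tuned:
tumor enhancement rate 2.0 ± 0.4 /min (background 1.2), elution rate
0.03–0.15 /min, amplitude 120 ± 15%, tumor T2 80 ± 8 ms (background
110), tumor ADC 0.8e-3 ± 0.08e-3 mm²/s (background 1.4e-3), PSA
log-normal with median 15 ng/mL. The class-separation knob shifts the
progressing class's tumor alpha mean by `class_effect` standard
deviations, increases the coarse (blocky, long-run) component of the
intratumoral texture — raising LRHGLE — and shifts PSA, Gleason and TNM
upward; `class_effect = 0` yields an uninformative cohort.

What the phantom does *not* emulate: prostate anatomy, scanner
artifacts, inter-sequence misregistration, arterial input variability,
or realistic inter-feature correlation structure. Passing phantom tests
therefore demonstrates correctness of the computations and the
plumbing — parameter recovery, split hygiene, learnability of a planted
signal — not clinical performance. The published clinical accuracy of
this model class on real cohorts is explicitly not a claim these tests
support.

## Numerical notes and problem sizes

- Voxel-wise EMM fitting is the cost center (~0.5 ms/voxel); T2/ADC maps
  are vectorized closed forms.
- Degenerate inputs are first-class: flat PSE curves return amplitude 0
  and are flagged; constant echo profiles have unbounded T2 and are
  invalid; a constant image quantizes to level 1; constant channels
  normalize to 0 with a warning; zero-denominator metrics are reported
  as undefined, never as 0.
- The demonstration-scale end-to-end study in the acceptance suite uses
  96 patients x 3 slices on a 28x28 grid, 64x64 samples, a narrow
  DenseNet (growth 8, two blocks, no bottleneck), 10 epochs, one split
  round, and a strong planted separation (`class_effect = 4`) — the
  smallest configuration at which the full two-stage pipeline, its
  single-modality baselines and a permuted-label control are all
  informative. Default architecture and training settings are unchanged
  by it.
- Everything is seeded: cohort generation, splits, initialization,
  shuffling, augmentation, and the booster (single-threaded) are
  reproducible end to end from the documented seeds.

## Known limitations

Training the full-width DenseNet-121 at 224x224 in this pure
R/Rcpp implementation is possible but slow (its forward pass is a few
seconds per image); the implementation is intended for methodological
study and moderate problem sizes, not GPU-scale training. KM/log-rank
evaluation uses the asymptotic chi-square p-value; no permutation option
in this version. Only 2D (per-slice) samples are supported, matching the
per-slice design of the modeled pipeline.
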