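---
title: "Multimodal tumor discrimination with ProbeFusion: models, assumptions and design choices"
author: "ProbeFusion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal tumor discrimination with ProbeFusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Colorectal biopsies can be characterized ex vivo with two fiber-probe
modalities that carry complementary information: Raman spectroscopy (RS)
measures a molecular fingerprint — an intensity vector over wavenumbers —
at single points, while optical coherence tomography (OCT) images the
tissue microstructure; its *enface* planes (parallel to the surface) show
the oriented, fibrous "desmoplastic" collagen patterns that accompany
tumor growth. Each biopsy sample is probed several times with each
modality, samples are nested in subjects, and the diagnostic question is
posed at the *sample* level: what is the probability that this biopsy
contains tumor?

ProbeFusion implements the full analysis chain for this setting:

1. a synthetic cohort generator that emulates the hierarchical data
   (subjects → samples → records) with known ground truth;
2. Raman spectral preprocessing down to area-normalized, background-free
   spectra and the selection of class-discriminative wavenumber bands;
3. four texture descriptor families for enface images;
4. leave-one-subject-out (LOSO) validation of a linear discriminant
   classifier per modality, with nested hyperparameter tuning;
5. sequential Bayesian fusion of per-record binary decisions into one
   tumor posterior per sample, with ROC operating-point reporting.

## The validation design

Records from one sample — and samples from one subject — are correlated;
putting them on both sides of a train/test split inflates performance
("identity confounding"). All validation here therefore splits at the
highest hierarchical level: each outer fold holds out *all* records of one
subject. Inside each outer training set, a second LOSO loop tunes the
classifier hyperparameters, so no configuration is ever chosen using data
from the evaluated subject. Fitted transforms (feature standardization,
PCA bases) are always learned on the training rows and applied unchanged
to held-out rows; the test suite probes this by perturbing held-out
records and asserting bit-identical fold parameters.

One deliberate exception mirrors the single-batch study design that the
package reproduces: SVD denoising and Welch band selection run once on the
*entire* Raman batch before any split. This is a mild form of information
sharing (the held-out spectra participate in the denoising basis and in
band selection). `preprocessConfig(welchPerFold = TRUE)` marks the
intent to recompute selection per fold for users who want strict
separation; the default keeps the global behaviour because the selection
is driven by a class-contrast statistic whose leakage effect at
`alpha = 1e-10` is small compared with subject-level confounding, and
because it matches the published processing order.

## Raman preprocessing

The chain is fixed: cosmic-spike repair → wavenumber calibration →
intensity-response correction → batch SVD denoising (rank 30) → asymmetric
least squares (ALS) baseline removal (`lambda = 1e3`, `p = 1e-5`, 10
iterations) → extended multiplicative signal correction (EMSC, polynomial
order 2) against the batch mean → area normalization → per-channel Welch
*t*-test band selection at `alpha = 1e-10`.

Numerical notes:

* **Spike detection** uses the robust z-score (median/MAD) of first
  differences with threshold 8; an up-jump closed by a down-jump within 3
  channels flags the enclosed channels, which are linearly interpolated
  from the nearest unflagged neighbours. Thresholds are configuration,
  not science: real cosmic spikes are tens of noise standard deviations
  high, so the result is insensitive to the exact value.
* **ALS** solves the pentadiagonal normal equations with a banded LDL^T
  factorization; the asymmetry parameter `p = 1e-5` makes the baseline an
  effective lower envelope. On curvature-rich smooth backgrounds the
  envelope bias grows with curvature times `lambda`; with the defaults the
  recovery error off peak supports stays below 5% RMS, which the
  acceptance suite verifies on a known synthetic baseline.
* **EMSC** models a spectrum as `b * reference + interferents +
  polynomial`; the package uses the batch mean spectrum as reference and
  accepts any interferent library (the synthetic generator emits its own
  "holder" and "room light" curves). A reference coefficient below 1e-6
  is refused rather than divided by.
* **Welch selection** reports maximal contiguous runs of significant
  channels as regions; single-channel runs are kept. The mask is monotone
  in `alpha`, and its null calibration (fraction selected ≈ `alpha`) is
  part of the acceptance suite.

## OCT texture descriptors

Four blocks, fixed order, fixed lengths:

* **Gabor (48 values)** — the bank is defined in the polar frequency
  domain: radial Gaussians centred at 0.4, 0.2, 0.1, 0.05 cycles/pixel
  (four bands one octave apart; the radial sd `0.352 * f0` puts the
  half-response width at one octave), angular Gaussians at orientations
  0°, 33°, 66°, 99°, 132°, 165° with a 30° full bandwidth, one-sided
  (analytic) and with the DC bin zeroed, so every filter ignores constant
  offsets. The kept statistics are the mean and standard deviation of the
  complex response magnitude. Filtering is FFT-based and periodic; for
  bands whose support fits below half Nyquist the response is evaluated on
  the exact half-resolution subgrid, which returns the same field at every
  second pixel. The bank parameterization ("4 bands, one octave, 30°
  bandwidth") is under-determined in prose; the formula above *is* the
  package's definition.
* **LBP (60 values)** — rotation-invariant uniform patterns at radii
  1, 2, 3 with 8, 16, 24 bilinearly interpolated neighbours
  (histograms of P + 2 bins), each scale accompanied by the mean and sd of
  the local neighbour variance, the standard rotation-invariant contrast
  companion to the sign patterns.
* **LPQ (256 values)** — the normalized histogram of 8-bit codes formed
  from the signs of the real and imaginary parts of four low-frequency
  short-term Fourier coefficients in a 7-pixel window (frequency 1/7;
  wave vectors (a,0), (0,a), (a,a), (a,−a)). No decorrelation step is
  applied — the basic, deterministic variant.
* **GLCM (24 values)** — co-occurrence matrices at distance 5 for angles
  0°, 90°, 180°, 270°, kept as separate asymmetric tallies, on images
  linearly rescaled to 256 gray levels; per angle the six scalar
  properties contrast, dissimilarity, homogeneity, energy, correlation
  and angular second moment.

Windowed operators (LBP, LPQ) use the valid interior region only; no
resizing or padding is applied to the images.

## Per-modality classification

Raman records enter as processed spectra restricted to the selected
channels; OCT records as the four texture blocks. Per outer fold:
Z-score standardization, then PCA to 10 components (per texture block for
OCT, whose four 10-dimensional score sets are concatenated to a 40-vector
— the per-block dimension is configurable; 10 keeps the modalities
symmetric). The classifier is a two-class linear discriminant with the
tumor posterior given by the logistic of the discriminant score under the
equal-covariance Gaussian model. The tuning grid crosses three solver
routes (SVD of the centred within-class data; least-squares solution of
the normal equations via rank-revealing QR; eigendecomposition of the
pooled covariance) with seven truncation tolerances (1e-2 … 1e-14), 21
configurations scored by mean inner-LOSO AUC; ties resolve to the first
configuration in grid order. On the well-conditioned PCA scores the routes
agree to machine precision with a reference implementation (`MASS::lda`),
which the tests assert; the grid matters only for ill-conditioned inputs,
and keeping all 21 configurations preserves the validated protocol.

All held-out record probabilities are pooled into a single ROC per
modality (the alternative — averaging per-fold curves — is not used; a
pooled curve corresponds to applying the per-fold models as one composite
classifier and is the only choice that yields one threshold axis).

## Sequential Bayes fusion

Each record's thresholded prediction (RS at 0.56, OCT at 0.73 — the
validated operating thresholds; configurable) is treated as one binary
diagnostic test with known sensitivity (TPR) and false positive rate
(FPR). Starting from an uninformative prior of 0.5, each sample's
posterior is updated once per record via the positive/negative predictive
value forms of Bayes' rule; the update multiplies the prior odds by the
test's likelihood ratio, so the final posterior is provably independent of
the record order (the package still applies RS before OCT, for log
fidelity). Each sample's posterior is computed exactly once, and
single-modality results are obtained by simply skipping the other
modality's updates.

Where do the per-fold TPR/FPR come from? Only training data are available
at test time, so each fold reads them off its own training predictions
thresholded at the fixed decision thresholds. Rates are clipped into
`[1e-3, 1 - 1e-3]` before use: the update equations are degenerate at the
boundary, and a fold whose training set happens to be perfectly separated
would otherwise produce absorbing posteriors of exactly 0 or 1.

A note on the RS threshold: the source analysis reports 0.56 in its
results and 0.57 in its conclusions; the package defaults to 0.56 and
exposes the value in every API that uses it.

Sample-level ROC curves are reported per mode (RS-only, OCT-only, fused)
with three operating points: the Youden optimum (maximal TPR − FPR, ties
towards the lower FPR), a confirmatory point (the most sensitive point
with FPR ≤ 0.1 — on a finite ROC the requested rate may not be exactly
achievable, and overshooting it would defeat the high-specificity
purpose), and a screening point (the first point with TPR ≥ 0.9).

## The synthetic cohort

No clinical data ship with the package; a generator emulates their
structure with known ground truth. Its defaults are fixed once and define
the simulated study conditions:

* **Hierarchy** — 27 subjects, 21 healthy + 40 tumor samples assigned
  near-uniformly to subjects, per-sample record counts of
  `1 + Poisson(mean − 1)` with means 303/61 (RS) and 346/61 (OCT), so
  default totals land near the 303 spectra / 346 images of the emulated
  dataset.
* **Within-tumor heterogeneity** — each tumor sample draws a purity
  uniformly from [0.1, 1]; each of its records is tumor-like with that
  probability. Healthy samples contain only healthy-like records. This
  caps the achievable record-level AUC well below 1 even for perfectly
  separable latent classes — the single strongest driver of realistic
  performance numbers in the simulation.
* **Raman records** — twelve pseudo-Voigt bands (FWHM 16–80 cm⁻¹,
  mixing 0.3) at the canonical colon-tissue positions on a 1024-channel
  axis over 600–3300 cm⁻¹, under a low-order-polynomial-plus-broad-
  Gaussian autofluorescence baseline, holder and room-light interferents,
  a smooth instrument response, shot-like noise
  (`sd = 0.05 * sqrt(signal + 0.5)`), and Bernoulli(0.1) cosmic spikes of
  ≥ 20 local noise sd. Tumor-like records shift nine of the twelve band
  amplitudes by `rsEffectSize * deltaDir * 0.1` counts; three bands carry
  no contrast, giving a known negative set for band-selection tests.
  Biological and measurement variability enter as lognormal amplitude
  jitter per record (15% common, 8% per band) and per subject (5% per
  band). With the default `rsEffectSize = 5` the class contrast at the
  strongest bands is of the order of one within-class standard deviation
  *before* purity dilution — chosen so that the processed batch yields a
  band selection of a handful of contiguous regions at `alpha = 1e-10`
  and record-level AUCs in the high-0.7s, the regime of the emulated
  study. (An earlier unit of "raw noise sd" alone proved irrelevant in
  practice because amplitude jitter, not shot noise, dominates the
  within-class variance of the processed spectra.)
* **OCT records** — healthy-like images are isotropic speckle (the
  magnitude of a complex Gaussian field with 1.5 px correlation);
  tumor-like images add a band-limited fibrous field (white noise blurred
  with sd 18 px along one axis and 1.5 px across) at a uniform random
  orientation, weighted by `octEffectSize * 0.45` of the mean speckle
  amplitude. Orientation is quoted as the dominant spectral angle; the
  fiber streaks run perpendicular to it. Per-image lognormal jitter on
  speckle grain (10%) and fiber prominence (30%), plus an 8% per-subject
  grain factor, keeps the latent classes from being trivially separable.
  Values are min–max scaled to [0, 1] per image — intensity is
  deliberately uninformative; only texture carries class information.

What the generator does *not* emulate: physical speckle formation and the
OCT transfer function, depth attenuation, probe-contact artefacts,
histology-driven spatial layout of tumor regions, and any correlation
between a sample's Raman and OCT effect strengths. Passing tests on this
cohort therefore demonstrate that the pipeline recovers planted structure
under realistic nuisance variation — not clinical performance.

## Problem sizes and reproducibility

Everything stochastic flows from explicit integer seeds through R's
global RNG (`withSeed()` wraps and restores state); a cohort, a pipeline
run and the acceptance analysis are bit-reproducible for a fixed seed.
The acceptance analysis (`scripts/acceptance.R`) runs one full default
cohort (61 samples, ≈ 300 spectra, ≈ 350 images of 500 × 500 px) through
the entire chain. The test suite exercises the same default scale for the
fusion-dominance and null-behaviour checks (10 and 3 seeds respectively)
and smaller cohorts (4–8 subjects, 32–64 px images) for module-level
properties, sizes chosen to keep a full check of the package in the
tens-of-minutes range on a laptop while leaving the statistical
conclusions stable.

## Known limitations

* The wavenumber calibration and intensity-response stages accept
  externally supplied peak tables and response curves; no certified
  reference material data are bundled.
* Spectra I/O uses CSV, images TIFF; no HDF5 container is provided.
* The Bayes fusion treats records as conditionally independent given the
  sample state; records taken close together on a heterogeneous biopsy
  violate this, and the resulting posteriors are sharper than warranted.
  The operating-point report, not the raw posterior magnitude, is the
  supported basis for decisions.
* Only two modalities are exercised; the fusion API accepts any number of
  update lists, but no third-modality code path is tested.
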