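---
title: "Predicting free proline in rice leaves from hyperspectral images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting free proline in rice leaves from hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperFP)
```

## The problem

Free proline (FP) accumulates in plant tissue under abiotic stress and is a
standard physiological marker of heavy-metal damage in rice. Wet-chemistry FP
assays are destructive and slow; hyperspectral imaging offers a
non-destructive alternative: calibrate a regression from 500–950 nm leaf
reflectance to FP (mg/g fresh weight), then apply it to every pixel of a leaf
image to map the spatial FP distribution.

hyperFP implements that pipeline end to end: radiometric calibration and leaf
segmentation, sample-level spectra extraction, three calibration engines,
three wavelength-selection methods, a rank-based evaluation protocol, and
pixel-wise FP maps. Because no public rice dataset accompanies this assay,
the package ships a synthetic study generator with known ground truth; all
claims the test suite makes are claims about this generator's output.

## The synthetic study

The generator reproduces a five-concentration (0, 5, 25, 50, 100 µM Cd) by
four-day (5, 10, 15, 20 d) design with 5 samples per group, each sample the
average of 4 leaves — 100 samples in all.

**Wavelength grid.** 350 band centres with affinely increasing spacing
(1.229 nm growing to 1.323 nm across the window), spanning 500.98–946.16 nm.
The three grid constants were calibrated by least squares so that the
consensus characteristic wavelengths quoted throughout the package
documentation (e.g. 650.34 or 943.52 nm) sit within 0.01 nm of a band
centre — the spacing pattern a V10E-class imaging spectrograph produces over
this window.

**FP ground truth.** Group-level FP means live in an editable trend table
(`defaultTrendTable()`). Only day-pooled statistics are fixed by the
reference design (`referenceDayStats()`); the per-group cell means are
interpolated under ordinal constraints — at day 5 the 5 µM group is highest
while stronger doses depress FP below the control; from day 15 group means
rise monotonically with concentration — with the constraint that pooling the
five groups of a day reproduces the day mean exactly and the day SD
approximately (between-group plus within-group variance). Within-group SDs
per day are 0.0121, 0.0077, 0.0041 and 0.0074 mg/g. Sample FP values are
Gaussian draws around the cell mean (truncated at zero by redraw); leaf
values add mean-centred deviations (SD 0.006 mg/g), so each sample's FP is
exactly the mean of its four leaves.

**Forward optical model.** A pixel's reflectance is

    R(λ) = base(λ) − aPig·pigment(λ) − aWat·water(λ) + aDry·dry(λ)
           − 0.25 · FP · fp(λ) + ε

where `base` is a smooth green-leaf curve (green peak at 553 nm, red-edge
logistic centred at 712 nm, NIR plateau ≈ 0.48), `pigment` and `water` are
Gaussian absorption shapes (675/605 nm and 960 nm), `dry` a broad slope, and
`fp` the FP-linked absorber with **unit weight at exactly six bands** — the
grid bands nearest 601.37, 625.18, 626.44, 650.34, 689.56 and 943.52 nm —
and zero elsewhere. Abundances vary leaf to leaf (CV 5 %); chlorophyll
declines by up to 15 % with a severity score that grows with both
concentration rank and day rank, which is what makes spectral group
differences broaden with stress time in the per-wavelength ANOVA.

The band-localised (delta) FP absorber is a deliberate design device, not a
claim about leaf optics: it makes wavelength-selection recovery a well-posed
assertion ("the returned set contains the six planted bands") instead of a
fuzzy overlap score. Real FP absorption features would be broad and heavily
confounded with water and protein bands; the generator therefore
demonstrates algorithmic correctness, and nothing here validates chemical
interpretability of selected wavelengths on real leaves. Likewise the
synthetic data are cleaner than a real campaign (no smile/keystone, no
scattering artefacts, no outlier samples), so the near-unity correlations
the pipeline reaches on it are an upper bound, not a forecast.

**Noise.** Per-pixel, per-band Gaussian noise (SD 0.01 reflectance) plus a
per-leaf band-wise residual (SD 0.0025) shared by all pixels of a leaf.
The sample-level generator (`simulateSpectraTable()`) uses the closed form
of the pixel average — the forward model is linear in pixel FP, so the
in-mask mean spectrum equals the model at the leaf-mean FP with pixel noise
attenuated by the effective pixel count (default 900) — which is
statistically equivalent to rendering each leaf cube and extracting its
mean spectrum, at a small fraction of the cost. The cube path
(`makeDataset()` → `extractStudyTable()`) exists and is tested; the
equivalence is exercised by a round-trip test on a small design.

**Leaves.** `renderLeafCube()` builds a lanceolate mask (pointed petiole and
tip, broadest about a third of the way up) and assigns each pixel
FP = leaf FP × gradient factor, the factor linear from 0.9 (petiole) to
1.15 (tip) along the main axis and renormalised to mean 1 over the mask so
the leaf mean is preserved.

## Image processing

Reflectance calibration is the standard two-point correction
`(raw − dark)/(white − dark)`, clipped to [0, 1.5] (the ceiling guards
specular pixels). Reference frames are averaged over image rows by default
(configurable off) to suppress reference noise. Segmentation thresholds the
band nearest 800 nm at reflectance 0.25 — leaves are bright on the NIR
plateau, backgrounds dark — and keeps the largest connected component;
masks under 50 pixels are rejected. Mean spectra are plain per-band
averages over the mask; four leaf spectra are averaged into each sample
row (pixels first, then leaves — with equal pixel counts the two orders
coincide). The analysis window 500–950 nm is inclusive on both endpoints.
No spectral pre-treatment (SNV, derivatives, smoothing) is applied.

## Calibration engines

All three engines select their hyperparameters at the minimum leave-one-out
RMSECV, with ties broken toward the simpler model (fewer latent variables,
fewer nodes, smaller gam then sig2).

**PLS** is NIPALS PLS1 on mean-centred spectra and response (no
autoscaling — reflectance bands share units). The latent-variable count is
searched over 1..15 by default; the regression-coefficient vector over
bands, `b`, is also the Bw profile used for selection. At full rank the
coefficients equal the least-squares solution, which the tests assert to
1e−8.

**LS-SVM** uses the RBF kernel `exp(−‖xi−xj‖²/sig2)` and solves the dual
KKT system `[0 1ᵀ; 1 K+I/gam][b; α] = [0; y]` directly; the relative
residual of the solved system must be ≤ 1e−8 (a validity condition of the
fitted object). The (gam, sig2) search is a log-spaced coarse grid
(10⁰..10⁷ × 10⁰..10⁶) refined once on a ±half-decade local grid around the
coarse optimum — the magnitudes this produces match what is typical for
reflectance calibrations.

**ELM** draws input weights and biases uniform on (−1, 1) from a recorded
seed (they are never trained), applies a sigmoid hidden layer, and solves
the output weights by min-norm least squares. Candidate node counts span
1..n (the training-set size). Node selection uses LOO-RMSECV by default;
the historical rule for this assay — minimum RMSE on the prediction set —
is available as `criterion = "rmsep"` but is not the default because it
lets the held-out set leak into model choice. The LOO search uses the exact
hat-matrix identity `e_loo = e/(1−h)` for the fixed random layer; tests
assert exact equality with the brute-force refit loop.

## Wavelength selection

**CARS** (competitive adaptive reweighted sampling): at iteration i a PLS
model is fitted on a Monte Carlo 80 % subsample, bands are ranked by |b|,
the retained count follows the exponentially decreasing function
`r_i = a·e^(−k·i)` with a and k fixed by r₁ = 1 and r_N = 2/p, and
|b|-weighted sampling with replacement competitively eliminates further
bands. Each iteration's set is scored by LOO-RMSECV of a PLS model on all
samples; the set minimising RMSECV over the whole 50-iteration trace is
returned. When weighted resampling would leave fewer than two variables the
schedule's floor of two (top-2 by weight) applies — with strongly localised
signal the weight distribution is extreme enough to reach that floor well
before the final iteration.

**GA**: binary chromosomes over bands, fitness −(LOO-RMSECV of PLS on the
encoded bands), tournament selection of size 2, single-point crossover
(rate 0.6), per-gene bit-flip mutation (rate 0.01), elitism of one,
population 30 for 100 generations. All-zero chromosomes get −∞ fitness and
are never returned. Defaults follow common spectral-GA practice; every knob
is an argument.

**Bw**: the bands at strict interior local maxima and minima of the signed
PLS coefficient profile (plateau points excluded), optionally filtered to
|b| above a quantile of the full profile. Extrema are taken on the signed
vector, not |b|, so both peaks and valleys count.

## Evaluation protocol

`rankSplit()` sorts samples by FP (ties by original index) and holds out
the third of every consecutive block of four — a 3:1 split, 75/25 at
n = 100. A trailing partial block goes entirely to calibration, keeping the
prediction set interior to the calibration range. Rc and RMSECV are
computed from leave-one-out predictions over the calibration set
(refitting with fixed hyperparameters); Rp and RMSEP on the untouched
prediction set. R is the Pearson correlation between predicted and
reference values; a degenerate constant predictor reports R = 0 with a
warning rather than NA.

Per-wavelength ANOVA is a one-way fixed-effects F-test of reflectance
against Cd concentration within one stress day, flagged at p < 0.05 with no
multiple-testing correction across bands (day-wise grouping, matching the
four-panel presentation of the reference design). Group comparisons of FP
use Tukey HSD at α = 0.05 summarised as a compact letter display; letters
are the maximal cliques of the "not significantly different" graph, so two
groups share a letter exactly when their comparison is not significant.

## FP distribution maps

`predictMap()` applies a fitted model to every in-mask pixel, matching the
model's band subset against the cube grid by wavelength. For the linear PLS
model the map mean equals the prediction of the mean spectrum exactly (an
affine-map identity asserted to 1e−8); for LS-SVM/ELM the identity holds on
homogeneous leaves. Negative pixel predictions are preserved in the stored
map and only clipped at display time, so diagnostics never hide model
behaviour. Panels share a display range (1st–99th percentile of the pooled
predictions); `renderPseudocolor()` writes a PNG with a colour-bar strip
and records the range in a text sidecar.

## Numerical choices and degenerate inputs

NIPALS stops extracting components when the residual covariance norm falls
below 1e−12 (perfect fit); constant responses and zero-variance spectra are
rejected. The LS-SVM solver propagates singular systems as errors. In the
ELM LOO identity, leverages within 1e−10 of 1 yield infinite fold errors,
which simply disqualifies that node count. RMSECV ties are broken toward
the first (simplest) candidate in grid order. Seeds are explicit arguments
everywhere randomness exists; identical seeds give bit-identical cubes,
tables, selections and models.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run the full 100-sample,
350-band study for design conformance, generator conformance, CARS
recovery, ELM held-out performance and map identities; selector unit tests
use planted toys (up to 100 × 50, two informative bands, SNR 20); the
ANOVA type-I simulation uses 200 replicates of a 25-sample, 40-band null
study; the end-to-end pipeline test uses 40 samples with a shortened CARS
schedule and a small GA. The default full-scale pipeline (GA included)
completes in a few minutes on one CPU.

## Known limitations

The generator does not model radiative transfer (no PROSPECT-style leaf
optics), instrument smile/keystone, scattering artefacts, or outlier
samples, and its FP absorber is deliberately band-localised; conclusions
about real-leaf chemistry cannot be drawn from recovery results on it. The
trend table's per-group means are a calibrated stand-in for statistics the
reference design only reports day-pooled. Whether Rc/Rp should be read as r
or R² in the historical tables is ambiguous; the package reports r and
says so.
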