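---
title: "Decoding mental engagement from fNIRS oxygenation and connectivity"
author: "fnirsbci authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding mental engagement from fNIRS oxygenation and connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsbci)
```

## The problem

Passive brain-computer interfaces monitor an operator's spontaneous mental
state rather than decoding voluntary commands. In high-stakes settings such
as piloting, a monitor that can tell an *actively engaged* operator (for
example, flying a landing manually) from a *supervising* one (watching the
autopilot land) could feed adaptive assistance systems. Functional
near-infrared spectroscopy (fNIRS) is attractive for this because it is
wearable and tolerant of motion: light at two wavelengths (760 and 850 nm
here) is injected into the scalp, and the attenuation changes measured a
few centimetres away track the concentration changes of oxy- and
deoxy-hemoglobin (HbO, HbR) in the underlying cortex.

`fnirsbci` implements the complete analysis chain for a two-condition,
within-subject engagement-decoding experiment: eight "landings" per
subject, four per condition, recorded over a 42-channel montage (7 channels
in each of 6 regions of interest covering frontal and occipital cortex) at
7.8125 Hz. Because no public recordings exist for this design, the package
also ships a first-class synthetic-session generator with known ground
truth, so that every stage — preprocessing, feature extraction, reduction,
classification, statistical thresholding — is testable end to end.

## Preprocessing model

Raw two-wavelength intensities are processed **per epoch**, never using
information from neighbouring epochs, so the chain extends naturally to
online use:

1. **Epoching.** Each landing is cut into 200-sample (~25.6 s) epochs with
   onsets 60 samples (~7.7 s) apart. The phrase "overlapping epochs" in this
   design is ambiguous between *step 60* and *overlap 60*; we adopt step 60
   because it is the only reading under which 12 epochs (11 × 60 + 200 =
   860 samples ≈ 110 s) fit into landings of 152 ± 22 s. Twelve epochs per
   landing is also the package default cap, giving 12 × 8 = 96 epochs per
   subject; the cap is additionally limited by the subject's shortest
   landing.
2. **Optical density.** `OD(t) = -log10(I(t)/I_ref)` with `I_ref` the
   per-epoch mean intensity (epochs are self-referenced because they are
   processed independently).
3. **Motion-artifact correction.** A maximal-overlap discrete wavelet
   transform (Daubechies-2, maximal dyadic depth) decomposes each OD epoch;
   detail coefficients outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` per level are
   zeroed and the epoch reconstructed. The MODWT is used (rather than the
   decimated transform) because it is defined for the non-dyadic 200-sample
   epoch length and is shift-invariant. The epoch is extended by reflection
   before the circular transform, and coefficients whose support crosses a
   reflection junction are exempt from zeroing: their large magnitudes come
   from the junction's slope break, not from artifacts. Without this
   exemption a clean sinusoid is visibly distorted at the epoch edges.
4. **Band-pass.** Butterworth high-pass (0.01 Hz, order 3) then low-pass
   (0.5 Hz, order 5). Filtering is zero-phase (forward-backward) by
   default, with a causal mode retained for online use. The zero-phase pass
   uses odd-reflection padding and constant-history initial conditions; the
   odd extension of a constant is the constant and a high-pass numerator
   sums to zero, so DC is removed exactly. At this cutoff the high-pass
   transient time constant (~250 samples) exceeds the epoch length, which
   is intrinsic to the design; in practice OD epochs are near zero mean
   and the kept window (below) discards the worst-affected edges.
5. **Modified Beer-Lambert inversion.** Per time point and channel the 2×2
   system `ΔOD(λ) = [ε_HbO(λ) ΔHbO + ε_HbR(λ) ΔHbR] · d · DPF(λ)` is
   solved. The extinction coefficients ship as a versioned CSV
   (`inst/extdata/extinction_coefficients.csv`, units 1/(M·cm)); DPF
   defaults are 6.4 at 760 nm and 5.75 at 850 nm and the source-detector
   distance is 3 cm — all overridable via `mbll_params()`. The synthetic
   generator uses the *same* constants for its forward model, so the
   round trip is exact up to filtering.
6. **Kept window.** Only the 80 centred samples (61..140, ~10 s) of each
   epoch feed the time-domain features. Time-frequency transforms are
   computed on the full 200-sample epoch and cropped to the central 80 time
   points afterwards, so spectral leakage from the epoch edges never
   reaches a feature value.

## Features

**Oxygenation (7 per channel and chromophore):** peak (signed maximum),
average, variance, skewness, kurtosis, area under the curve, and slope.
Moments are population moments (divide by N), matching their expectation
form; kurtosis is non-excess (a Gaussian scores 3). AUC is the plain sum of
absolute sample values, not a trapezoid. Slope is the least-squares
regression coefficient against time *in seconds*, so its units
(concentration/s) do not depend on the sampling rate. Zero-variance windows
make skewness/kurtosis undefined; they propagate as missing values and the
affected dimension (never the epoch) is excluded downstream with a warning.

**Connectivity (5 per channel pair and chromophore):** covariance (sample
convention, divisor N−1), Pearson and Spearman correlation (average-rank
convention), magnitude-squared spectral coherence, and Morlet wavelet
coherence. The two coherences are averaged over the standard fNIRS
connectivity band 0.078125–0.3125 Hz (periods 3.2–12.8 s).

The spectral coherence uses a Welch estimator: Hamming-tapered 100-sample
segments with 50% overlap, giving K = 3 segments on a 200-sample epoch. The
segment length is the compromise between two hard constraints: K must
exceed 1 (the single-segment estimator is *identically* 1 for any pair —
an algebraic identity the test suite asserts) and the segment must resolve
the 0.078 Hz band edge. All estimator parameters are arguments.

The wavelet coherence follows the Torrence-Compo construction: Morlet
mother wavelet with ω₀ = 6 (period ≈ 1.033 × scale), scale spacing
dj = 1/12 octave, smallest scale 2Δt, scales up to the largest period
≤ 12.8 s. The squared coherence is

R²(s, n) = |S(W_xy/s)|² / ( S(|W_x|²/s) · S(|W_y|²/s) ),

with W_xy the cross-wavelet transform and S a smoothing operator: a
Gaussian in time whose width matches the scale, then a boxcar across scales
over the Morlet decorrelation length (0.6/dj scales). Smoothing is what
makes the estimator informative — with S the identity, R² ≡ 1 for any
pair, which the tests assert as the reason S is mandatory. Points inside
the cone of influence are retained (the 200→80 central crop already removes
the worst edge effects). For the batch extractor the per-channel transforms
are computed once per epoch and reused across pairs, time smoothing is a
single FFT pass over stacked pair fields, and only the scales feeding the
band average (plus the boxcar margin) are evaluated — an exact
restriction, verified bit-for-bit against the single-pair path.

## ROI reduction

Channel features are averaged into 6 ROI values per oxygenation feature;
channel-pair values are pooled over ROI pairs into C(6,2) + 6 = 21 values
per connectivity measure (within-ROI terms are kept as features; each
averages the C(7,2) = 21 internal channel pairs of the default montage).
Between-ROI terms precede within-ROI terms, each block in canonical ROI
order, so feature indices are stable across runs.

## Classification and statistics

Features are z-scored and classified with a linear discriminant whose
pooled covariance is shrunk toward a scaled identity,
`(1-γ)S + γ(tr S/p)I`, with γ estimated analytically (Ledoit-Wolf) — the
standard regularization in the BCI literature, well-posed even for p > n.
A fixed-γ override exists. Ties in the discriminant score break toward the
first class in canonical label order.

Cross-validation is stratified by landing: every combination of one
held-out landing per condition forms a fold — 16 folds of 72 training and
24 test epochs for the 4+4 design. The z-scoring is fit on the training
fold only and applied to the test fold; a `global_zscore` flag reproduces
whole-session scaling (with its normalization leakage) for comparability,
default off. Single features (12) and all C(12,2) = 66 feature pairs
(column-wise concatenation before normalization) are evaluated per
chromophore.

Significance uses the exact binomial chance level: the smallest k with
`Binom-CDF(k; n, 1/c) ≥ 1-α`, reported as 100·k/n. For n = 96 test
predictions, two classes and α = 0.05 this is 56/96 = 58.33%.

## The synthetic generator

`simulate_session()` emulates the statistical structure the analysis
assumes, not the physics of a head:

* **ROI-latent mixture.** Each ROI has a unit-variance latent signal:
  band-limited (0.06–0.12 Hz) low-frequency oscillations plus a 1/f (pink)
  background (20% of variance). Channels are their ROI's latent plus
  independent channel noise, scaled to ~1 µM. Inter-ROI coupling is imposed
  by mixing the independent latents through a factor of the condition's
  6×6 coupling matrix (eigenvalue-clipped to stay positive semi-definite),
  so the latent cross-correlation *equals* the requested coupling — which
  makes ground-truth coupling monotonically recoverable by the
  connectivity features.
* **Two-channel condition contrast.** The "manual" condition differs from
  "auto" in (a) the coupling matrix (defaults 0.7 vs 0.2 between all ROI
  pairs) and (b) a mean HbO activation offset (0.3 µM vs 0). Either can be
  zeroed independently for null testing.
* **Physiology and noise.** Global cardiac (~1.1 Hz), respiratory
  (~0.25 Hz) and Mayer-wave (~0.1 Hz) sinusoids with random phases; HbR is
  the anti-correlated copy of the deterministic HbO part (gain −0.5) plus
  independent noise, so with all noise amplitudes at zero the HbO-HbR
  correlation is exactly −1.
* **Forward model and artifacts.** Hemoglobin is pushed through the same
  modified Beer-Lambert constants the preprocessing inverts; motion
  artifacts (80% transient spikes with ~0.5 s exponential decay, 20% step
  shifts; 2 events/min; 0.02–0.2 OD units) are injected in OD space before
  exponentiation to intensities.
* **Durations.** Landing durations are drawn from a normal with mean 152 s
  and sd 22 s, truncated below at 120 s so that 12 epochs always fit.

What the generator does **not** emulate: photon transport through realistic
head geometry, scalp/skin blood flow, serially correlated physiological
noise, task-locked hemodynamic response shapes, or optode-coupling drift.
Passing tests on synthetic sessions therefore demonstrate that the
*pipeline* is correct and sensitive to the structure it targets — not that
real flight-deck recordings would reach any particular accuracy.

## Numerical choices and problem sizes

* Wavelet coherence values are clipped to [0, 1]; by Cauchy-Schwarz the
  smoothed ratio cannot exceed 1, so clipping only absorbs float jitter.
* The simulation studies in the test suite and the acceptance script use a
  reduced 12-channel montage (2 channels per ROI) for classification
  experiments and a 6-channel montage (1 per ROI) for coherence-recovery
  experiments. The channel dimension only enters through ROI averaging, so
  these sizes exercise the full pipeline (including within-ROI terms) at a
  desk-scale cost; the structural counts (861 pairs, 21 ROI features) are
  always checked on the full 42-channel montage.
* Decoding validity is assessed on 5 simulated subjects (96 epochs, 16
  folds each) under the default contrast, under a null generator with
  identical conditions, and over a 3-level coupling-contrast grid
  (2 subjects per level; 24 simulated landings per level for coherence
  recovery).
* A master seed is fanned out deterministically to per-subject,
  per-stage sub-seeds (`derive_seed`), so any subject can be re-simulated
  in isolation and full runs are bit-reproducible.

## Known limitations

* With step-60 epoching the kept 80-sample windows of successive epochs
  are 60 samples apart, i.e. they overlap by 20 samples rather than tiling
  the landing exactly; the step is a parameter if strict non-overlap is
  wanted (at the cost of fewer epochs per landing).
* The spectral-coherence estimator (taper, segmentation) and the wavelet
  scale grid are analysis choices with no single canonical value in the
  fNIRS connectivity literature; the defaults above are declared,
  configurable, and recorded in the run report.
* SNIRF I/O delegates the HDF5 container format to a bundled Python
  helper using `h5py`; an R session without a `python` + h5py on the PATH
  can run everything except `write_snirf()`/`read_snirf()`.
* The package makes no claim about accuracies attainable on real
  flight-deck recordings; its validation evidence is the synthetic
  ground-truth recovery described above, plus the ability to ingest real
  SNIRF data through the same code path.
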