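---
title: "Methods: intensity-fluctuation mapping of hair-cell somatic activity"
author: "fluctmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intensity-fluctuation mapping of hair-cell somatic activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctmap)
```

# Scope and model

`fluctmap` analyzes high-speed, label-free wide-field recordings of
hair-cell somata. The physiological premise is that mechanotransduction —
bundle deflection opening tension-gated channels, the ensuing ionic fluxes
and depolarization — perturbs the refractive index of the tissue locally,
so somatic activity appears as small temporal fluctuations of transmitted
light intensity at specific subcellular locations. The package quantifies
those fluctuations and their coupling to hair-bundle motion; it does not
model the biophysics of the perturbation itself.

Two kinds of objects flow through the pipeline: `ImageStack` (a
`[row, col, frame]` array of raw camera counts with frame rate, pixel
pitch and axial-section index) and `Trace` (a uniformly sampled series of
bundle displacement in nm, stimulus command in nm, or dimensionless
ΔI/I). Coordinates are 0-based `(row, col)`; time starts at `t0 = 0`;
displacements are in nm and intensities remain raw counts until explicitly
normalized.

## Activity maps

For frames $I_k$, $k = 1 \dots N$:

$$\mu = \frac{1}{N}\sum_k I_k, \qquad
  \sigma = \sqrt{\frac{1}{N}\sum_k (I_k - \mu)^2}$$

per pixel. Two deliberate choices:

- **Population normalization ($1/N$), not $1/(N-1)$.** The map is a
  descriptive heatmap of fluctuation energy, not an inferential variance
  estimate, and at $N \geq 10^3$ frames the distinction is negligible; the
  population form is the convention adopted throughout, and the oracle
  tests check it exactly.
- **"Normalized intensity" is an option, not an assumption.** Whether the
  σ map should be computed on raw counts or on frames divided by their
  spatial background mean is genuinely ambiguous in practice, so
  `temporalStats(normalize =)` provides both and records the choice in
  `ActivityMap@normalized`. Normalization cancels frame-wide illumination
  drifts (the property suite verifies exact invariance to a per-frame
  multiplicative factor) and is the default.

## Hotspot detection

Published analyses of such heatmaps typically select hot areas by eye. A
reproducible stand-in is used here: pixels with
$\sigma > \mathrm{mean}(\sigma\,|\,\mathrm{mask}) + k\,\mathrm{sd}(\sigma\,|\,\mathrm{mask})$
are grouped by 8-connectivity; components of at least `minArea` pixels
become hotspots, each assigned a disk ROI (default radius 5 px ≈ 0.54 µm
at 108.3 nm/px) at the σ-weighted centroid. Defaults `kSigma = 3`,
`minArea = 4` px keep the false-positive rate at effectively zero on
hotspot-free synthetic renders while recovering injected hotspots to a
fraction of a pixel; ties in peak σ (exact equality only) resolve by
lexicographic centroid order so results are reproducible. The analysis
mask should be the cell interior (`somaMask()` for simulated scenes):
the bundle ridge is itself a strong σ source and must not be mistaken
for somatic activity.

## ΔI/I extraction

Per frame, `extractTrace` computes
$(\overline{I}_{\mathrm{roi}} - \overline{I}_{\mathrm{bg}}) /
\overline{I}_{\mathrm{bg}}$ over disk ROIs, the label-free analog of
ΔF/F in fluorescence work. The background disk must be disjoint from the
signal ROI and outside the cell; a zero background mean in any frame is
an error rather than a silent NaN.

## Bundle tracking

The original tracking method for these preparations is not reproduced
here; the package implements the standard alternative for bullfrog-bundle
video: per frame, subtract a floor (10th intensity percentile of the ROI —
robust to shot noise without biasing the centroid) and either

- **centroid**: intensity-weighted mean of pixel positions projected on
  the motion axis, or
- **gaussian_fit**: least-squares fit of a 1D Gaussian **plus a constant
  offset** to the floor-subtracted, axis-projected samples (falling back
  to the centroid with a warning if the fit fails to converge).

Displacement is `(position − baseline) × pixelPitch` in nm. The two
methods trade robustness against accuracy: the centroid is exact for
compact symmetric profiles (an exact 1-px translation maps to exactly
108.3 nm in the tests) but, when the ROI contains substantial non-ridge
area, residual positive noise weights dilute its amplitude toward the ROI
center — with the default simulator SNR and a generous disk this
shrinkage reaches tens of percent. The Gaussian fit's offset term absorbs
that background, making it the method of choice for amplitude
quantification; the suite verifies 60 nm, 10 Hz motion (0.554 px at
108.3 nm/px) recovered within 10% under shot noise, and sub-pixel
linearity with slope 1.00 ± 0.02 over ±2 px for both methods in the
noiseless case. Whether positions come from edges or centroids in other
implementations is unknowable; the choice here is documented rather than
guessed.

## Spectra and lagged correlation

`normalizedSpectrum` uses the plain FFT of the mean-subtracted trace
without padding (resolution = rate/M), one-sided amplitudes
$a(f) = 2|X(f)|/M$ so an on-bin sinusoid of amplitude $A$ reads $A$
(verified to 1e-10), DC and Nyquist carrying factor 1. Under this
convention the on-bin Parseval identity is
$\sum_f a(f)^2 \cdot M/2 = \sum_t x_t^2$ (mean removed), which the
property suite asserts; an optional Hann window (amplitude-corrected by
the window sum) trades leakage for off-bin peak accuracy. Peak lookup
breaks exact amplitude ties toward the lower frequency.

`maxShiftCorrelation` scans every integer lag in `[-maxLag, maxLag]`,
computing the Pearson coefficient over the overlapping segment only (both
halves re-centered and re-scaled on the overlap). "All possible shifts"
must be bounded in practice — unbounded lags end in degenerate
few-sample overlaps — so the default is
`maxLag = min(N/2, 500)` samples with a minimum overlap of half the
trace. The maximum of the *signed* coefficient is returned (an
absolute-value mode exists but is not the default), with exact ties
resolved to the smallest |lag|, then the negative lag; positive lag means
the second trace is delayed relative to the first. The implementation is
FFT-based (cross-products plus prefix sums) and is held to 1e-12
agreement with a brute-force per-lag `cor()` oracle in the tests.
Classification against the conservative threshold 0.2 — roughly 4 SD
above the null distribution of maximal lagged correlations between
independent recordings, adopted as a constant rather than re-derived — is
inclusive at the boundary. A Monte-Carlo null (independent noise pairs)
confirms the threshold sits far above the observed null tail.

## Sweep segmentation and phase-locked response

Stepped sweeps hold each frequency $f_i$ for
`round(cyclesPerStep × rate / f_i)` samples (closed-open intervals tiling
the sweep; every step starts at phase 0). The phase-locked response per
step is the single-frequency discrete Fourier projection
$2\,|\sum_t x_t e^{-i 2\pi f_i t / f_s}|/M_i$ of the mean-subtracted
segment — identical to the FFT-bin amplitude when the step holds an
integer number of cycles, and robust when rounding makes the count
slightly non-integer, which is why projection was chosen over bin lookup.
Segments shorter than 16 samples are refused. Dispersion envelopes
(min–max across repeat sweeps) are attached by `aggregateCurves` when
repeats exist; single sweeps carry none.

# The synthetic-recording generator

The generator exists so that every stage above can be validated against
known ground truth. Its defaults describe one fixed set of study
conditions; they are not tuning knobs.

**Camera** (`CameraModel`): 1000 frames/s, 108.3 nm/px, 16-bit, gain
0.46 e⁻/count, read noise 1.6 counts — a standard high-speed sCMOS
operating point. Shot noise is Poisson, approximated as Gaussian with
variance counts/gain above 50 counts (error negligible there) and exact
Poisson below; frames are quantized with saturation clipping. Under the
default scene (background 800 counts) saturation is never approached.

**Bundle** (`BundleModel`): spontaneous motion is a two-state relaxation
oscillation — bullfrog bundle oscillations are relaxation-like, not
sinusoidal — with gamma-distributed dwell times (duty cycle 0.5, CV 0.5;
spontaneous oscillations are quite irregular), edges smoothed by a 2 ms
Gaussian low-pass, plus 3 nm of Gaussian position noise. Defaults: 8 Hz,
20 nm half-amplitude, within the range typical of sacculus preparations.
A pure sinusoid mode exists for analytic tests. Entrainment is a binary
threshold at 25 nm stimulus amplitude — between the 10 nm drive observed
to be ineffective and the 50 nm drive that entrains reliably — above
which the bundle follows the stimulus waveform plus position noise; a
full Arnold-tongue model is deliberately out of scope. While any probe
is attached (any nonzero-amplitude protocol), the spontaneous limit
cycle is scaled by `probeLoadFactor` (default 0.5): a stimulus fiber
stiff enough to drive a bundle also loads it, reducing spontaneous
amplitude. That loading, together with dwell-time decoherence (phase
memory of the CV-0.5 oscillator lasts ~1–2 cycles), is what keeps the
sub-threshold sweep response near the floor at every step, as the
acceptance suite requires.

**Sweeps** are stepped, 30 log-spaced frequencies over 1–100 Hz, 10
cycles per step. Whether real sweeps of this kind are stepped or
continuous, and how spaced, is generally unstated in the literature this
emulates; stepped-log is the documented stand-in, chosen because the
analysis (integer-cycle portions per frequency) is most natural on steps.

**Hotspots** (`HotspotSpec`): each hotspot's ΔI/I modulation is
`suppressionFactor × (gain × x(t − lag) + intrinsic noise)`; the lag is
rounded to whole samples. All hotspot physiology — gain, lag,
suppression, intrinsic noise — enters through the ground-truth traces
built by `makeGroundTruth`; `renderStack` then scales them by
`backgroundLevel × zAttenuation[z]` and paints an isotropic Gaussian blob
(SD = radius/2 — hot areas are diffuse, with no published profile to
copy) at the hotspot center of its z-section. This single point of
application keeps suppression from being double-counted and makes the
"tip-links-severed" dataset's modulation traces exactly zero by
construction. The true gain linking bundle displacement to somatic ΔI/I
is unknown; the default (0.002 ΔI/I per nm, i.e. 6% modulation for a
30 nm oscillation) is set so that detection operates at a realistic,
non-trivial SNR — hotspot σ roughly twice the shot-noise floor.

**Scene and depth**: a polygonal soma (15% brighter than background), a
Gaussian bundle ridge (contrast 0.8 × background, SD 2 px) rendered only
at z-section 0 — the focal plane at the stereocilia tips, matching the
acquisition order in which bundle motion is recorded before refocusing
deeper — and six axial sections with multiplicative depth attenuation
`exp(-z/2.5)` emulating the loss of modulation contrast deeper in the
tissue.

**Conditions and seeding**: one master seed; each component (bundle,
hotspot noise, per-z camera noise) draws from a stream derived by fixed
offsets, so control/treated pairs share every noise realization.
`"bapta"` (tip links severed) sets all suppression factors to 0 and
disables entrainment; `"salicylate"` (prestin block) changes nothing but
the manifest — the generative claim being that prestin plays no role in
these fluctuations. With the same master seed a salicylate dataset is
bit-identical to its control; the acceptance script therefore models the
salicylate *experiment* — two sequential recordings of unchanged
dynamics — by rendering the treated recording from a different seed, and
the resulting peak-amplitude change is a few percent, the measurement
repeatability of the pipeline.

## What the generator does and does not emulate

Emulated: relaxation-like spontaneous bundle kinematics with realistic
irregularity; entrainment above a threshold drive; lagged, depth-
attenuated, condition-dependent somatic modulation; camera shot/read
noise and quantization at 16 bits; paired-condition experiments.

Not emulated: optical point-spread blurring beyond per-section
attenuation; stereocilia fine structure; probe-artifact light; motion of
the soma itself; photobleaching or slow drift; spike-like excursions
between cycles at weak locking; any biophysical channel-gating model.
Consequently, passing tests demonstrate that the *analysis* is correct
and well-calibrated on data with the assumed statistical structure — they
do not certify performance on real recordings, where segmentation,
drift and optical artifacts dominate the difficulty.

# Numerical choices

- Lags, delays and sweep boundaries are exact integer sample counts;
  the hotspot lag is rounded to the nearest sample and its leading edge
  padded with the first value.
- Zero-variance overlaps in the lag scan are skipped (error only if all
  lags are degenerate); zero traces cannot be max-normalized; flat
  tracker profiles are errors, not zeros.
- The FFT cross-correlation pads to the next power of two ≥ Na + Nb, so
  circular wrap-around never contaminates a linear lag.
- `detectHotspots` uses the sample SD of the masked σ values for its
  threshold; with thousands of mask pixels the estimator choice is
  immaterial, and the brute-force tests pin the exact rule.
- Renders are chunked (≈8M pixels per chunk) with a fixed chunk rule, so
  memory stays bounded and the noise stream — hence the output — is
  independent of stack size only through the fixed rule, keeping renders
  bit-reproducible.
- Problem sizes in the validation suite (e.g. 128×128 × 3000 frames for
  end-to-end recovery, 48×48 for the ~67 000-frame sweep datasets, 10–20
  random stacks for oracle equivalence) were chosen as the smallest
  scenes that leave the relevant effects comfortably measurable.

# Interface notes

The package's surface is its exported functions plus this vignette; no
command-line wrapper is shipped, as every operation is a one-liner on the
S4 objects. TIFF metadata: the available TIFF writer cannot embed custom
description tags, so `writeStack` persists frame rate, pixel pitch and z
index in a JSON sidecar (`<path>.meta.json`); `readStack` honors
ImageJ-style description tags (`finterval`/`fps`, `pixelpitch`) when a
third-party file carries them, then the sidecar, then its arguments —
explicit arguments always win, and a missing frame rate is an error, not
a default.

# Known limitations

- The hotspot detector is a thresholding rule standing in for expert
  visual selection; on real heatmaps with structured backgrounds it will
  need a hand-drawn mask and possibly per-cell `kSigma`.
- The centroid tracker's amplitude shrinkage under broad ROIs (above) is
  intrinsic; use `gaussian_fit` or tight ROIs when amplitudes matter.
- The entrainment model is binary; near-threshold drives produce no
  partial locking, so phenomena like intermittent cycle slips cannot be
  studied with this generator.
- The correlation threshold 0.2 is adopted as a constant; its original
  derivation (a null over bundle pairs) involves parameters not
  re-derivable here, and the Monte-Carlo check in the suite is a
  consistency test, not a re-derivation.
- `zProfile` compares sequentially recorded sections, as in the
  experimental protocol it mirrors; it cannot distinguish depth
  attenuation from slow nonstationarity between recordings.
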