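# fluctmap

Label-free intensity-fluctuation activity mapping for hair-cell recordings.

## The problem

Hair cells of the inner ear transduce nanometer-scale deflections of their
hair bundle into ionic currents. The transduction cascade also perturbs the
soma itself — ion fluxes, membrane-potential changes and vesicle dynamics
alter the local refractive index — and those perturbations are visible as
tiny, localized fluctuations of transmitted light intensity in plain
wide-field, label-free microscopy at high frame rates. `fluctmap` implements
the analysis chain needed to find and quantify those fluctuations and relate
them to bundle motion:

- **Activity maps.** For a recording of N frames I_k, the per-pixel temporal
  mean μ = (1/N) Σ I_k and the population-normalized temporal SD
  σ = sqrt((1/N) Σ (I_k − μ)²), optionally after dividing each frame by its
  spatial background mean. σ is the "activity" heatmap.
- **Hotspot detection.** Pixels with σ above mean + k·SD of the masked σ
  distribution, grouped by 8-connectivity, become circular ROIs at their
  σ-weighted centroids.
- **ΔI/I traces.** Per frame, (mean ROI intensity − mean background) / mean
  background — the label-free analog of fluorescence ΔF/F.
- **Bundle tracking.** Sub-pixel position of the bundle ridge along its
  motion axis (floor-subtracted intensity centroid, or a 1D Gaussian +
  offset least-squares fit), converted to nm via the pixel pitch.
- **Coupling statistics.** The maximal Pearson correlation between two
  traces over all integer time shifts, with an inclusive classification
  threshold of 0.2 (≈4 SD above the null for independent recordings);
  normalized one-sided amplitude spectra (a pure sine of amplitude A gives
  a spectral amplitude A at its bin).
- **Entrainment curves.** For stepped 1–100 Hz frequency sweeps, the
  phase-locked response per 10-cycle step: the amplitude of the trace's
  component at the exact stimulus frequency (single-frequency Fourier
  projection).

Because raw recordings of this kind are not generally available, the package
ships a synthetic-recording simulator (`simulateBundle`, `renderStack`,
`makeDataset`) that generates ground-truth-annotated image stacks: a noisy
relaxation-oscillator (or sinusoidal) bundle, somatic hotspots whose
intensity is modulated coherently with lagged bundle motion across six axial
sections, pharmacological condition flags (tip-link severing, prestin
block), camera shot/read noise and 16-bit quantization. Every analysis stage
is validated against this generator and against brute-force oracles.

## Worked example

Simulate a 2-s control recording (64×64 px, 1000 fps) of a spontaneously
oscillating bundle (15 Hz, 30 nm) with one somatic hotspot, then run the
full pipeline:

```r
library(fluctmap)

sc     <- demoScene(shape = c(64, 64), seed = 1L)
bundle <- BundleModel(waveform = "sinusoid", naturalFrequency = 15,
                      amplitude = 30)
ds     <- makeDataset(sc, bundle, StimulusProtocol("none", duration = 2),
                      CameraModel(), condition = "control", seed = 1L)
stack  <- ds$stacks$z0
stack
#> ImageStack: 64 x 64 px, 2000 frames @ 1000 fps, 108.3 nm/px, 16-bit, z = 0

bg   <- backgroundRoi(sc)
amap <- temporalStats(stack, normalize = TRUE, background = bg,
                      mask = somaMask(sc))
hs   <- detectHotspots(amap)
hotspotTable(hs)
#>        row      col radius zIndex  peakSigma areaPx
#> 1 40.04731 19.13412      5     NA 0.06961347     22
```

The injected hotspot sits at (40, 19); the detector recovers it to a tenth
of a pixel. Extract its ΔI/I trace, track the bundle, and test coupling:

```r
tr      <- extractTrace(stack, hs[[1]]@roi, bg)
tracked <- trackBundle(stack, TrackerConfig(Roi(c(7, 32), 6,
                                                label = "bundle")))
maxShiftCorrelation(tracked, tr)
#> CorrelationResult: max corr 0.8715 at lag 0 samples (0 s); correlated (threshold 0.20)

unlist(peakMetrics(normalizedSpectrum(tr), band = c(2, 100)))
#> peakFrequency peakAmplitude
#>   15.00000000    0.02664376
```

The hotspot's intensity trace oscillates at the bundle frequency (15 Hz,
ΔI/I amplitude ≈ 2.7%) and is classified as correlated with the tracked
bundle motion (r = 0.87, far above the 0.2 threshold). A control ROI placed
outside the cell stays below threshold.

See the methods vignette (`vignettes/fluctmap-methods.Rmd`) for the model
behind the simulator, the default parameters and their rationale, and known
limitations.

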