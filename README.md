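# fiberT1 — fiber-orientation-dependent T1 relaxometry in white matter

T1 relaxation in white matter depends on the angle θ<sub>FB</sub> between
the axonal fiber direction and the main magnetic field B0. Across the field
strengths used in human neuroimaging, angular T1 profiles of coherent
(high-FA) white matter show two features: a quasi-linear increase of T1 from
parallel (0°) to perpendicular (90°) fibers, and a broad long-T1 hump
centered near 40° (a dip in the rate R1 = 1/T1). `fiberT1` is an R package
for scientists who want to measure these features quantitatively from their
own data — or to study the estimation chain itself on synthetic phantoms.

The package implements the full measurement chain:

* **Polarity-restored T1 mapping** from magnitude inversion-recovery TI
  series: the signed model *s(TI) = a + b·exp(−TI/T1)* is fit per voxel by a
  Nelder–Mead simplex search after re-negating the samples at or close to
  the minimum magnitude (several candidate sign assignments, best SSE
  retained), in a compiled core; plus the four-longest-TI variant that
  assumes all magnitudes positive. R1 maps are exact voxel-wise reciprocals.
* **Fiber-to-field angle maps** θ = arccos |V1 · B̂0| ∈ [0°, 90°] from
  principal diffusion eigenvectors, FA-window masks (strict lower bound,
  e.g. FA > 0.5) and block-mean volume downsampling.
* **Angular profiles**: 9°-binned mean/SD/count of T1, R1 and per-TI signal
  versus θ (1-D) and versus θ × FA (2-D).
* **Feature quantification**: Δ(0°–90°) with linear endpoint extrapolation
  through the 4.5° and 13.5° bins, the two-anchor baseline joining the
  0–20° and 80–90° window means, the baseline-subtracted 40° hump amplitude,
  its peak angle and interpolated FWHM, percent-of-mean features, and group
  aggregation with Welch/paired t tests.
* **A synthetic phantom**: uniform-on-sphere fiber directions (sin-θ angle
  law), single-pool angular T1 truth (linear term + Gaussian hump
  parameterised by FWHM) or a two-pool short/long-T1 mixture with
  field-dependent short T1 (≈120/260/540 ms at 1.5/3/7 T), and exact Rician
  magnitude noise — so every downstream stage is testable without scanner
  data.
* **A seeded pipeline driver** (`runPipeline()`) and a thin CLI
  (`inst/cli/fibert1`) that write NIfTI volumes, TSV tables and a hashed
  JSON manifest; re-running from the emitted config is bit-identical.

## Worked example

A 32³ phantom with 1.5 T-scale features — mask-mean T1 calibrated to
564.1 ms, injected linear span 27 ms, injected hump 23.5 ms / FWHM 34°,
six TIs {170, 340, 650, 1200, 2000, 3000} ms, Rician SNR 50 — analysed by
the full chain:

```r
library(fiberT1)

truth <- calibrateParallelT1(
  angularT1Model(500, delta090 = 27, humpAmplitude = 23.5,
                 humpCenter = 40, humpFwhm = 34),
  targetMean = 564.1
)
cfg <- runConfig(field = "1.5T", gridShape = c(32, 32, 32), truth = truth,
                 fracHigh = 1, seed = 42, fitModes = "all")
res <- runPipeline(cfg, outDir = file.path(tempdir(), "example"))
res$featureTable[, c("quantity", "delta_0_90", "hump_amplitude",
                     "pct_hump", "fwhm", "mean_value")]
#>   quantity delta_0_90 hump_amplitude pct_hump  fwhm mean_value
#> 1       t1   24.26167       20.79823    3.682 33.55    564.878
#> 2       r1    0.08013        0.06637    3.742 34.01      1.774

res$features$all$t1
#> AngularFeatureSet 't1':
#>   delta(0-90): 24.26 (4.3% of mean 564.88)
#>   hump: 20.80 (3.7%) at 40.5 deg, FWHM 33.6 deg
```

Reading the numbers: the 0°→90° T1 difference is recovered at 24.3 ms
(4.3 % of the mask-wide mean), the 40° hump at 20.8 ms peaking in the
40.5° bin with FWHM ≈ 34°. Recovered amplitudes sit ~10 % below the
injected truth by construction of the summary statistic: the two-anchor
baseline is slightly contaminated by a broad hump at its 13.5° anchor and
9° bins average the peak down — the methods vignette
(`vignettes/fiberT1-methods.Rmd`) discusses this and every other
convention. The R1 dip, 0.066 1/s here, is the reciprocal-propagated image
of the T1 hump.

On real data, replace the simulation with your co-registered inputs: a TI
series (`readTISeries()`, one 4-D NIfTI or one file per TI plus a JSON
sidecar with the TI list), a principal-eigenvector volume and an FA volume
(`readFiberField()`), then `fitT1Map()` → `computeThetaMap()` →
`angularProfile1D()` → `quantifyFeatures()`, or `runPipeline()` with
`inputs = list(tiSidecar = ..., v1 = ..., fa = ...)`.

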