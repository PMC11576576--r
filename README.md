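# pcctSPR

A self-contained **virtual study of proton stopping-power-ratio (SPR)
estimation from photon-counting CT (PCCT)** of the head, written as an R
package.

Proton treatment planning needs the stopping-power ratio of patient tissue
relative to water — the quantity whose line integral sets the proton range
and hence where the Bragg peak lands. Clinically, SPR is inferred from CT
Hounsfield units, an uncertain conversion because photon attenuation and
proton stopping depend differently on tissue composition. This package
builds the entire experiment in software, with known ground truth at every
pixel, for researchers studying HU→SPR conversion methods:

* **Tissue physics** — relative electron density
  ρₑ = ρ N_A Σωᵢ Zᵢ/Aᵢ / ρₑ,w, electron-weighted log-average mean
  ionization energy I, and the Bethe ratio
  SPR = ρₑ · (ln[2mₑc²β²/((1−β²)I)] − β²) / (ln[2mₑc²β²/((1−β²)I_w)] − β²)
  at β = 0.461376419 (≈100 MeV protons), on embedded ICRU-style tissue
  compositions.
* **Digital head phantoms** — procedural skin/skull/adipose/gray/white/
  whole-brain ellipsoids at 0.25 mm voxels; the default dataset is 6
  phantoms (203–224 mm diameters) × 281 slices = 1686 example slices.
* **A PCCT simulator** — polyenergetic parallel-beam projection of
  polyethylene/PVC basis maps, 8 energy bins, quantum + electronic Poisson
  noise, per-ray maximum-likelihood material decomposition, ramp-filtered
  back-projection, and virtual monoenergetic image (VMI) synthesis.
* **Three estimators** — a U-Net (40/70 keV VMI pair → SPR map, trained
  with L1/MSE/perceptual-composite losses), single-energy stoichiometric
  calibration with a piecewise-linear HLUT, and a VMI-pair method solving
  for effective atomic number and electron density.
* **Evaluation** — per-ROI RMSE / relative error / relative SD (in
  percent), HU-binned error histograms, and line profiles.

See the methods vignette (`vignettes/virtual-spr-study.Rmd`) for the model,
its assumptions, parameter defaults, and limitations.

## Worked example

Calibrate a head HLUT on the generic insert set, apply it to a noise-free
70 keV VMI of a head slice, and score it against ground truth:

```r
library(pcctSPR)

spec <- phantomSpec(headDiameter = 215, nSlices = 3, pixelSize = 0.9, seed = 4)
vol  <- generateHeadPhantom(spec, slices = 2)
truth <- sprGroundTruthMap(vol, 1)

hl  <- stoichiometricCalibrate(defaultInserts(70), energy = 70)
hl
#> HLUT: 5 knots over [-1000, 3000] HU
#>     HU    SPR
#>  -1000 0.0000
#>   -120 0.9346
#>    100 1.0796
#>    300 1.1256
#>   3000 2.2023

est  <- applyHLUT(hl, syntheticVMI(vol, 1, 70))
rois <- placeROIs(phantomLabels(vol)[, , 1], materialTable(vol), seed = 1)
m <- roiMetrics(truth, est, rois)
m[m$roi == "mean", ]
#>             material  roi  n rmse_pct rel_error_pct rel_sd_pct
#>    brain_gray_matter mean 75    0.630        0.6089          0
#>   brain_white_matter mean 64    0.155        0.1500          0
#>          brain_whole mean 75    0.375        0.3621          0
#>  skull_cortical_bone mean 72    0.152        0.0898          0
```

The HLUT knots are the calibrated HU→SPR breakpoints (air at −1000 HU maps
to 0; cortical-bone HU map to SPR ≈ 1.7). The table converts noise-free
brain-tissue HU with sub-percent RMSE; the zero relative SD columns reflect
that a pixelwise lookup adds no noise to a noise-free image.

The simulated chain replaces `syntheticVMI()` with
`simulateSinogram() |> mlDecompose() |> fbpReconstruct() |> makeVMI()`,
and the learned estimator with `trainModel()` / `predictSPR()`; the
vignette walks through both.

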