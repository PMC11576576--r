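---
title: "A virtual photon-counting CT study of proton stopping-power estimation"
author: "pcctSPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual photon-counting CT study of proton stopping-power estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcctSPR)
```

## The problem

Proton treatment planning converts CT Hounsfield units (HU) into the proton
stopping-power ratio (SPR) of tissue relative to water, because the proton
range in a patient is governed by the line integral of SPR along the beam.
The conversion is uncertain: HU measures photon attenuation while SPR is a
function of electron density and mean excitation energy, and the two depend
differently on elemental composition. `pcctSPR` builds a fully simulated
("virtual") testbed in which this conversion can be studied with a known
ground truth: digital head phantoms with per-voxel tissue compositions, an
energy-binned photon-counting CT (PCCT) simulator, virtual monoenergetic
images (VMIs), and three estimators — a learned U-Net domain transform from
a VMI pair to an SPR map, a single-energy stoichiometric calibration with a
piecewise-linear lookup table (HLUT), and a VMI-pair method that solves for
effective atomic number and electron density.

## Physics model

Ground truth is defined at the material level. For a material with mass
density $\rho$ and elemental mass fractions $\omega_i$,

$$\rho_e = \frac{\rho N_A \sum_i \omega_i Z_i / A_i}{\rho_{e,w}}, \qquad
  I = \exp\!\left(\frac{\sum_i \omega_i \tfrac{Z_i}{A_i}\ln I_i}
                      {\sum_i \omega_i \tfrac{Z_i}{A_i}}\right),$$

and the SPR is the plain Bethe ratio without shell or density-effect
corrections,

$$\mathrm{SPR} = \rho_e\,
  \frac{\ln\!\frac{2 m_e c^2 \beta^2}{(1-\beta^2) I} - \beta^2}
       {\ln\!\frac{2 m_e c^2 \beta^2}{(1-\beta^2) I_w} - \beta^2}.$$

The default beam uses the literal speed ratio $\beta = 0.461376419$
(nominally a 100 MeV proton under the non-relativistic relation
$\beta = \sqrt{2T/m_pc^2}$; the printed $\beta$ does not exactly match that
closed form for the standard proton rest energy, so the literal value is
kept as the study parameter and `betaFromKineticEnergy()` is provided
separately). The water normalizers $\rho_{e,w}$ and $I_w$ are always derived
from the embedded water composition ($\omega_H = 0.111894$,
$\omega_O = 0.888106$), never hard-coded; with the ICRU-style elemental $I$
values this gives $I_w \approx 69.0$ eV.

```{r}
stoppingPowerRatio(getMaterial("brain_whole"))
stoppingPowerRatio(getMaterial("skull_cortical_bone"))
```

### Embedded tables and their provenance

Elemental mean excitation energies follow the ICRU-37 convention. The
per-element mass attenuation tables shipped in `inst/extdata/` are
**parametric**: the incoherent term is the exact Klein–Nishina total cross
section per electron, and the photoelectric and coherent terms are power
laws $Z^{4.62}/E^{p}$ and $Z^{2.5}/E^{q}$ whose four constants were fitted
once to reference water mass-attenuation values over 10–150 keV (residuals
below 0.15 % across the range). They are therefore smooth, self-consistent
stand-ins for measured compilations rather than a redistribution of them.
Every part of the study — ground-truth HU, the CT forward model, the
decomposition, and both calibration baselines — uses the same tables, so
the virtual study closes on itself; absolute deviations from published
attenuation data would shift all components together without changing the
comparisons made here. The 120 kV source spectrum is likewise parametric
(Kramers bremsstrahlung filtered by 6 mm aluminium, tabulated at 1 keV,
mean energy ≈ 58.5 keV).

## Digital head phantoms

`generateHeadPhantom()` builds an elliptical head: a 2.5 mm skin ring, a
6.5 mm skull ring, an adipose-filled gap, and a brain interior partitioned
into a cortical gray-matter ribbon (3 mm), an optional mixed "whole brain"
annulus (2 mm) standing in for structures that are neither purely white nor
purely gray, and a white-matter core. The gray/white boundary is perturbed
by a seeded sum of angular harmonics ("lobed" pattern) so that phantoms
differ anatomically; cross sections shrink along the axis as the central
window of a spheroidal dome, emulating the selection of central slices from
a larger scan. Voxel defaults are 0.25 mm in-plane and 0.416 mm slices.

The default dataset mirrors the study conditions: six phantoms with
long-axis diameters 203, 208, 209, 215, 223 and 224 mm and 281 slices each,
1686 example slices in total, split 64/16/20 into train/validation/test by
a seeded shuffle (80/20 applied twice). `makeDataset()` returns a lazy
manifest; `realizeExample()` renders a slice as a 40/70 keV VMI pair plus
its ground-truth SPR map at any requested grid size.

What the generator does **not** emulate: real cortical folding, CSF,
ventricles, air sinuses, partial-volume mixtures (every voxel is a single
material), pathology, and pediatric anatomy. Tests passing on these
phantoms therefore demonstrate correctness of the pipeline and
self-consistency of the physics, not clinical performance.

## The PCCT simulator

The scanner model is deliberately reduced to the parts that matter for SPR
estimation downstream of reconstruction:

* **Geometry** — parallel-beam, 4000 views over 180° by default, 350 mm
  reconstruction FOV. A parallel geometry was chosen because its filtered
  back-projection is exactly invertible, which keeps reconstruction bias
  out of the comparisons; the interface carries a geometry field should a
  fan-beam variant be added.
* **Source** — the embedded 120 kV spectrum; tube current and rotation time
  are abstracted into `airCounts`, the expected photons per ray in an air
  scan (default $10^5$), since absolute fluence of a real tube cannot be
  recovered without a specific detector model.
* **Detector** — ideal energy response (no crosstalk or pile-up, matching a
  system with perfect corrections); 8 bins between 20 and 120 keV placed at
  equal expected air counts by default. Electronic noise enters as
  Poisson-distributed spurious counts in the lowest bin, defaulting to 1 %
  of that bin's air counts — the mechanism is part of the study design, the
  magnitude is a package choice.
* **Forward model** — per ray, PE/PVC line integrals $(A_1, A_2)$ of the
  basis-coefficient maps (Eq. below), expected counts
  $\lambda_b = \sum_E S_b(E)\, e^{-A_1 \mu_{PE}(E) - A_2 \mu_{PVC}(E)}$,
  Poisson sampling when noise is on.

Tissue attenuation is compressed into two basis materials, polyethylene
(PE) and polyvinyl chloride (PVC), by solving per voxel

$$a_1 \mu_{PE}(E_k) + a_2 \mu_{PVC}(E_k) = \mu(E_k), \quad E_k \in \{40, 70\}\,\text{keV}.$$

**Material decomposition.** `mlDecompose()` maximizes the Poisson
log-likelihood of the binned counts per ray with a damped
(Levenberg–Marquardt) Newton iteration, initialized from a log-ratio solve
of the two outermost bins at their effective energies; the damping is
increased for any ray whose candidate step does not decrease the negative
log-likelihood, which keeps heavily attenuated rays (nearly empty bins) on
a stable descent path. Tolerance is $10^{-8}$ on the parameter step with at
most 50 iterations; rays that still fail are imputed from neighboring
detectors and counted. On noise-free data the solver inverts the forward
model to better than $10^{-6}$ cm over line integrals up to 40 cm PE and
4 cm PVC.

**Reconstruction.** Ram-Lak (ramp) filtering with the standard discrete
real-space kernel, then pixel-driven back-projection per basis channel. No
denoising of any kind is applied. VMIs at arbitrary energies follow by
linear recombination and the HU mapping
$\mathrm{HU} = 1000 (\mu - \mu_w)/(\mu_w - \mu_a)$.

Because exactly two basis functions generate the data and the decomposition
uses the exact spectrum, beam hardening cancels: a noise-free 200 mm water
cylinder reconstructs to within a fraction of an HU of zero at both 40 and
70 keV (the acceptance script prints the achieved values).

## Baseline estimators

**Stoichiometric HLUT.** The calibration follows the standard head
workflow: (i) fit the three-parameter model
$\mu/\mu_w = \rho_e (k_1 \tilde{Z}^{3.62}\text{-term} + k_2
\tilde{Z}^{1.86}\text{-term} + k_3)$ to the measured HU of the insert set
by linear least squares (photoelectric, coherent, Compton terms); (ii)
predict HU for the embedded reference tissues; (iii) pair them with
Bethe-Bloch SPR; (iv) fit soft- and bone-tissue regression lines and
assemble a continuous piecewise-linear table with connection knots at
−1000, −120, 100, 300 and 3000 HU (configurable; the guide the workflow
follows leaves these to its published code, so they are package defaults).
Insert HU are measured as the mean of a circular ROI covering 70 % of the
insert cross-section over 12 slices. The shipped insert set is a generic,
documented stand-in for a commercial electron-density phantom (lung,
adipose, solid-water, muscle, liver and graded bone equivalents): the
calibration procedure, not the insert brand, is under study.

**VMI-pair method.** From two VMIs at energies $E_1 < E_2$, each pixel's
attenuation pair is inverted to (effective atomic number, relative electron
density) under the two-term electronic cross-section model
$\sigma_e(E, Z) = c_0(E) + c_1(E) Z^{m-1}$ with the Mayneord exponent
$m = 3.21$; $c_0, c_1$ are least-squares fits over the elements H–Ca at
each energy. Two self-consistency calibrations absorb the residuals of
this deliberately small model: the $\ln I$-versus-$Z_\mathrm{eff}$ lines
(separate soft and bone branches) are fitted against the *apparent*
effective atomic number that the same inversion assigns to the reference
tissues at the chosen energy pair, and the electron-density scale is
normalized so that water is exact. Both are calibrations the physical
method performs against known materials; neither uses the image under
test. `optimizeVMIPair()` scores every unordered pair in 40–140 keV by
insert-set RMSE and returns the argmin (ties to the lexicographically
smaller pair). With noise-free synthetic VMIs the optimum drifts toward
high, closely spaced energies where the two-term model is most accurate —
under realistic noise the optimum moves down in energy, and the original
method's sensitivity of this ranking to the insert selection is a known
caveat; the package reports the pair rather than asserting a particular
one.

## The U-Net

`buildModel()` assembles an encoder–decoder with skip connections, one
residual block per resolution, channel widths `baseFeatures` ×
(1, 1, 2, 2, 2, 2, 2), average-pool downsampling and nearest-neighbor
upsampling — no time embeddings and no FIR anti-aliasing. Each residual
branch's final convolution starts at zero so every block is an identity at
initialization, which keeps the 15-block stack well-scaled without
normalization layers. Inputs are the 40/70 keV VMI pair scaled by 1/1000;
targets are physical SPR. Adam uses the study settings (learning rate
$10^{-4}$, $\beta_1 = 0.5$, $\beta_2 = 0.9$, batch size 2), and the
composite loss is

$$\mathrm{VGG16\_L1} = \lambda_1\,\mathrm{MSE}(F(\hat{y}), F(y)) +
  \lambda_2\,\mathrm{L1}(\hat{y}, y), \qquad \lambda_1 = \lambda_2 = 1,$$

with $F$ a perceptual feature extractor. No pretrained VGG16 weights ship
with the package (they require a download); the perceptual variants accept
a user-supplied extractor and otherwise raise an instructive error, and all
training in the tests uses the pure L1 loss, the second-best variant in the
original loss comparison. With $\lambda_1 = 0$ the composite reduces
bit-for-bit to L1.

### Desk-scale training protocol

The full protocol (256×256 inputs, 64 base features, 350 epochs, 15
repeats) is a multi-hour GPU workload. The package's CPU-scale protocol,
used by the tests and the acceptance script, is an overfit task chosen to
exercise the full training loop end to end: 8 noise-free slices at 64×64,
12 base features, L1 loss, 200 epochs. Two optimizer adjustments reflect
the 300-fold smaller step budget rather than any change of method: the
learning rate is raised to $3\times10^{-3}$ and decays to zero on a cosine
schedule (`lrSchedule = "cosine"`), because the L1 gradient's constant
magnitude otherwise leaves a weight-oscillation floor at the learning-rate
scale. At 64×64 the skull ring and gray ribbon are only one or two pixels
wide, so region statistics there measure boundary behavior rather than
conversion accuracy; the desk-scale success criterion is therefore
evaluated on white-matter ROIs, the one material with a genuinely
homogeneous interior at that resolution. `repeatTraining()` implements the
repeated-training variability protocol (mean ± sample SD of per-ROI scores
across seeds).

## Evaluation

`roiMetrics()` computes, per ROI with constant true value $T$ and
estimates $e$,

$$\mathrm{RMSE} = 100\sqrt{\tfrac1N \sum (T - e)^2}, \quad
  \mathrm{rel.err} = 100\,\frac{|T - \bar{e}|}{T}, \quad
  \mathrm{rel.SD} = \frac{100}{T}\sqrt{\tfrac{1}{N-1}\sum (e - \bar{e})^2},$$

with the sample (N−1) standard deviation and a missing value (not zero)
when a ROI has fewer than two pixels. Default ROI pixel counts per material
are white matter 20/20/24, gray matter 24/24/27, whole brain 24/27/24 and
skull 24/24/24. ROI coordinates are not prescribed anywhere, so
`placeROIs()` chooses them procedurally: candidate centers are pixels whose
neighborhood lies entirely inside the material, three well-separated
centers are picked greedily from a seeded start, and each ROI collects the
nearest material pixels without overlap. `huBinnedErrorHistogram()` groups
signed SPR errors (estimate minus truth, in percent) of all body pixels by
VMI HU — one bin below 0, ten 10-HU bins to 100, one bin above —
partitioning the body mask exactly. `lineProfile()` extracts matched image
rows for boundary inspection.

## Numerical choices and degenerate inputs

* Air SPR is 0 by convention (the Bethe ratio is undefined at $\rho = 0$);
  air pixels are excluded from ROI metrics and histograms.
* All images are stored as doubles; HU are never rounded.
* The HLUT is clamped to its end segments outside [−1000, 3000] HU and is
  checked for monotonicity at calibration time (a warning reports negative
  segment slopes).
* The VMI-pair inversion clamps pixels whose attenuation ratio leaves the
  fitted $Z_\mathrm{eff}$ range to the nearest grid value and counts them;
  near-air pixels (μ below 0.005 cm⁻¹) get SPR 0 directly.
* A zero-intensity source produces an all-zero scan; a single-material
  phantom with density 0 produces zero attenuation and −1000 HU.
* Every random element (phantom lobes, splits, noise, weight
  initialization, shuffling, ROI seeding) flows from explicit integer
  seeds, and the RNG state of the session is saved and restored around
  seeded internals.

## Problem sizes used by the tests

The shipped tests and the acceptance script run the simulator at 800 views
× 256 detectors on 256² phantom grids (128–512² reconstructions), train the
desk-scale network for 200 epochs on 8 slices, and evaluate baselines on
0.7–1.4 mm phantom renderings. The noisy head-slice evaluation uses
5×10⁵ photons per ray so that its 800 views carry the same total photon
budget as the 4000-view default at 10⁵. These sizes are the package's desk-scale
study conditions; the full-scale settings (4000 views, 512 detectors, 512²
reconstruction, 256×256 training at 64 features) remain the documented
defaults of the respective constructors.

## Known limitations

* The phantom is a geometric stand-in; no claim of anatomical realism.
* Parallel-beam only; no bowtie filtration, scatter, crosstalk, pile-up,
  detector drift, or helical trajectories.
* The attenuation tables are parametric fits anchored to water, not a
  measured compilation.
* No pretrained perceptual weights; the shipped loss variants usable
  offline are L1 and MSE (plus the composite with a user extractor).
* SPR is evaluated per pixel; beam-range (water-equivalent path length)
  metrics are out of scope.
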