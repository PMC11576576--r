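# S4 classes for the virtual PCCT/SPR study.

#' Material: a named tissue or insert with density and elemental composition
#'
#' @slot name material name
#' @slot rho mass density in g/cm^3
#' @slot fractions named numeric vector of elemental mass fractions (sums to 1)
#' @exportClass Material
setClass("Material",
  representation(name = "character", rho = "numeric", fractions = "numeric"))

setValidity("Material", function(object) {
  msg <- character()
  if (length(object@rho) != 1 || is.na(object@rho) || object@rho < 0)
    msg <- c(msg, "rho must be a single nonnegative number")
  if (length(object@fractions) < 1 || is.null(names(object@fractions)))
    msg <- c(msg, "fractions must be a named numeric vector")
  if (any(object@fractions < 0)) msg <- c(msg, "fractions must be nonnegative")
  if (abs(sum(object@fractions) - 1) > 1e-6)
    msg <- c(msg, "fractions must sum to 1 within 1e-6")
  if (length(msg)) msg else TRUE
})

#' Physics constants derived from the embedded water/air compositions
#'
#' `rhoEWaterAbs` (electrons/cm^3) and `IWater` (eV) are always computed from
#' the embedded water composition, never hard-coded.
#'
#' @slot avogadro Avogadro's constant (1/mol)
#' @slot meC2 electron rest energy (keV)
#' @slot rhoEWaterAbs absolute electron density of water (electrons/cm^3)
#' @slot IWater mean ionization energy of water (eV)
#' @slot water,air the water and air [Material] objects used as normalizers
#' @exportClass PhysicsConstants
setClass("PhysicsConstants",
  representation(avogadro = "numeric", meC2 = "numeric",
                 rhoEWaterAbs = "numeric", IWater = "numeric",
                 water = "Material", air = "Material"))

#' Proton beam parameterized by its speed ratio
#' @slot beta speed relative to light, in (0, 1)
#' @slot kineticEnergy nominal kinetic energy in MeV (informational)
#' @exportClass ProtonBeam
setClass("ProtonBeam",
  representation(beta = "numeric", kineticEnergy = "numeric"))

setValidity("ProtonBeam", function(object) {
  if (length(object@beta) != 1 || object@beta <= 0 || object@beta >= 1)
    "beta must lie strictly between 0 and 1" else TRUE
})

#' Specification of a procedural head phantom
#'
#' @slot headDiameter long-axis diameter in mm
#' @slot aspectRatio short/long axis ratio
#' @slot skullThickness,skinThickness ring thicknesses in mm
#' @slot gapThickness adipose gap between brain and skull in mm
#' @slot grayThickness,wholeBrainThickness cortical gray ribbon and mixed
#'   whole-brain annulus thicknesses in mm (whole-brain may be 0)
#' @slot nSlices number of axial slices
#' @slot pixelSize in-plane voxel size in mm
#' @slot sliceThickness slice width in mm
#' @slot margin air margin around the head in mm
#' @slot seed integer seed for the gray/white boundary pattern
#' @slot grayWhitePattern "lobed" or "concentric"
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(headDiameter = "numeric", aspectRatio = "numeric",
                 skullThickness = "numeric", skinThickness = "numeric",
                 gapThickness = "numeric", grayThickness = "numeric",
                 wholeBrainThickness = "numeric", nSlices = "integer",
                 pixelSize = "numeric", sliceThickness = "numeric",
                 margin = "numeric", seed = "integer",
                 grayWhitePattern = "character"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@skullThickness <= 0) msg <- c(msg, "skullThickness must be > 0")
  if (object@skinThickness <= 0) msg <- c(msg, "skinThickness must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@nSlices < 1) msg <- c(msg, "nSlices must be >= 1")
  if (!object@grayWhitePattern %in% c("lobed", "concentric"))
    msg <- c(msg, "grayWhitePattern must be 'lobed' or 'concentric'")
  if (length(msg)) msg else TRUE
})

#' A voxelized phantom: 3D material label map plus material table
#'
#' @slot labels integer array (x, y, slice) of material IDs
#' @slot materialTable named list mapping label ID (as character) to [Material]
#' @slot spec the generating [PhantomSpec]
#' @exportClass PhantomVolume
setClass("PhantomVolume",
  representation(labels = "array", materialTable = "list", spec = "PhantomSpec"))

setValidity("PhantomVolume", function(object) {
  ids <- sort(unique(as.integer(object@labels)))
  known <- sort(as.integer(names(object@materialTable)))
  if (!all(ids %in% known))
    sprintf("labels contain IDs without material table entries: %s",
            paste(setdiff(ids, known), collapse = ", "))
  else TRUE
})

#' Basis-material coefficient maps (polyethylene and PVC fractions)
#' @slot a1,a2 matrices of PE and PVC coefficients
#' @slot energies the two fit energies in keV
#' @slot pixelSize in-plane pixel size in mm
#' @exportClass BasisCoefficientMaps
setClass("BasisCoefficientMaps",
  representation(a1 = "matrix", a2 = "matrix", energies = "numeric",
                 pixelSize = "numeric"))

setValidity("BasisCoefficientMaps", function(object) {
  if (!all(dim(object@a1) == dim(object@a2))) "a1 and a2 must share dimensions"
  else TRUE
})

#' A per-pixel stopping-power-ratio map
#' @slot values matrix of SPR values (dimensionless; air carries 0)
#' @slot provenance one of ground_truth, predicted_dl, predicted_hlut,
#'   predicted_na
#' @exportClass SPRMap
setClass("SPRMap",
  representation(values = "matrix", provenance = "character"))

setValidity("SPRMap", function(object) {
  ok <- c("ground_truth", "predicted_dl", "predicted_hlut", "predicted_na")
  if (!object@provenance %in% ok)
    paste("provenance must be one of:", paste(ok, collapse = ", "))
  else TRUE
})

#' CT scan geometry
#' @slot nViews number of view angles over 180 degrees (parallel beam)
#' @slot nDetectors number of detector channels
#' @slot fov reconstruction field of view in mm (also the detector span)
#' @slot geometry "parallel"
#' @slot reconPixels reconstructed image side length in pixels
#' @slot reconSliceThickness mm
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(nViews = "integer", nDetectors = "integer", fov = "numeric",
                 geometry = "character", reconPixels = "integer",
                 reconSliceThickness = "numeric"))

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (object@nViews < 2) msg <- c(msg, "nViews must be >= 2")
  if (object@nDetectors < 2) msg <- c(msg, "nDetectors must be >= 2")
  if (!object@geometry %in% "parallel")
    msg <- c(msg, "only parallel-beam geometry is implemented")
  if (length(msg)) msg else TRUE
})

#' X-ray source model: tabulated spectrum and photon budget
#' @slot kv tube voltage (kV)
#' @slot spectrum data.frame with columns energy_keV, relative_fluence
#' @slot airCounts expected total photons per ray in an air scan
#' @exportClass SourceModel
setClass("SourceModel",
  representation(kv = "numeric", spectrum = "data.frame", airCounts = "numeric"))

setValidity("SourceModel", function(object) {
  msg <- character()
  if (any(object@spectrum$relative_fluence < 0))
    msg <- c(msg, "spectrum must be nonnegative")
  if (any(object@spectrum$relative_fluence[object@spectrum$energy_keV > object@kv] > 0))
    msg <- c(msg, "spectrum must vanish above the tube voltage")
  if (object@airCounts < 0) msg <- c(msg, "airCounts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Photon-counting detector model
#' @slot binEdges strictly increasing keV thresholds (length nBins + 1)
#' @slot electronicNoise expected spurious counts per ray in the lowest bin
#' @slot idealEnergyResponse always TRUE (no crosstalk/pileup model)
#' @exportClass DetectorModel
setClass("DetectorModel",
  representation(binEdges = "numeric", electronicNoise = "numeric",
                 idealEnergyResponse = "logical"))

setValidity("DetectorModel", function(object) {
  msg <- character()
  if (length(object@binEdges) < 3) msg <- c(msg, "need at least 2 energy bins")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (object@binEdges[1] <= 0) msg <- c(msg, "lowest bin edge must be > 0")
  if (length(msg)) msg else TRUE
})

#' Energy-binned sinogram of photon counts
#' @slot counts array [view, detector, bin]
#' @slot geometry,source,detector provenance objects
#' @slot noise whether Poisson noise was applied
#' @exportClass BinnedSinogram
setClass("BinnedSinogram",
  representation(counts = "array", geometry = "ScanGeometry",
                 source = "SourceModel", detector = "DetectorModel",
                 noise = "logical"))

#' Basis-material line-integral sinogram (cm of PE and PVC)
#' @slot A1,A2 matrices [view, detector]
#' @slot geometry scan geometry
#' @slot nonConverged number of rays that failed the likelihood solve
#' @exportClass BasisSinogram
setClass("BasisSinogram",
  representation(A1 = "matrix", A2 = "matrix", geometry = "ScanGeometry",
                 nonConverged = "integer"))

#' A calibration insert with measured Hounsfield units
#' @slot material insert [Material]
#' @slot category "lung", "soft" or "bone"
#' @slot measuredHU named numeric vector, names are energies in keV
#' @exportClass CalibrationInsert
setClass("CalibrationInsert",
  representation(material = "Material", category = "character",
                 measuredHU = "numeric"))

setValidity("CalibrationInsert", function(object) {
  if (!object@category %in% c("lung", "soft", "bone"))
    "category must be lung, soft or bone"
  else if (any(!is.finite(object@measuredHU))) "measuredHU must be finite"
  else TRUE
})

#' Piecewise-linear HU to SPR lookup table
#'
#' Stored as knots (HU) and values (SPR); the function is the linear
#' interpolant between consecutive knots, clamped outside the domain.
#' @slot knots ordered HU breakpoints covering at least [-1000, 3000]
#' @slot values SPR at the knots
#' @slot fit list of calibration details (stoichiometric parameters, residuals)
#' @exportClass HLUT
setClass("HLUT",
  representation(knots = "numeric", values = "numeric", fit = "list"))

setValidity("HLUT", function(object) {
  msg <- character()
  if (length(object@knots) != length(object@values))
    msg <- c(msg, "knots and values must have equal length")
  if (any(diff(object@knots) <= 0)) msg <- c(msg, "knots must be increasing")
  if (object@knots[1] > -1000 || object@knots[length(object@knots)] < 3000)
    msg <- c(msg, "knots must cover [-1000, 3000] HU")
  if (length(msg)) msg else TRUE
})

#' Effective-atomic-number model for the VMI-pair SPR estimator
#' @slot mayneordExponent exponent m of the Z^(m-1) cross-section term
#' @slot energies keV grid of the per-energy cross-section fits
#' @slot c0,c1 per-energy electronic cross-section coefficients
#' @slot softLnI,boneLnI (intercept, slope) of ln I vs Zeff for soft/bone
#' @slot zeffSplit threshold Zeff between the soft and bone branches
#' @slot zeffGrid,zGridSigma Zeff inversion grid and per-energy cross sections
#' @slot tissueMu reference-tissue linear attenuations on the energy grid
#' @slot tissueLnI,tissueCat reference-tissue log mean ionization energies
#'   and categories, used for pair-specific ln I calibration
#' @exportClass ZeffModel
setClass("ZeffModel",
  representation(mayneordExponent = "numeric", energies = "numeric",
                 c0 = "numeric", c1 = "numeric", softLnI = "numeric",
                 boneLnI = "numeric", zeffSplit = "numeric",
                 zeffGrid = "numeric", zGridSigma = "matrix",
                 tissueMu = "matrix", tissueLnI = "numeric",
                 tissueCat = "character"))

#' Training configuration for the U-Net SPR regressor
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(learningRate = "numeric", adamBeta1 = "numeric",
                 adamBeta2 = "numeric", batchSize = "integer",
                 epochs = "integer", baseFeatures = "integer",
                 channelMultipliers = "integer", inputSize = "integer",
                 loss = "character", lambda1 = "numeric", lambda2 = "numeric",
                 splitRatio = "numeric", seed = "integer", nRepeats = "integer",
                 lrSchedule = "character"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@loss %in% c("MSE", "L1", "VGG16", "VGG16_L1"))
    msg <- c(msg, "loss must be one of MSE, L1, VGG16, VGG16_L1")
  if (object@splitRatio <= 0 || object@splitRatio >= 1)
    msg <- c(msg, "splitRatio must lie in (0, 1)")
  lv <- length(object@channelMultipliers)
  if (object@inputSize %% 2L^(lv - 1L) != 0L)
    msg <- c(msg, sprintf("inputSize must be divisible by 2^%d", lv - 1L))
  if (length(msg)) msg else TRUE
})

#' A (possibly trained) U-Net model with its parameters and normalization
#' @slot params named list of weight arrays
#' @slot config the [TrainConfig]
#' @slot arch architecture description (layer widths per level)
#' @slot normalization input/output affine scaling parameters
#' @slot log per-epoch training/validation loss data.frame
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(params = "list", config = "TrainConfig", arch = "list",
                 normalization = "list", log = "data.frame"))

#' A lazily realized phantom dataset (manifest of example slices)
#' @slot manifest data.frame with phantom_id, slice_index, split
#' @slot specs list of per-phantom [PhantomSpec]
#' @exportClass PhantomDataset
setClass("PhantomDataset",
  representation(manifest = "data.frame", specs = "list"))
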