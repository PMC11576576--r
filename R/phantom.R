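# Procedural digital head phantoms with known per-voxel materials.
#
# Each axial slice is a set of nested ellipses: skin ring, skull ring, an
# adipose-filled gap, and a brain interior partitioned into a cortical gray
# ribbon, an optional mixed "whole brain" annulus, and a white-matter core.
# The gray/white boundary can be perturbed by a seeded sum of angular
# harmonics ("lobed" pattern). Cross sections shrink smoothly toward the
# vertex along the axis, emulating a head-shaped dome.

# label IDs (fixed)
.LBL <- c(air = 0L, skin = 1L, skull = 2L, adipose = 3L,
          white = 4L, gray = 5L, whole_brain = 6L)

.phantomMaterialTable <- function(includeWholeBrain = TRUE) {
  tb <- list("0" = getMaterial("air"),
             "1" = getMaterial("skin"),
             "2" = getMaterial("skull_cortical_bone"),
             "3" = getMaterial("adipose"),
             "4" = getMaterial("brain_white_matter"),
             "5" = getMaterial("brain_gray_matter"))
  if (includeWholeBrain) tb[["6"]] <- getMaterial("brain_whole")
  tb
}

#' Specification of a procedural head phantom
#'
#' Defaults mirror the study protocol: skull 6.5 mm, skin 2.5 mm, pixel
#' 0.25 mm, slice 0.416 mm, 281 slices.
#'
#' @param headDiameter long-axis diameter in mm
#' @param aspectRatio short/long axis ratio of the head ellipse
#' @param skullThickness,skinThickness ring thicknesses in mm
#' @param gapThickness adipose gap between brain and skull in mm
#' @param grayThickness cortical gray-matter ribbon thickness in mm
#' @param wholeBrainThickness mixed whole-brain annulus thickness in mm
#'   (0 disables the annulus)
#' @param nSlices number of axial slices
#' @param pixelSize in-plane voxel size in mm
#' @param sliceThickness slice width in mm
#' @param margin air margin around the head in mm
#' @param seed seed for the gray/white boundary pattern
#' @param grayWhitePattern "lobed" (default) or "concentric"
#' @return a [PhantomSpec]
#' @export
phantomSpec <- function(headDiameter = 215, aspectRatio = 0.78,
                        skullThickness = 6.5, skinThickness = 2.5,
                        gapThickness = 1.5, grayThickness = 3,
                        wholeBrainThickness = 2, nSlices = 281L,
                        pixelSize = 0.25, sliceThickness = 0.416,
                        margin = 6, seed = 1L,
                        grayWhitePattern = "lobed") {
  if (headDiameter <= 0) stop("headDiameter must be positive")
  if (margin < 0) stop("margin must be nonnegative: head must fit in the grid")
  new("PhantomSpec", headDiameter = headDiameter, aspectRatio = aspectRatio,
      skullThickness = skullThickness, skinThickness = skinThickness,
      gapThickness = gapThickness, grayThickness = grayThickness,
      wholeBrainThickness = wholeBrainThickness, nSlices = as.integer(nSlices),
      pixelSize = pixelSize, sliceThickness = sliceThickness, margin = margin,
      seed = as.integer(seed), grayWhitePattern = grayWhitePattern)
}

# grid side length (pixels) for a spec
.gridSize <- function(spec) {
  half <- (spec@headDiameter / 2 + spec@margin) / spec@pixelSize
  2L * as.integer(ceiling(round(half, 6)))
}

# axial scale factor of slice k (1 at the widest slice, shrinking toward the
# vertex); the generated stack is the central window of a longer dome
.sliceScale <- function(spec, k) {
  n <- spec@nSlices
  pad <- if (n == 1L) 0L else max(1L, as.integer(floor(0.15 * n)))
  ntot <- n + 2L * pad
  if (ntot == 1L) return(1)
  u <- 0.9 * (2 * (k + pad - 1) / (ntot - 1) - 1)
  sqrt(pmax(1 - u^2, 0))
}

# seeded angular perturbation of the gray/white boundary
.lobePattern <- function(spec) {
  if (spec@grayWhitePattern == "concentric")
    return(function(theta) rep(0, length(theta)))
  coefs <- withSeed(spec@seed, {
    m <- 3:8
    list(m = m, c = runif(length(m), 0.005, 0.04),
         phi = runif(length(m), 0, 2 * pi))
  })
  function(theta) {
    d <- 0
    for (j in seq_along(coefs$m))
      d <- d + coefs$c[j] * cos(coefs$m[j] * theta + coefs$phi[j])
    d
  }
}

# one slice of labels (integer matrix n x n)
.phantomSlice <- function(spec, k, lobe = .lobePattern(spec)) {
  n <- .gridSize(spec)
  px <- spec@pixelSize
  xs <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  s <- .sliceScale(spec, k)
  a <- s * spec@headDiameter / 2
  b <- s * spec@aspectRatio * spec@headDiameter / 2
  lab <- matrix(.LBL[["air"]], n, n)

  inside <- function(ax, bx, dl = NULL) {
    if (ax <= px / 4 || bx <= px / 4) return(matrix(FALSE, n, n))
    r2 <- (X / ax)^2 + (Y / bx)^2
    if (is.null(dl)) r2 <= 1 else r2 <= (1 + dl)^2
  }

  skinIn <- c(a - spec@skinThickness, b - spec@skinThickness)
  skullIn <- skinIn - spec@skullThickness
  brainOut <- skullIn - spec@gapThickness
  grayIn <- brainOut - spec@grayThickness
  wbIn <- grayIn - spec@wholeBrainThickness

  lab[inside(a, b)] <- .LBL[["skin"]]
  lab[inside(skinIn[1], skinIn[2])] <- .LBL[["skull"]]
  lab[inside(skullIn[1], skullIn[2])] <- .LBL[["adipose"]]
  brain <- inside(brainOut[1], brainOut[2])
  lab[brain] <- .LBL[["gray"]]
  theta <- atan2(Y, X)
  dl <- matrix(lobe(as.numeric(theta)), n, n)
  # lobed boundaries are clipped to the brain envelope so substructures
  # never cross the adipose gap into the skull
  if (spec@wholeBrainThickness > 0)
    lab[inside(grayIn[1], grayIn[2], dl) & brain] <- .LBL[["whole_brain"]]
  lab[inside(wbIn[1], wbIn[2], dl) & brain] <- .LBL[["white"]]
  lab
}

#' Generate a voxelized head phantom
#'
#' Deterministic given the spec (including its seed): the same spec yields
#' bit-identical label arrays.
#'
#' @param spec a [PhantomSpec]
#' @param slices which axial slices to generate (default: all)
#' @return a [PhantomVolume]
#' @export
generateHeadPhantom <- function(spec, slices = seq_len(spec@nSlices)) {
  validObject(spec)
  if (any(slices < 1 | slices > spec@nSlices)) stop("slice index out of range")
  n <- .gridSize(spec)
  if (n < spec@headDiameter / spec@pixelSize)
    stop("head larger than the image grid")
  lobe <- .lobePattern(spec)
  labels <- array(0L, dim = c(n, n, length(slices)))
  for (j in seq_along(slices))
    labels[, , j] <- .phantomSlice(spec, slices[j], lobe)
  new("PhantomVolume", labels = labels,
      materialTable = .phantomMaterialTable(spec@wholeBrainThickness > 0),
      spec = spec)
}

#' A uniform cylinder phantom (single material in air)
#'
#' Convenience for simulator validation and calibration scans.
#'
#' @param materialName name of the embedded material filling the cylinder
#' @param diameter cylinder diameter in mm
#' @param pixelSize in-plane voxel size in mm
#' @param nPixels grid side length in pixels
#' @param nSlices number of identical slices
#' @return a [PhantomVolume] with labels 0 (air) and 1 (the material)
#' @export
cylinderPhantom <- function(materialName = "water", diameter = 200,
                            pixelSize = 1, nPixels = 256L, nSlices = 1L) {
  xs <- (seq_len(nPixels) - (nPixels + 1) / 2) * pixelSize
  X <- matrix(xs, nPixels, nPixels)
  Y <- matrix(xs, nPixels, nPixels, byrow = TRUE)
  disk <- (X^2 + Y^2) <= (diameter / 2)^2
  labels <- array(rep(as.integer(disk), nSlices),
                  dim = c(nPixels, nPixels, nSlices))
  spec <- phantomSpec(headDiameter = diameter, nSlices = nSlices,
                      pixelSize = pixelSize, margin = 0,
                      grayWhitePattern = "concentric")
  new("PhantomVolume", labels = labels,
      materialTable = list("0" = getMaterial("air"),
                           "1" = getMaterial(materialName)),
      spec = spec)
}

# map label matrix -> values via the material table
.lookupMap <- function(labels, materialTable, valueFun) {
  ids <- as.integer(names(materialTable))
  vals <- vapply(materialTable, valueFun, numeric(1))
  idx <- match(as.integer(labels), ids)
  matrix(vals[idx], nrow(labels), ncol(labels))
}

#' Ground-truth SPR map of a phantom slice
#'
#' Per-pixel Bethe-Bloch SPR of the voxel material; air pixels are set to 0
#' by convention (excluded from ROI metrics).
#'
#' @param volume a [PhantomVolume]
#' @param sliceIndex slice to convert
#' @param beam a [ProtonBeam]
#' @return an [SPRMap] with provenance "ground_truth"
#' @export
sprGroundTruthMap <- function(volume, sliceIndex = 1L, beam = protonBeam()) {
  lab <- volume@labels[, , sliceIndex]
  vals <- .lookupMap(lab, volume@materialTable, function(m) {
    if (m@name == "air") 0 else stoppingPowerRatio(m, beam)
  })
  new("SPRMap", values = vals, provenance = "ground_truth")
}

#' Basis-material coefficient maps of a phantom slice
#'
#' Per-voxel exact solve of the 2x2 system a1 muPE(E) + a2 muPVC(E) = mu(E)
#' at the two fit energies.
#'
#' @param volume a [PhantomVolume]
#' @param sliceIndex slice to convert
#' @param energies the two fit energies in keV (default 40 and 70)
#' @return a [BasisCoefficientMaps]
#' @export
basisCoefficientMaps <- function(volume, sliceIndex = 1L,
                                 energies = c(40, 70)) {
  stopifnot(length(energies) == 2)
  pe <- getMaterial("polyethylene"); pvc <- getMaterial("pvc")
  M <- rbind(c(linearAttenuation(pe, energies[1]), linearAttenuation(pvc, energies[1])),
             c(linearAttenuation(pe, energies[2]), linearAttenuation(pvc, energies[2])))
  if (abs(det(M)) < 1e-12)
    stop("singular basis matrix: the two energies do not separate PE and PVC")
  lab <- volume@labels[, , sliceIndex]
  mt <- volume@materialTable
  coefs <- vapply(mt, function(m)
    solve(M, linearAttenuation(m, energies)), numeric(2))
  ids <- as.integer(names(mt))
  idx <- match(as.integer(lab), ids)
  n <- nrow(lab)
  new("BasisCoefficientMaps",
      a1 = matrix(coefs[1, idx], n, ncol(lab)),
      a2 = matrix(coefs[2, idx], n, ncol(lab)),
      energies = energies, pixelSize = volume@spec@pixelSize)
}

#' Synthetic virtual monoenergetic image of a phantom slice
#'
#' Per-pixel HU from the theoretical linear attenuation of each voxel
#' material at the requested energy (no CT simulation).
#'
#' @param volume a [PhantomVolume]
#' @param sliceIndex slice to convert
#' @param energy photon energy in keV
#' @return numeric HU matrix
#' @export
syntheticVMI <- function(volume, sliceIndex = 1L, energy = 70) {
  cst <- physicsConstants()
  lab <- volume@labels[, , sliceIndex]
  .lookupMap(lab, volume@materialTable, function(m)
    huFromMu(linearAttenuation(m, energy), energy, cst))
}

#' Assemble the default multi-phantom dataset (lazy manifest)
#'
#' The default configuration mirrors the study: six head phantoms with
#' long-axis diameters 203, 208, 209, 215, 223 and 224 mm, 281 slices each,
#' for 1686 example slices in total. Examples are realized on demand with
#' [realizeExample()]; the manifest carries a seeded train/val/test split
#' (64/16/20).
#'
#' @param diameters long-axis diameters in mm, one per phantom
#' @param seeds per-phantom pattern seeds (same length as `diameters`)
#' @param spec template [PhantomSpec]; diameter and seed are overridden
#' @param splitSeed seed for the random split
#' @return a [PhantomDataset]
#' @export
makeDataset <- function(diameters = c(203, 208, 209, 215, 223, 224),
                        seeds = seq_along(diameters),
                        spec = phantomSpec(), splitSeed = 1L) {
  if (length(diameters) != length(seeds))
    stop("diameters and seeds must have the same length")
  specs <- lapply(seq_along(diameters), function(i) {
    s <- spec
    s@headDiameter <- diameters[i]
    s@seed <- as.integer(seeds[i])
    s
  })
  manifest <- do.call(rbind, lapply(seq_along(specs), function(i)
    data.frame(phantom_id = i, slice_index = seq_len(specs[[i]]@nSlices))))
  ne <- nrow(manifest)
  split <- withSeed(splitSeed, {
    sp <- rep("train", ne)
    idx <- sample.int(ne)
    nTest <- round(0.2 * ne)
    nVal <- round(0.2 * (ne - nTest))
    sp[idx[seq_len(nTest)]] <- "test"
    sp[idx[nTest + seq_len(nVal)]] <- "val"
    sp
  })
  manifest$split <- split
  new("PhantomDataset", manifest = manifest, specs = specs)
}

#' Realize one dataset example as VMI pair and ground-truth SPR map
#'
#' @param dataset a [PhantomDataset]
#' @param i example index into the manifest
#' @param energies VMI energies in keV (default 40 and 70)
#' @param imageSize optional target image side length in pixels; when given,
#'   the slice is generated directly at the coarser matching pixel size
#' @param beam a [ProtonBeam]
#' @return list with elements `vmi` (named list of HU matrices), `spr`
#'   (an [SPRMap]), and `labels`
#' @export
realizeExample <- function(dataset, i, energies = c(40, 70),
                           imageSize = NULL, beam = protonBeam()) {
  row <- dataset@manifest[i, ]
  spec <- dataset@specs[[row$phantom_id]]
  if (!is.null(imageSize)) {
    imageSize <- as.integer(imageSize)
    if (imageSize %% 2L != 0L) stop("imageSize must be even")
    spec@pixelSize <- (spec@headDiameter + 2 * spec@margin) / imageSize
  }
  vol <- generateHeadPhantom(spec, slices = row$slice_index)
  vmi <- lapply(energies, function(E) syntheticVMI(vol, 1L, E))
  names(vmi) <- paste0("keV", energies)
  list(vmi = vmi, spr = sprGroundTruthMap(vol, 1L, beam),
       labels = vol@labels[, , 1])
}
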