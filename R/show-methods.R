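# show() methods for the main containers

setMethod("show", "Material", function(object) {
  cat(sprintf("Material '%s': rho = %.4g g/cm^3\n", object@name, object@rho))
  fr <- sort(object@fractions, decreasing = TRUE)
  cat("  fractions:", paste(sprintf("%s=%.4f", names(fr), fr), collapse = " "), "\n")
})

setMethod("show", "PhantomVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("PhantomVolume: %d x %d x %d voxels (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3], object@spec@pixelSize, object@spec@pixelSize,
              object@spec@sliceThickness))
  tb <- table(object@labels)
  nm <- vapply(names(tb), function(id) object@materialTable[[id]]@name, "")
  cat("  voxels per material:\n")
  for (k in seq_along(tb))
    cat(sprintf("    %-22s %d\n", nm[k], as.integer(tb[k])))
})

setMethod("show", "BinnedSinogram", function(object) {
  d <- dim(object@counts)
  cat(sprintf("BinnedSinogram: %d views x %d detectors x %d bins (%s)\n",
              d[1], d[2], d[3],
              if (object@noise) "Poisson noise" else "noise-free"))
  cat("  bin edges (keV):", paste(object@detector@binEdges, collapse = ", "), "\n")
})

setMethod("show", "SPRMap", function(object) {
  v <- object@values[object@values > 0]
  cat(sprintf("SPRMap (%s): %d x %d pixels; body SPR range [%.3f, %.3f]\n",
              object@provenance, nrow(object@values), ncol(object@values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "HLUT", function(object) {
  cat(sprintf("HLUT: %d knots over [%g, %g] HU\n", length(object@knots),
              object@knots[1], object@knots[length(object@knots)]))
  print(data.frame(HU = object@knots, SPR = round(object@values, 4)),
        row.names = FALSE)
})

setMethod("show", "TrainedModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("U-Net model: %d parameters, input %dx%d, loss %s\n",
              np, object@config@inputSize, object@config@inputSize,
              object@config@loss))
  if (nrow(object@log))
    cat(sprintf("  trained %d epochs; final train loss %.4g\n",
                max(object@log$epoch), object@log$train_loss[nrow(object@log)]))
})

setMethod("show", "PhantomDataset", function(object) {
  cat(sprintf("PhantomDataset: %d phantoms, %d examples\n",
              length(object@specs), nrow(object@manifest)))
  print(table(object@manifest$split))
})

# ---- accessors ----

#' Label array of a phantom volume
#' @param volume a [PhantomVolume]
#' @return integer array of material IDs
#' @export
phantomLabels <- function(volume) volume@labels

#' Material lookup table of a phantom volume
#' @param volume a [PhantomVolume]
#' @return named list mapping label ID to [Material]
#' @export
materialTable <- function(volume) volume@materialTable

#' Pixel values of an SPR map
#' @param map an [SPRMap]
#' @return numeric matrix
#' @export
sprValues <- function(map) map@values

#' Photon counts of a binned sinogram
#' @param sino a [BinnedSinogram]
#' @return array [view, detector, bin]
#' @export
sinogramCounts <- function(sino) sino@counts

#' Number of examples in a phantom dataset
#' @param dataset a [PhantomDataset]
#' @return integer count of example slices
#' @export
nExamples <- function(dataset) nrow(dataset@manifest)

#' Manifest of a phantom dataset
#' @param dataset a [PhantomDataset]
#' @return data.frame with phantom_id, slice_index, split
#' @export
datasetManifest <- function(dataset) dataset@manifest
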