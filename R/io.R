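# Import/export helpers: NIfTI volumes, HLUT tables, calibration reports
# and training logs.

#' Write a 3D volume (or 2D map) as NIfTI with mm voxel sizes
#'
#' @param x numeric array/matrix, [PhantomVolume] or [SPRMap]
#' @param path output .nii/.nii.gz path
#' @param pixelSize in-plane voxel size in mm (taken from the object when
#'   available)
#' @param sliceThickness slice width in mm
#' @return the path, invisibly
#' @export
writeVolume <- function(x, path, pixelSize = NULL, sliceThickness = NULL) {
  if (is(x, "PhantomVolume")) {
    pixelSize <- x@spec@pixelSize
    sliceThickness <- x@spec@sliceThickness
    x <- x@labels
  } else if (is(x, "SPRMap")) {
    x <- x@values
  }
  if (is.null(pixelSize)) pixelSize <- 1
  if (is.null(sliceThickness)) sliceThickness <- 1
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(pixelSize, pixelSize, sliceThickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path .nii/.nii.gz path
#' @return numeric array with a "pixdim" attribute
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Export an HLUT as CSV (breakpoint HU, SPR)
#' @param hlut an [HLUT]
#' @param path output path
#' @return the path, invisibly
#' @export
exportHLUT <- function(hlut, path) {
  write.csv(data.frame(hu = hlut@knots, spr = hlut@values), path,
            row.names = FALSE)
  invisible(path)
}

#' Import an HLUT from CSV
#' @param path CSV with columns hu, spr
#' @return an [HLUT] (with an empty fit record)
#' @export
importHLUT <- function(path) {
  df <- read.csv(path)
  new("HLUT", knots = df$hu, values = df$spr, fit = list())
}

#' Write a stoichiometric calibration report as JSON
#' @param hlut an [HLUT] produced by [stoichiometricCalibrate()]
#' @param path output path
#' @return the path, invisibly
#' @export
exportCalibrationReport <- function(hlut, path) {
  f <- hlut@fit
  jsonlite::write_json(list(
    energy_keV = f$energy, parameters = f$k, exponents = f$exponents,
    insert_residuals = f$residuals,
    soft_line = f$soft, bone_line = f$bone,
    knots_hu = hlut@knots, knots_spr = hlut@values),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a training log as CSV (epoch, train_loss, val_loss)
#' @param model a [TrainedModel]
#' @param path output path
#' @return the path, invisibly
#' @export
exportTrainingLog <- function(model, path) {
  write.csv(model@log, path, row.names = FALSE)
  invisible(path)
}

#' Write a metric report as CSV
#' @param report data.frame from [roiMetrics()]
#' @param path output path
#' @return the path, invisibly
#' @export
exportMetricReport <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
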