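# ROI error metrics, HU-binned error histograms, and line profiles.

#' A set of regions of interest
#' @slot rois list of entries, each a list with `material` (name), `roi`
#'   (index 1-3) and `pixels` (two-column matrix of row/col indices)
#' @exportClass ROISet
setClass("ROISet", representation(rois = "list"))

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d ROIs\n", length(object@rois)))
  for (r in object@rois)
    cat(sprintf("  %-22s ROI %d: %d pixels\n", r$material, r$roi,
                nrow(r$pixels)))
})

# pixel counts per ROI, as in the evaluation protocol
.defaultRoiCounts <- list(
  brain_white_matter = c(20, 20, 24),
  brain_gray_matter = c(24, 24, 27),
  brain_whole = c(24, 27, 24),
  skull_cortical_bone = c(24, 24, 24))

# candidate ROI centers: pixels whose (2r+1)^2 neighborhood lies inside mask
.interiorPixels <- function(mask, r) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  cs <- apply(mask, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))      # cs[i, j] = sum mask[1:i, 1:j]
  padded <- matrix(0, n1 + 1, n2 + 1)
  padded[-1, -1] <- cs
  box <- function(i0, i1, j0, j1)
    padded[cbind(i1 + 1, j1 + 1)] - padded[cbind(i0, j1 + 1)] -
      padded[cbind(i1 + 1, j0)] + padded[cbind(i0, j0)]
  idx <- which(mask, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  ok <- i - r >= 1 & i + r <= n1 & j - r >= 1 & j + r <= n2
  idx <- idx[ok, , drop = FALSE]
  if (!nrow(idx)) return(idx)
  full <- box(idx[, 1] - r, idx[, 1] + r, idx[, 2] - r, idx[, 2] + r) ==
    (2 * r + 1)^2
  idx[full, , drop = FALSE]
}

#' Place ROIs inside homogeneous material regions of a label map
#'
#' For each requested material, candidate centers are pixels with a fully
#' interior neighborhood; three well-separated centers are chosen (seeded,
#' greedy max-min distance) and each ROI takes the requested number of
#' nearest material pixels around its center, without overlap.
#'
#' @param labels integer label matrix (one slice)
#' @param materialTable named list mapping label ID to [Material]
#' @param counts named list: material name -> vector of per-ROI pixel counts
#' @param seed seed for the center choice
#' @return an [ROISet]
#' @export
placeROIs <- function(labels, materialTable, counts = .defaultRoiCounts,
                      seed = 1L) {
  nameToId <- setNames(as.integer(names(materialTable)),
                       vapply(materialTable, function(m) m@name, ""))
  rois <- list()
  for (matName in names(counts)) {
    id <- nameToId[[matName]]
    if (is.null(id)) stop("material not present in label map: ", matName)
    mask <- labels == id
    if (!any(mask)) stop("material has no pixels in this slice: ", matName)
    cand <- NULL
    for (r in c(3, 2, 1, 0)) {
      cand <- .interiorPixels(mask, r)
      if (nrow(cand) >= 3) break
    }
    if (nrow(cand) < 3) cand <- which(mask, arr.ind = TRUE)
    centers <- withSeed(seed + id, {
      first <- cand[sample.int(nrow(cand), 1), , drop = FALSE]
      picked <- first
      for (k in 2:3) {
        d <- apply(cand, 1, function(p)
          min(colSums((t(picked) - p)^2)))
        picked <- rbind(picked, cand[which.max(d), ])
      }
      picked
    })
    allPix <- which(mask, arr.ind = TRUE)
    used <- rep(FALSE, nrow(allPix))
    for (k in seq_along(counts[[matName]])) {
      nPix <- counts[[matName]][k]
      d2 <- (allPix[, 1] - centers[k, 1])^2 + (allPix[, 2] - centers[k, 2])^2
      ord <- order(d2, seq_len(nrow(allPix)))
      ord <- ord[!used[ord]]
      if (length(ord) < nPix)
        stop("not enough free pixels of ", matName, " for ROI ", k)
      take <- ord[seq_len(nPix)]
      used[take] <- TRUE
      rois[[length(rois) + 1]] <- list(material = matName, roi = k,
                                       pixels = allPix[take, , drop = FALSE])
    }
  }
  new("ROISet", rois = rois)
}

#' ROI error metrics (RMSE, relative error, relative standard deviation)
#'
#' Per ROI with constant true SPR T and estimates e:
#' RMSE = sqrt(mean((T - e)^2)) * 100;
#' relative error = |T - mean(e)| / T * 100;
#' relative SD = sd(e) / T * 100 (sample SD, divisor N-1; NA when N < 2).
#' Per-material means over the three ROIs are appended as roi = "mean".
#'
#' @param truth ground-truth [SPRMap] (or matrix)
#' @param est estimated [SPRMap] (or matrix)
#' @param rois an [ROISet]
#' @return data.frame with columns material, roi, n, rmse_pct,
#'   rel_error_pct, rel_sd_pct
#' @export
roiMetrics <- function(truth, est, rois) {
  tv <- if (is(truth, "SPRMap")) truth@values else truth
  ev <- if (is(est, "SPRMap")) est@values else est
  if (!all(dim(tv) == dim(ev))) stop("truth and estimate maps must align")
  rows <- lapply(rois@rois, function(r) {
    t <- tv[r$pixels]; e <- ev[r$pixels]
    T0 <- mean(t)
    data.frame(material = r$material, roi = as.character(r$roi),
               n = length(e),
               rmse_pct = sqrt(mean((t - e)^2)) * 100,
               rel_error_pct = abs(T0 - mean(e)) / T0 * 100,
               rel_sd_pct = if (length(e) >= 2) sd(e) / T0 * 100 else NA_real_)
  })
  out <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(out, out$material), function(g)
    data.frame(material = g$material[1], roi = "mean", n = sum(g$n),
               rmse_pct = mean(g$rmse_pct),
               rel_error_pct = mean(g$rel_error_pct),
               rel_sd_pct = mean(g$rel_sd_pct))))
  rownames(means) <- NULL
  rbind(out, means)
}

#' HU-binned SPR error distributions
#'
#' Signed errors (estimated minus true, in SPR percent) of all body pixels
#' (true SPR > 0), grouped by the HU of a reference VMI: one bin below 0 HU,
#' ten bins of 10 HU between 0 and 100, and one bin above 100 HU by default.
#'
#' @param truth ground-truth [SPRMap] (or matrix)
#' @param est estimated [SPRMap] (or matrix)
#' @param vmi HU image used for the binning
#' @param breaks bin edges (default `c(-Inf, seq(0, 100, 10), Inf)`)
#' @return data.frame (bin_low, bin_high, count, mean_err, sd_err) with the
#'   per-bin signed errors attached as attribute "errors"
#' @export
huBinnedErrorHistogram <- function(truth, est, vmi,
                                   breaks = c(-Inf, seq(0, 100, 10), Inf)) {
  tv <- if (is(truth, "SPRMap")) truth@values else truth
  ev <- if (is(est, "SPRMap")) est@values else est
  body <- tv > 0
  err <- (ev[body] - tv[body]) * 100
  hu <- vmi[body]
  bin <- findInterval(hu, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1
  errs <- lapply(seq_len(nb), function(b) err[bin == b])
  out <- data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                    count = vapply(errs, length, 1L),
                    mean_err = vapply(errs, function(e)
                      if (length(e)) mean(e) else NA_real_, 1),
                    sd_err = vapply(errs, function(e)
                      if (length(e) > 1) sd(e) else NA_real_, 1))
  attr(out, "errors") <- errs
  out
}

#' Extract and compare a row profile from two aligned images
#'
#' @param imageA,imageB 2D maps of equal width
#' @param row row index
#' @return list with `a`, `b` (the two profiles) and `maxAbsDiff`
#' @export
lineProfile <- function(imageA, imageB, row) {
  if (ncol(imageA) != ncol(imageB)) stop("images must have equal widths")
  if (row < 1 || row > nrow(imageA) || row > nrow(imageB))
    stop("row out of range")
  a <- imageA[row, ]; b <- imageB[row, ]
  list(a = a, b = b, maxAbsDiff = max(abs(a - b)))
}
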