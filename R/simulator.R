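# Simplified photon-counting CT chain: polyenergetic parallel-beam forward
# projection of PE/PVC basis maps, energy-binned Poisson counts (quantum +
# electronic noise), projection-space maximum-likelihood material
# decomposition, ramp-filtered back-projection, and VMI synthesis.

#' CT scan geometry
#'
#' @param nViews number of view angles over 180 degrees (default 4000)
#' @param nDetectors number of detector channels (default 512)
#' @param fov reconstruction field of view in mm (default 350)
#' @param geometry "parallel" (the only implemented geometry)
#' @param reconPixels reconstructed image side length (default 512)
#' @param reconSliceThickness mm (default 0.4167)
#' @return a [ScanGeometry]
#' @export
scanGeometry <- function(nViews = 4000L, nDetectors = 512L, fov = 350,
                         geometry = "parallel", reconPixels = 512L,
                         reconSliceThickness = 0.4167) {
  new("ScanGeometry", nViews = as.integer(nViews),
      nDetectors = as.integer(nDetectors), fov = fov, geometry = geometry,
      reconPixels = as.integer(reconPixels),
      reconSliceThickness = reconSliceThickness)
}

#' X-ray source model
#'
#' The tube-current/rotation-time product is abstracted into `airCounts`, the
#' expected total number of registered photons per ray in an air scan.
#'
#' @param kv tube voltage in kV (default 120; must match the spectrum)
#' @param spectrum data.frame (energy_keV, relative_fluence); defaults to the
#'   embedded 120 kV spectrum
#' @param airCounts expected photons per ray in air (default 1e5; 0 gives
#'   an all-zero scan)
#' @return a [SourceModel]
#' @export
sourceModel <- function(kv = 120, spectrum = sourceSpectrum(),
                        airCounts = 1e5) {
  new("SourceModel", kv = kv, spectrum = spectrum, airCounts = airCounts)
}

#' Photon-counting detector model
#'
#' Default bin edges split 20-120 keV into `nBins` bins of equal expected
#' air counts under the source spectrum. Electronic noise is modeled as
#' Poisson-distributed spurious counts in the lowest bin; the default rate
#' (NA) resolves to 1 percent of the air counts in that bin at scan time.
#'
#' @param binEdges keV thresholds (length nBins + 1), or NULL for defaults
#' @param nBins number of bins when `binEdges` is NULL (default 8)
#' @param electronicNoise expected spurious counts per ray in the lowest bin;
#'   NA for the 1 percent default
#' @param source source model used to place equal-count default edges
#' @return a [DetectorModel]
#' @export
detectorModel <- function(binEdges = NULL, nBins = 8L, electronicNoise = NA,
                          source = sourceModel()) {
  if (is.null(binEdges)) {
    sp <- source@spectrum
    keep <- sp$energy_keV >= 20 & sp$energy_keV <= 120
    E <- sp$energy_keV[keep]; f <- sp$relative_fluence[keep]
    cf <- cumsum(f) / sum(f)
    inner <- vapply(seq_len(nBins - 1) / nBins, function(q)
      E[which.min(abs(cf - q))], numeric(1))
    binEdges <- c(20, inner, 120)
  }
  new("DetectorModel", binEdges = as.numeric(binEdges),
      electronicNoise = as.numeric(electronicNoise),
      idealEnergyResponse = TRUE)
}

# spectrum restricted to the detector bins: energies, expected photons per
# ray per energy (summing to airCounts), bin assignment, basis attenuations
.binSpectrum <- function(source, detector) {
  sp <- source@spectrum
  edges <- detector@binEdges
  keep <- sp$energy_keV >= edges[1] & sp$energy_keV <= edges[length(edges)] &
    sp$relative_fluence > 0
  E <- sp$energy_keV[keep]
  f <- sp$relative_fluence[keep]
  if (!length(E)) stop("empty spectrum within the detector bins")
  bin <- findInterval(E, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  if (any(tabulate(bin, nb) == 0))
    stop("at least one energy bin contains no spectrum support")
  S <- f / sum(f) * source@airCounts
  elec <- detector@electronicNoise
  if (is.na(elec)) elec <- 0.01 * sum(S[bin == 1])
  list(E = E, S = S, bin = bin, nBins = nb, elec = elec,
       muPE = linearAttenuation(getMaterial("polyethylene"), E),
       muPVC = linearAttenuation(getMaterial("pvc"), E))
}

# expected counts per ray and bin for line integrals (A1, A2) in cm
.expectedCounts <- function(A1, A2, bs) {
  nr <- length(A1)
  lam <- matrix(0, nr, bs$nBins)
  for (k in seq_along(bs$E)) {
    w <- bs$S[k] * exp(-A1 * bs$muPE[k] - A2 * bs$muPVC[k])
    lam[, bs$bin[k]] <- lam[, bs$bin[k]] + w
  }
  lam[, 1] <- lam[, 1] + bs$elec
  lam
}

#' Simulate an energy-binned photon-counting sinogram
#'
#' Parallel-beam line integrals of the basis coefficient maps are attenuated
#' through the polyenergetic spectrum; expected counts per energy bin follow
#' Beer-Lambert with the PE/PVC basis attenuations. With `noise = TRUE` the
#' counts are Poisson-sampled and Poisson electronic counts are added to the
#' lowest bin. Deterministic given `seed`.
#'
#' @param maps a [BasisCoefficientMaps] (e.g. from [basisCoefficientMaps()])
#' @param geometry a [ScanGeometry]
#' @param source a [SourceModel]
#' @param detector a [DetectorModel]
#' @param noise logical; apply Poisson noise
#' @param seed integer seed for the noise
#' @return a [BinnedSinogram]
#' @export
simulateSinogram <- function(maps, geometry = scanGeometry(),
                             source = sourceModel(),
                             detector = detectorModel(source = source),
                             noise = TRUE, seed = 1L) {
  stopifnot(is(maps, "BasisCoefficientMaps"))
  bs <- .binSpectrum(source, detector)
  if (is.na(detector@electronicNoise)) detector@electronicNoise <- bs$elec
  A1 <- .fpParallel(maps@a1, maps@pixelSize, geometry@nViews,
                    geometry@nDetectors, geometry@fov)
  A2 <- .fpParallel(maps@a2, maps@pixelSize, geometry@nViews,
                    geometry@nDetectors, geometry@fov)
  lam <- .expectedCounts(as.numeric(A1), as.numeric(A2), bs)
  if (noise) lam[] <- withSeed(seed, rpois(length(lam), lam))
  counts <- array(lam, dim = c(geometry@nViews, geometry@nDetectors, bs$nBins))
  new("BinnedSinogram", counts = counts, geometry = geometry, source = source,
      detector = detector, noise = noise)
}

#' Projection-space maximum-likelihood basis material decomposition
#'
#' Per ray, finds the PE/PVC line integrals (A1, A2) maximizing the Poisson
#' log-likelihood of the binned counts under the polyenergetic forward model
#' (including the electronic-noise mean in the lowest bin). Newton iterations
#' with step clamping, initialized from a log-ratio solve of the two
#' outermost bins at their effective energies. On noise-free input this
#' inverts the forward model to solver tolerance.
#'
#' @param sino a [BinnedSinogram]
#' @param source,detector forward-model components (default: as recorded in
#'   the sinogram)
#' @param tol convergence tolerance on the parameter step in cm
#' @param maxIter maximum Newton iterations
#' @return a [BasisSinogram]; rays that failed to converge are imputed from
#'   neighboring detectors and counted in the `nonConverged` slot
#' @export
mlDecompose <- function(sino, source = sino@source, detector = sino@detector,
                        tol = 1e-8, maxIter = 50L) {
  bs <- .binSpectrum(source, detector)
  nb <- bs$nBins
  if (nb < 2) stop("need at least two energy bins")
  cnt <- matrix(sino@counts, ncol = nb)
  nr <- nrow(cnt)

  # initialization: effective-energy solve of the two outermost bins
  effE <- vapply(c(1, nb), function(b) {
    i <- bs$bin == b
    sum(bs$E[i] * bs$S[i]) / sum(bs$S[i])
  }, numeric(1))
  M0 <- rbind(c(linearAttenuation(getMaterial("polyethylene"), effE[1]),
                linearAttenuation(getMaterial("pvc"), effE[1])),
              c(linearAttenuation(getMaterial("polyethylene"), effE[2]),
                linearAttenuation(getMaterial("pvc"), effE[2])))
  air <- .expectedCounts(0, 0, bs)
  y1 <- log(air[1, 1] / pmax(cnt[, 1], 0.5))
  y2 <- log(air[1, nb] / pmax(cnt[, nb], 0.5))
  Minv <- solve(M0)
  A1 <- Minv[1, 1] * y1 + Minv[1, 2] * y2
  A2 <- Minv[2, 1] * y1 + Minv[2, 2] * y2

  active <- rep(TRUE, nr)
  damp <- rep(1e-4, nr)   # per-ray Levenberg-Marquardt damping
  iter <- 0L
  nll <- function(a1, a2) {
    l <- .expectedCounts(a1, a2, bs)
    rowSums(l - cnt * log(l))
  }
  while (any(active) && iter < maxIter) {
    iter <- iter + 1L
    lam <- matrix(0, nr, nb)
    M1 <- matrix(0, nr, nb); M2 <- matrix(0, nr, nb)
    M11 <- matrix(0, nr, nb); M12 <- matrix(0, nr, nb); M22 <- matrix(0, nr, nb)
    for (k in seq_along(bs$E)) {
      p <- bs$muPE[k]; v <- bs$muPVC[k]; b <- bs$bin[k]
      w <- bs$S[k] * exp(-A1 * p - A2 * v)
      lam[, b] <- lam[, b] + w
      M1[, b] <- M1[, b] + p * w
      M2[, b] <- M2[, b] + v * w
      M11[, b] <- M11[, b] + p * p * w
      M12[, b] <- M12[, b] + p * v * w
      M22[, b] <- M22[, b] + v * v * w
    }
    lam[, 1] <- lam[, 1] + bs$elec
    r <- 1 - cnt / lam          # d NLL / d lambda
    q <- cnt / lam^2
    g1 <- -rowSums(r * M1)
    g2 <- -rowSums(r * M2)
    H11 <- rowSums(r * M11 + q * M1 * M1)
    H12 <- rowSums(r * M12 + q * M1 * M2)
    H22 <- rowSums(r * M22 + q * M2 * M2)
    # damped (Levenberg-Marquardt) step: increase the damping of rays whose
    # candidate does not decrease the negative log-likelihood; this stays
    # robust in the flat valleys of heavily attenuated rays
    f0 <- nll(A1, A2)
    scale <- (H11 + H22) / 2 + 1e-12
    s1 <- numeric(nr); s2 <- numeric(nr)
    accepted <- !active
    for (h in 1:12) {
      todo <- !accepted
      if (!any(todo)) break
      d11 <- H11 + damp * scale; d22 <- H22 + damp * scale
      dt <- d11 * d22 - H12^2
      dt[!is.finite(dt) | dt <= 1e-300] <- 1
      c1 <- -(d22 * g1 - H12 * g2) / dt
      c2 <- -(-H12 * g1 + d11 * g2) / dt
      t1 <- pmin(pmax(A1 + c1, -2), 80) - A1
      t2 <- pmin(pmax(A2 + c2, -2), 80) - A2
      fTry <- nll(A1 + t1, A2 + t2)
      ok <- todo & is.finite(fTry) & (fTry <= f0 + 1e-12)
      s1[ok] <- t1[ok]; s2[ok] <- t2[ok]
      accepted <- accepted | ok
      damp[todo & !ok] <- damp[todo & !ok] * 9
    }
    A1 <- A1 + s1
    A2 <- A2 + s2
    damp <- pmax(damp / 3, 1e-8)
    converged <- accepted & (pmax(abs(s1), abs(s2)) <= tol)
    active <- active & !converged
  }
  nBad <- sum(active)
  if (nBad > 0) {
    # impute non-converged rays from neighboring detectors in the same view
    dims <- dim(sino@counts)[1:2]
    A1m <- matrix(A1, dims[1], dims[2]); A2m <- matrix(A2, dims[1], dims[2])
    ok <- matrix(!active, dims[1], dims[2])
    idx <- which(!ok, arr.ind = TRUE)
    for (r0 in seq_len(nrow(idx))) {
      v0 <- idx[r0, 1]; d0 <- idx[r0, 2]
      nbr <- intersect(c(d0 - 1, d0 + 1, d0 - 2, d0 + 2), seq_len(dims[2]))
      nbr <- nbr[ok[v0, nbr]]
      if (length(nbr)) {
        A1m[v0, d0] <- mean(A1m[v0, nbr]); A2m[v0, d0] <- mean(A2m[v0, nbr])
      }
    }
    A1 <- A1m; A2 <- A2m
  }
  new("BasisSinogram",
      A1 = matrix(A1, dim(sino@counts)[1], dim(sino@counts)[2]),
      A2 = matrix(A2, dim(sino@counts)[1], dim(sino@counts)[2]),
      geometry = sino@geometry, nonConverged = as.integer(nBad))
}

# ramp (Ram-Lak) filtering of a [view x detector] sinogram, spacing dt (cm)
.rampFilter <- function(P, dt) {
  nDet <- ncol(P)
  m <- 2^ceiling(log2(2 * nDet))
  k <- seq_len(nDet - 1)
  h <- numeric(m)
  h[1] <- 1 / (4 * dt^2)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi * odd * dt)^2
  h[m + 1 - odd] <- -1 / (pi * odd * dt)^2
  H <- fft(h)
  X <- matrix(0, m, nrow(P))
  X[seq_len(nDet), ] <- t(P)
  Q <- Re(mvfft(mvfft(X) * H, inverse = TRUE)) / m
  t(Q[seq_len(nDet), , drop = FALSE]) * dt
}

#' Filtered back-projection of a basis sinogram
#'
#' Ramp-filtered parallel-beam FBP applied independently to the PE and PVC
#' channels; a linear operator by construction.
#'
#' @param basis a [BasisSinogram]
#' @param geometry a [ScanGeometry] (default: as recorded in the sinogram)
#' @return a [BasisCoefficientMaps] of reconstructed coefficients on the
#'   `reconPixels` grid
#' @export
fbpReconstruct <- function(basis, geometry = basis@geometry) {
  if (!all(dim(basis@A1) == c(geometry@nViews, geometry@nDetectors)))
    stop("sinogram dimensions do not match the scan geometry")
  dtcm <- geometry@fov / geometry@nDetectors / 10
  pxr <- geometry@fov / geometry@reconPixels
  rec <- lapply(list(basis@A1, basis@A2), function(P) {
    .bpParallel(.rampFilter(P, dtcm), geometry@reconPixels, pxr, geometry@fov)
  })
  new("BasisCoefficientMaps", a1 = rec[[1]], a2 = rec[[2]],
      energies = c(40, 70), pixelSize = pxr)
}

#' Synthesize a virtual monoenergetic image from basis coefficient maps
#'
#' Per pixel mu = a1 muPE(E) + a2 muPVC(E), converted to HU.
#'
#' @param recon a [BasisCoefficientMaps]
#' @param energy photon energy in keV
#' @return numeric HU matrix
#' @export
makeVMI <- function(recon, energy = 70) {
  muPE <- linearAttenuation(getMaterial("polyethylene"), energy)
  muPVC <- linearAttenuation(getMaterial("pvc"), energy)
  huFromMu(recon@a1 * muPE + recon@a2 * muPVC, energy)
}
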