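# Physics-based SPR estimators used as baselines: single-energy
# stoichiometric calibration with a piecewise-linear HU-to-SPR lookup table
# (HLUT), and the VMI-pair method that solves for effective atomic number
# and relative electron density from two virtual monoenergetic images.

# electron fractions lambda_i = w_i Z_i / A_i, normalized
.electronFractions <- function(mat) {
  el <- elementTable()
  i <- match(names(mat@fractions), el$symbol)
  lam <- mat@fractions * el$Z[i] / el$A[i]
  list(lambda = lam / sum(lam), Z = el$Z[i])
}

#' Effective atomic number of a material (Mayneord power law)
#'
#' Zeff = ( sum_i lambda_i Z_i^m )^(1/m) with lambda the electron fractions.
#'
#' @param mat a [Material]
#' @param exponent the Mayneord exponent m (default 3.21)
#' @return effective atomic number
#' @export
zeffMayneord <- function(mat, exponent = 3.21) {
  ef <- .electronFractions(mat)
  sum(ef$lambda * ef$Z^exponent)^(1 / exponent)
}

#' Construct a calibration insert
#'
#' @param mat insert [Material] (see [insertMaterials()])
#' @param category "lung", "soft" or "bone"; defaults to the material's
#'   category attribute
#' @param measuredHU named numeric vector of measured HU, names in keV
#' @return a [CalibrationInsert]
#' @export
calibrationInsert <- function(mat, category = attr(mat, "category"),
                              measuredHU) {
  new("CalibrationInsert", material = mat, category = category,
      measuredHU = measuredHU)
}

#' Theoretical (noise-free) HU of a material at given energies
#'
#' Shortcut for an ideal VMI measurement: HU from the material's linear
#' attenuation at each energy.
#'
#' @param mat a [Material]
#' @param energies keV vector
#' @return named numeric vector of HU
#' @export
theoreticalHU <- function(mat, energies) {
  cst <- physicsConstants()
  setNames(vapply(energies, function(E)
    huFromMu(linearAttenuation(mat, E), E, cst), numeric(1)),
    as.character(energies))
}

#' The default calibration insert set with ideal measured HU
#'
#' @param energies keV energies at which to record HU (default 40 and 70)
#' @return list of [CalibrationInsert]
#' @export
defaultInserts <- function(energies = c(40, 70)) {
  lapply(insertMaterials(), function(m)
    calibrationInsert(m, measuredHU = theoreticalHU(m, energies)))
}

#' Circular ROI mask covering a fraction of an insert's cross section
#'
#' @param nPixels image side length
#' @param pixelSize mm per pixel
#' @param center (x, y) center in mm relative to the image center
#' @param insertDiameter insert inner diameter in mm
#' @param areaFraction fraction of the insert area covered (default 0.70)
#' @return logical matrix mask
#' @export
circularROI <- function(nPixels, pixelSize, center = c(0, 0),
                        insertDiameter = 25, areaFraction = 0.70) {
  xs <- (seq_len(nPixels) - (nPixels + 1) / 2) * pixelSize
  X <- matrix(xs, nPixels, nPixels)
  Y <- matrix(xs, nPixels, nPixels, byrow = TRUE)
  r <- sqrt(areaFraction) * insertDiameter / 2
  (X - center[1])^2 + (Y - center[2])^2 <= r^2
}

#' Mean HU of an insert ROI over a stack of slices
#'
#' @param vmiStack a matrix, a list of matrices, or a 3D array of HU images
#' @param mask logical ROI mask
#' @return mean HU over (pixels x slices)
#' @export
measureInsertHU <- function(vmiStack, mask) {
  if (is.list(vmiStack)) vmiStack <- simplify2array(vmiStack)
  if (length(dim(vmiStack)) == 2) dim(vmiStack) <- c(dim(vmiStack), 1)
  if (!any(mask)) stop("empty ROI mask")
  mean(apply(vmiStack, 3, function(s) mean(s[mask])))
}

#' Stoichiometric calibration of a piecewise-linear HU-to-SPR table
#'
#' Fits the three-parameter stoichiometric model
#' mu/mu_w = rho_e (k1 t1 + k2 t2 + k3), with t1 = sum(lambda Z^3.62) and
#' t2 = sum(lambda Z^1.86) (photoelectric, coherent and Compton terms), to
#' the measured insert HU by linear least squares; predicts HU for the
#' embedded reference tissues; pairs them with Bethe-Bloch ground-truth SPR;
#' and assembles a continuous piecewise-linear head HLUT from per-category
#' regression lines (soft, bone) bridged at configurable connection points.
#'
#' @param inserts list of [CalibrationInsert] spanning soft and bone (and
#'   optionally lung) categories
#' @param energy evaluation energy in keV (default 70)
#' @param beam a [ProtonBeam]
#' @param exponents the (photoelectric, coherent) Z exponents
#' @param knots HU breakpoints of the assembled table
#' @return an [HLUT]; the `fit` slot records the stoichiometric parameters,
#'   per-insert residuals and the reference-tissue table
#' @export
stoichiometricCalibrate <- function(inserts, energy = 70,
                                    beam = protonBeam(),
                                    exponents = c(3.62, 1.86),
                                    knots = c(-1000, -120, 100, 300, 3000)) {
  if (length(inserts) < 3) stop("need at least 3 calibration inserts")
  cst <- physicsConstants()
  muw <- linearAttenuation(cst@water, energy)
  mua <- linearAttenuation(cst@air, energy)
  eKey <- as.character(energy)

  feat <- function(m) {
    ef <- .electronFractions(m)
    c(sum(ef$lambda * ef$Z^exponents[1]), sum(ef$lambda * ef$Z^exponents[2]))
  }
  X <- t(vapply(inserts, function(ins) {
    rhoE <- electronDensity(ins@material, cst)
    rhoE * c(feat(ins@material), 1)
  }, numeric(3)))
  hu <- vapply(inserts, function(ins) {
    if (!eKey %in% names(ins@measuredHU))
      stop("insert '", ins@material@name, "' has no measured HU at ",
           energy, " keV")
    ins@measuredHU[[eKey]]
  }, numeric(1))
  muRel <- hu * (muw - mua) / (1000 * muw) + 1
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("rank-deficient stoichiometric fit; design matrix:\n",
         paste(apply(round(X, 6), 1, paste, collapse = " "), collapse = "\n"))
  k <- qr.coef(qrX, muRel)
  resid <- as.numeric(X %*% k - muRel)

  # predict HU and pair with ground-truth SPR for the reference tissues
  tissues <- icruMaterials(c("soft", "bone", "lung"))
  tissues <- tissues[names(tissues) != "water"]
  tis <- do.call(rbind, lapply(names(tissues), function(nm) {
    m <- tissues[[nm]]
    rhoE <- electronDensity(m, cst)
    muRelHat <- rhoE * sum(k * c(feat(m), 1))
    data.frame(name = nm, category = materialNames()$category[
      match(nm, materialNames()$name)],
      hu = 1000 * muw * (muRelHat - 1) / (muw - mua),
      spr = stoppingPowerRatio(m, beam, cst))
  }))

  softFit <- lm(spr ~ hu, data = tis[tis$category == "soft", ])
  boneFit <- lm(spr ~ hu, data = tis[tis$category == "bone", ])
  lineAt <- function(fit, h) unname(coef(fit)[1] + coef(fit)[2] * h)
  values <- c(0, lineAt(softFit, knots[2]), lineAt(softFit, knots[3]),
              lineAt(boneFit, knots[4]), lineAt(boneFit, knots[5]))
  values <- pmax(values, 0)
  hl <- new("HLUT", knots = knots, values = values,
            fit = list(k = unname(k), residuals = resid, energy = energy,
                       exponents = exponents, tissues = tis,
                       soft = coef(softFit), bone = coef(boneFit)))
  slopes <- diff(values) / diff(knots)
  if (any(slopes < 0))
    warning("HLUT has a segment with negative slope; HU-to-SPR mapping is ",
            "not monotone")
  hl
}

#' Evaluate an HLUT on an HU image
#'
#' Piecewise-linear interpolation between the table knots; values outside
#' the domain are clamped to the end segments.
#'
#' @param hlut an [HLUT]
#' @param vmi70 HU image (matrix) or numeric vector
#' @return an [SPRMap] (provenance "predicted_hlut") for matrix input,
#'   numeric vector otherwise
#' @export
applyHLUT <- function(hlut, vmi70) {
  out <- approx(hlut@knots, hlut@values, xout = as.numeric(vmi70),
                rule = 2)$y
  if (is.matrix(vmi70))
    new("SPRMap", values = matrix(out, nrow(vmi70), ncol(vmi70)),
        provenance = "predicted_hlut")
  else out
}

#' Fit the effective-atomic-number model for the VMI-pair estimator
#'
#' At each energy the electronic cross section sigma_e(E, Z) of the elements
#' H through Ca is fitted as c0(E) + c1(E) Z^(m-1) with m the Mayneord
#' exponent. ln I is parameterized linearly in Zeff, separately for the
#' embedded soft and bone reference tissues, split at `zeffSplit`.
#'
#' @param energies keV grid on which the cross-section fit is available
#' @param mayneordExponent m (default 3.21)
#' @param zeffSplit soft/bone branch threshold (default 8.8)
#' @return a [ZeffModel]
#' @export
zeffModel <- function(energies = 40:140, mayneordExponent = 3.21,
                      zeffSplit = 8.8) {
  el <- elementTable()
  fitEl <- el[el$Z <= 20, ]
  avog <- 6.02214076e23
  zp <- fitEl$Z^(mayneordExponent - 1)
  c0 <- numeric(length(energies)); c1 <- numeric(length(energies))
  for (j in seq_along(energies)) {
    mr <- .muRhoElements(fitEl$symbol, energies[j])
    sigE <- as.numeric(mr) * fitEl$A / (avog * fitEl$Z)
    f <- lm.fit(cbind(1, zp), sigE)
    c0[j] <- f$coefficients[1]; c1[j] <- f$coefficients[2]
  }
  lnIfit <- function(category) {
    mats <- icruMaterials(category)
    z <- vapply(mats, zeffMayneord, numeric(1), exponent = mayneordExponent)
    y <- log(vapply(mats, meanIonization, numeric(1)))
    unname(coef(lm(y ~ z)))
  }
  grid <- seq(1, 30, by = 0.01)
  sig <- outer(grid^(mayneordExponent - 1), c1) +
    matrix(c0, length(grid), length(energies), byrow = TRUE)
  # reference tissues for pair-specific ln I calibration on the apparent
  # Zeff scale (the inversion's own scale, which absorbs fit residuals)
  tissues <- icruMaterials(c("soft", "bone"))
  tMu <- t(vapply(tissues, function(m)
    linearAttenuation(m, energies), numeric(length(energies))))
  cats <- materialNames()
  new("ZeffModel", mayneordExponent = mayneordExponent,
      energies = as.numeric(energies), c0 = c0, c1 = c1,
      softLnI = lnIfit("soft"), boneLnI = lnIfit("bone"),
      zeffSplit = zeffSplit, zeffGrid = grid, zGridSigma = sig,
      tissueMu = tMu,
      tissueLnI = log(vapply(tissues, meanIonization, numeric(1))),
      tissueCat = cats$category[match(names(tissues), cats$name)])
}

# pair-specific ln I calibration: invert the reference tissues' attenuation
# ratio on the apparent Zeff scale and refit lnI ~ Zeff per category
.pairLnIFit <- function(model, energies) {
  j1 <- match(energies[1], model@energies)
  j2 <- match(energies[2], model@energies)
  ratioGrid <- model@zGridSigma[, j1] / model@zGridSigma[, j2]
  rt <- model@tissueMu[, j1] / model@tissueMu[, j2]
  z <- approx(ratioGrid, model@zeffGrid,
              xout = pmin(pmax(rt, min(ratioGrid)), max(ratioGrid)),
              rule = 2, ties = "ordered")$y
  linefit <- function(x, y) {
    sxx <- sum((x - mean(x))^2)
    if (sxx < 1e-12) return(c(mean(y), 0))  # degenerate pair: flat fit
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    c(mean(y) - b * mean(x), b)
  }
  soft <- model@tissueCat == "soft"
  bone <- model@tissueCat == "bone"
  list(soft = linefit(z[soft], model@tissueLnI[soft]),
       bone = linefit(z[bone], model@tissueLnI[bone]),
       split = (max(z[soft]) + min(z[bone])) / 2)
}

# per-energy fitted electronic cross section on the Zeff grid
.sigmaAtEnergy <- function(model, energy) {
  j <- match(energy, model@energies)
  if (is.na(j)) stop("energy ", energy, " keV not in the ZeffModel grid")
  model@zGridSigma[, j]
}

#' SPR estimation from a pair of virtual monoenergetic images
#'
#' Per pixel: invert HU to linear attenuation at both energies; solve
#' mu(E) = rho_e,abs sigma_e(E, Zeff) for (rho_e, Zeff) using the fitted
#' two-term cross-section model; map Zeff to mean ionization energy through
#' the soft or bone ln I parameterization; and evaluate the Bethe-Bloch
#' ratio. Pixels whose attenuation ratio falls outside the fitted Zeff range
#' are clamped to the nearest grid value and counted in the "flagged"
#' attribute; non-physical (air-like) pixels get SPR 0.
#'
#' @param vmiLow,vmiHigh HU images at the lower/higher energy
#' @param energies the two energies in keV
#' @param model a [ZeffModel] (default covers 40-140 keV)
#' @param beam a [ProtonBeam]
#' @return an [SPRMap] with provenance "predicted_na"
#' @export
naEstimateSPR <- function(vmiLow, vmiHigh, energies = c(40, 70),
                          model = zeffModel(), beam = protonBeam()) {
  stopifnot(length(energies) == 2, energies[1] != energies[2])
  if (energies[1] > energies[2]) {
    tmp <- vmiLow; vmiLow <- vmiHigh; vmiHigh <- tmp
    energies <- rev(energies)
  }
  cst <- physicsConstants()
  mu1 <- muFromHu(as.numeric(vmiLow), energies[1], cst)
  mu2 <- muFromHu(as.numeric(vmiHigh), energies[2], cst)
  s1 <- .sigmaAtEnergy(model, energies[1])
  s2 <- .sigmaAtEnergy(model, energies[2])
  ratioGrid <- s1 / s2
  body <- mu1 > 0.005 & mu2 > 0.005   # exclude air-like pixels
  ratio <- mu1[body] / mu2[body]
  flagged <- sum(ratio < min(ratioGrid) | ratio > max(ratioGrid))
  ratio <- pmin(pmax(ratio, min(ratioGrid)), max(ratioGrid))
  zeff <- approx(ratioGrid, model@zeffGrid, xout = ratio, rule = 2,
                 ties = "ordered")$y
  sigma1 <- approx(model@zeffGrid, s1, xout = zeff)$y
  rhoE <- mu1[body] / (cst@rhoEWaterAbs * sigma1)
  # normalize the electron-density scale so that water is exact at this
  # pair (standard water calibration; absorbs cross-section fit residuals)
  muw1 <- linearAttenuation(cst@water, energies[1])
  muw2 <- linearAttenuation(cst@water, energies[2])
  zw <- approx(ratioGrid, model@zeffGrid,
               xout = min(max(muw1 / muw2, min(ratioGrid)), max(ratioGrid)),
               rule = 2, ties = "ordered")$y
  rhoEw <- muw1 / (cst@rhoEWaterAbs * approx(model@zeffGrid, s1, xout = zw)$y)
  rhoE <- rhoE / rhoEw
  lf <- .pairLnIFit(model, energies)
  lnI <- ifelse(zeff <= lf$split,
                lf$soft[1] + lf$soft[2] * zeff,
                lf$bone[1] + lf$bone[2] * zeff)
  spr <- numeric(length(mu1))
  spr[body] <- sprFromRhoEI(rhoE, exp(lnI), beam, cst)
  out <- matrix(spr, nrow(as.matrix(vmiLow)), ncol(as.matrix(vmiLow)))
  res <- new("SPRMap", values = out, provenance = "predicted_na")
  attr(res, "flagged") <- flagged
  res
}

#' Select the optimal VMI energy pair for the VMI-pair estimator
#'
#' Exhaustive search over unordered pairs of candidate energies; each pair
#' is scored by the RMSE of [naEstimateSPR()] on the category's inserts
#' against Bethe-Bloch ground truth. Ties break toward the lexicographically
#' smaller pair.
#'
#' @param inserts list of [CalibrationInsert]
#' @param category insert category to optimize over ("soft" or "bone")
#' @param candidates candidate energies in keV (default 40:140)
#' @param beam a [ProtonBeam]
#' @param model a [ZeffModel] covering the candidates
#' @return numeric pair (E1, E2) with an "rmse" attribute giving the full
#'   score table
#' @export
optimizeVMIPair <- function(inserts, category, candidates = 40:140,
                            beam = protonBeam(), model = zeffModel(candidates)) {
  sel <- Filter(function(i) i@category == category, inserts)
  if (!length(sel)) stop("no inserts in category '", category, "'")
  cst <- physicsConstants()
  truth <- vapply(sel, function(i)
    stoppingPowerRatio(i@material, beam, cst), numeric(1))
  # HU at every candidate energy (measured if present, else theoretical)
  huMat <- vapply(sel, function(ins) {
    vapply(candidates, function(E) {
      key <- as.character(E)
      if (key %in% names(ins@measuredHU)) ins@measuredHU[[key]]
      else theoreticalHU(ins@material, E)[[1]]
    }, numeric(1))
  }, numeric(length(candidates)))
  pairs <- t(utils::combn(sort(candidates), 2))
  rmse <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i1 <- match(pairs[r, 1], candidates); i2 <- match(pairs[r, 2], candidates)
    est <- naEstimateSPR(huMat[i1, , drop = FALSE], huMat[i2, , drop = FALSE],
                         energies = pairs[r, ], model = model, beam = beam)
    rmse[r] <- sqrt(mean((sprValues(est)[1, ] - truth)^2))
  }
  best <- which(rmse == min(rmse))[1]   # pairs are in lexicographic order
  out <- as.numeric(pairs[best, ])
  attr(out, "rmse") <- data.frame(E1 = pairs[, 1], E2 = pairs[, 2],
                                  rmse = rmse)
  out
}
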