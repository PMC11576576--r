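# Stoichiometric HLUT calibration and the VMI-pair estimator.

test_that("insert HU measurement averages pixels and slices", {
  img <- matrix(5, 16, 16)
  mask <- circularROI(16, 2, insertDiameter = 12)
  expect_equal(measureInsertHU(img, mask), 5)
  s1 <- matrix(2, 16, 16); s2 <- matrix(4, 16, 16)
  expect_equal(measureInsertHU(list(s1, s2), mask), 3)
  expect_error(measureInsertHU(img, mask & FALSE), "empty")
  # zero-mean noise: recovered mean within 3 standard errors
  set.seed(31)
  stack <- lapply(1:12, function(i) matrix(100 + rnorm(256, sd = 10), 16, 16))
  n <- sum(mask) * 12
  got <- measureInsertHU(stack, mask)
  expect_lt(abs(got - 100), 3 * 10 / sqrt(n))
})

test_that("stoichiometric fit recovers generating parameters exactly", {
  # inverse crime: insert HU generated from the three-parameter model
  cst <- physicsConstants()
  kTrue <- c(2.1e-4, 6.3e-3, 0.992)
  muw <- linearAttenuation(cst@water, 70)
  mua <- linearAttenuation(cst@air, 70)
  feat <- function(m) {
    ef <- pcctSPR:::.electronFractions(m)
    c(sum(ef$lambda * ef$Z^3.62), sum(ef$lambda * ef$Z^1.86))
  }
  inserts <- lapply(insertMaterials(), function(m) {
    muRel <- electronDensity(m, cst) * sum(kTrue * c(feat(m), 1))
    hu <- 1000 * muw * (muRel - 1) / (muw - mua)
    calibrationInsert(m, measuredHU = setNames(hu, "70"))
  })
  hl <- stoichiometricCalibrate(inserts, energy = 70)
  expect_equal(hl@fit$k, kTrue, tolerance = 1e-6)
  expect_lt(max(abs(hl@fit$residuals)), 1e-10)
})

test_that("rank-deficient insert sets are rejected with the design matrix", {
  w <- insertMaterials()$insert_solid_water
  ins <- replicate(4, calibrationInsert(w, measuredHU = c("70" = 10)),
                   simplify = FALSE)
  expect_error(stoichiometricCalibrate(ins, 70), "rank-deficient")
})

test_that("HLUT evaluation is continuous, clamped and knot-exact", {
  hl <- new("HLUT", knots = c(-1000, -100, 100, 400, 3000),
            values = c(0, 0.93, 1.08, 1.2, 2.2), fit = list())
  # exact at knots
  for (i in seq_along(hl@knots))
    expect_equal(applyHLUT(hl, hl@knots[i]), hl@values[i])
  # continuity at breakpoints
  for (k in hl@knots[-c(1, 5)]) {
    expect_lt(abs(applyHLUT(hl, k - 1e-7) - applyHLUT(hl, k + 1e-7)), 1e-6)
  }
  # clamped outside the domain
  expect_equal(applyHLUT(hl, -2000), 0)
  expect_equal(applyHLUT(hl, 5000), 2.2)
  # matrix input returns an SPRMap with uniform values at a knot HU
  m <- applyHLUT(hl, matrix(-100, 3, 3))
  expect_s4_class(m, "SPRMap")
  expect_true(all(sprValues(m) == 0.93))
})

test_that("the calibrated head HLUT converts soft tissue within 2%", {
  hl <- stoichiometricCalibrate(defaultInserts(70), energy = 70)
  expect_gte(applyHLUT(hl, -1000), 0)
  # monotone over the domain
  hu <- seq(-1000, 3000, by = 10)
  expect_true(all(diff(applyHLUT(hl, hu)) >= -1e-12))
  # brain-tissue conversion error on theoretical 70 keV HU
  for (nm in c("brain_white_matter", "brain_gray_matter", "brain_whole")) {
    m <- getMaterial(nm)
    got <- applyHLUT(hl, theoreticalHU(m, 70)[[1]])
    expect_lt(abs(got / stoppingPowerRatio(m) - 1), 0.02, )
  }
})

test_that("VMI-pair estimation is self-consistent for water", {
  zm <- zeffModel()
  est <- naEstimateSPR(matrix(0, 2, 2), matrix(0, 2, 2), c(40, 70), zm)
  expect_lt(max(abs(sprValues(est) - 1)), 0.005)
})

test_that("VMI-pair estimation is homogeneous in electron density", {
  zm <- zeffModel()
  cst <- physicsConstants()
  m <- getMaterial("brain_whole")
  mu1 <- linearAttenuation(m, 40); mu2 <- linearAttenuation(m, 70)
  toHU <- function(mu, E) huFromMu(mu, E, cst)
  base <- sprValues(naEstimateSPR(matrix(toHU(mu1, 40), 1, 1),
                                  matrix(toHU(mu2, 70), 1, 1), c(40, 70), zm))
  scaled <- sprValues(naEstimateSPR(matrix(toHU(1.2 * mu1, 40), 1, 1),
                                    matrix(toHU(1.2 * mu2, 70), 1, 1),
                                    c(40, 70), zm))
  expect_equal(as.numeric(scaled / base), 1.2, tolerance = 1e-6)
})

test_that("soft-tissue inserts are estimated within 1% at the optimal pair", {
  ins <- defaultInserts(c(40, 70))
  cand <- seq(40, 140, by = 10)
  zm <- zeffModel(cand)
  opt <- optimizeVMIPair(ins, "soft", cand, model = zm)
  soft <- Filter(function(i) i@category == "soft", ins)
  for (i in soft) {
    hu <- theoreticalHU(i@material, opt)
    est <- sprValues(naEstimateSPR(matrix(hu[1], 1, 1), matrix(hu[2], 1, 1),
                                   opt, zm))
    expect_lt(abs(est / stoppingPowerRatio(i@material) - 1), 0.01,
              )
  }
})

test_that("pair optimization equals the exhaustive brute-force oracle", {
  ins <- defaultInserts(c(40, 70))
  cand <- c(40, 60, 80, 100, 120, 140)
  zm <- zeffModel(cand)
  cst <- physicsConstants()
  for (cat in c("soft", "bone")) {
    opt <- optimizeVMIPair(ins, cat, cand, model = zm)
    # oracle: plain double loop over ordered pairs
    sel <- Filter(function(i) i@category == cat, ins)
    truth <- vapply(sel, function(i) stoppingPowerRatio(i@material),
                    numeric(1))
    best <- NULL; bestScore <- Inf
    for (a in seq_along(cand)) for (b in seq_along(cand)) {
      if (b <= a) next
      errs <- vapply(sel, function(i) {
        hu <- theoreticalHU(i@material, cand[c(a, b)])
        sprValues(naEstimateSPR(matrix(hu[1], 1, 1), matrix(hu[2], 1, 1),
                                cand[c(a, b)], zm))[1, 1]
      }, numeric(1)) - truth
      score <- sqrt(mean(errs^2))
      if (score < bestScore) { bestScore <- score; best <- cand[c(a, b)] }
    }
    expect_identical(as.numeric(opt), as.numeric(best))
  }
  # degenerate candidate set: the only pair wins
  zm2 <- zeffModel(c(50, 80))
  expect_identical(as.numeric(optimizeVMIPair(ins, "soft", c(50, 80),
                                              model = zm2)), c(50, 80))
  expect_error(optimizeVMIPair(list(), "soft", c(50, 80), model = zm2),
               "no inserts")
})

test_that("both baselines stay within 2% on noise-free head soft tissue", {
  spec <- phantomSpec(headDiameter = 215, nSlices = 3, pixelSize = 0.9,
                      seed = 4)
  vol <- generateHeadPhantom(spec, slices = 2)
  truth <- sprGroundTruthMap(vol, 1)
  rois <- placeROIs(phantomLabels(vol)[, , 1], materialTable(vol), seed = 1)
  v40 <- syntheticVMI(vol, 1, 40); v70 <- syntheticVMI(vol, 1, 70)
  hl <- stoichiometricCalibrate(defaultInserts(70), energy = 70)
  mh <- roiMetrics(truth, applyHLUT(hl, v70), rois)
  zm <- zeffModel()
  mn <- roiMetrics(truth, naEstimateSPR(v40, v70, c(40, 70), zm), rois)
  softMats <- c("brain_white_matter", "brain_gray_matter", "brain_whole")
  for (mm in list(mh, mn)) {
    soft <- mm[mm$roi == "mean" & mm$material %in% softMats, ]
    expect_true(all(soft$rmse_pct < 2))
  }
  # pixelwise maps add no noise: noise-free input gives near-zero ROI SD
  for (mm in list(mh, mn)) {
    soft <- mm[mm$roi == "mean" & mm$material %in% softMats, ]
    expect_true(all(soft$rel_sd_pct < 0.5))
  }
})
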