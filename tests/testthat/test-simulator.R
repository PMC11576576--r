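# Photon-counting CT chain: forward model, maximum-likelihood material
# decomposition, filtered back-projection and VMI synthesis.

smallGeometry <- function(nViews = 200L, nDetectors = 128L,
                          reconPixels = 64L)
  scanGeometry(nViews = nViews, nDetectors = nDetectors,
               reconPixels = reconPixels)

test_that("an air scan registers the unattenuated per-bin spectrum", {
  vol <- cylinderPhantom("water", diameter = 0.1, pixelSize = 2,
                         nPixels = 16L)
  maps <- basisCoefficientMaps(vol, 1)
  maps@a1[] <- 0; maps@a2[] <- 0
  geo <- smallGeometry(nViews = 4L, nDetectors = 8L)
  src <- sourceModel(airCounts = 5e4)
  det <- detectorModel(source = src)
  sino <- simulateSinogram(maps, geo, src, det, noise = FALSE)
  cnt <- sinogramCounts(sino)
  # all rays identical
  for (b in seq_len(dim(cnt)[3]))
    expect_equal(max(cnt[, , b]) - min(cnt[, , b]), 0)
  # per-bin totals equal the spectrum integral (oracle: direct CSV sum)
  tb <- .oracleTables()$sp
  edges <- det@binEdges
  keep <- tb$energy_keV >= edges[1] & tb$energy_keV <= edges[length(edges)] &
    tb$relative_fluence > 0
  E <- tb$energy_keV[keep]; f <- tb$relative_fluence[keep]
  S <- f / sum(f) * 5e4
  bin <- findInterval(E, edges, rightmost.closed = TRUE)
  want <- as.numeric(tapply(S, bin, sum))
  want[1] <- want[1] + 0.01 * want[1] # electronic mean: 1% of bin-1 counts
  expect_equal(as.numeric(cnt[1, 1, ]), want, tolerance = 1e-9)
})

test_that("a zero-intensity source yields an all-zero scan", {
  vol <- cylinderPhantom("water", diameter = 20, pixelSize = 2,
                         nPixels = 16L)
  maps <- basisCoefficientMaps(vol, 1)
  sino <- simulateSinogram(maps, smallGeometry(4L, 8L),
                           sourceModel(airCounts = 0), noise = FALSE)
  expect_identical(max(sinogramCounts(sino)), 0)
})

test_that("central-ray counts match a per-ray quadrature oracle", {
  vol <- cylinderPhantom("water", diameter = 100, pixelSize = 350 / 128,
                         nPixels = 128L)
  maps <- basisCoefficientMaps(vol, 1)
  geo <- scanGeometry(nViews = 2L, nDetectors = 129L, fov = 350,
                      reconPixels = 64L)
  src <- sourceModel(airCounts = 1e5)
  det <- detectorModel(source = src)
  sino <- simulateSinogram(maps, geo, src, det, noise = FALSE)
  # oracle: at view angle 0 the central ray (t = 0 for an odd detector
  # count) integrates along image columns; the even pixel grid straddles
  # x = 0, so average the two central column sums
  dCenter <- 65L  # t = 0
  A1 <- mean(rowSums(maps@a1[64:65, , drop = FALSE])) * (350 / 128) / 10
  A2 <- mean(rowSums(maps@a2[64:65, , drop = FALSE])) * (350 / 128) / 10
  tb <- .oracleTables()$sp
  edges <- det@binEdges
  keep <- tb$energy_keV >= edges[1] & tb$energy_keV <= edges[length(edges)] &
    tb$relative_fluence > 0
  E <- tb$energy_keV[keep]
  S <- tb$relative_fluence[keep] / sum(tb$relative_fluence[keep]) * 1e5
  bin <- findInterval(E, edges, rightmost.closed = TRUE)
  muPE <- vapply(E, function(e)
    oracleMu(oracleFractions("polyethylene"), oracleDensity("polyethylene"),
             e), 1)
  muPVC <- vapply(E, function(e)
    oracleMu(oracleFractions("pvc"), oracleDensity("pvc"), e), 1)
  lam <- S * exp(-A1 * muPE - A2 * muPVC)
  want <- as.numeric(tapply(lam, bin, sum))
  want[1] <- want[1] + 0.01 * sum(S[bin == 1])
  got <- as.numeric(sinogramCounts(sino)[1, dCenter, ])
  # sampling projector vs column-sum oracle: percent-level agreement
  expect_equal(got, want, tolerance = 0.02)
})

test_that("likelihood decomposition inverts the noise-free forward model", {
  src <- sourceModel(airCounts = 1e5)
  det <- detectorModel(source = src)
  bs <- pcctSPR:::.binSpectrum(src, det)
  grid <- expand.grid(A1 = seq(0, 40, length.out = 6),
                      A2 = seq(0, 4, length.out = 5))
  lam <- pcctSPR:::.expectedCounts(grid$A1, grid$A2, bs)
  geo <- scanGeometry(nViews = 6L, nDetectors = 5L, reconPixels = 16L)
  sino <- new("BinnedSinogram",
              counts = array(lam, c(6, 5, bs$nBins)), geometry = geo,
              source = src, detector = det, noise = FALSE)
  bas <- mlDecompose(sino)
  expect_identical(bas@nonConverged, 0L)
  expect_lt(max(abs(as.numeric(bas@A1) - grid$A1)), 1e-6)
  expect_lt(max(abs(as.numeric(bas@A2) - grid$A2)), 1e-6)
})

test_that("two bins and two unknowns reduce to the deterministic solve", {
  src <- sourceModel(airCounts = 1e5)
  det <- detectorModel(binEdges = c(30, 60, 100), electronicNoise = 0)
  bs <- pcctSPR:::.binSpectrum(src, det)
  A <- c(12, 1.5)
  lam <- pcctSPR:::.expectedCounts(A[1], A[2], bs)
  # oracle: independently coded 2D Newton on the two count equations
  f <- function(x) {
    l <- c(sum(bs$S[bs$bin == 1] * exp(-x[1] * bs$muPE[bs$bin == 1] -
                                        x[2] * bs$muPVC[bs$bin == 1])),
           sum(bs$S[bs$bin == 2] * exp(-x[1] * bs$muPE[bs$bin == 2] -
                                        x[2] * bs$muPVC[bs$bin == 2])))
    l - as.numeric(lam)
  }
  x <- c(5, 0.5)
  for (it in 1:100) {
    f0 <- f(x)
    J <- cbind((f(x + c(1e-7, 0)) - f0) / 1e-7,
               (f(x + c(0, 1e-7)) - f0) / 1e-7)
    x <- x - solve(J, f0)
    if (max(abs(f0)) < 1e-12) break
  }
  geo <- scanGeometry(nViews = 2L, nDetectors = 2L, reconPixels = 8L)
  sino <- new("BinnedSinogram", counts = array(rep(lam, each = 4), c(2, 2, 2)),
              geometry = geo, source = src, detector = det, noise = FALSE)
  bas <- mlDecompose(sino)
  expect_equal(as.numeric(bas@A1[1, 1]), x[1], tolerance = 1e-6)
  expect_equal(as.numeric(bas@A2[1, 1]), x[2], tolerance = 1e-6)
})

test_that("air rays decompose to zero line integrals", {
  vol <- cylinderPhantom("water", diameter = 0.1, pixelSize = 2,
                         nPixels = 16L)
  maps <- basisCoefficientMaps(vol, 1)
  maps@a1[] <- 0; maps@a2[] <- 0
  sino <- simulateSinogram(maps, smallGeometry(4L, 8L),
                           sourceModel(airCounts = 1e5), noise = FALSE)
  bas <- mlDecompose(sino)
  expect_lt(max(abs(bas@A1)), 1e-6)
  expect_lt(max(abs(bas@A2)), 1e-6)
})

test_that("filtered back-projection is linear and maps zero to zero", {
  geo <- smallGeometry(nViews = 30L, nDetectors = 32L, reconPixels = 24L)
  zero <- new("BasisSinogram", A1 = matrix(0, 30, 32), A2 = matrix(0, 30, 32),
              geometry = geo, nonConverged = 0L)
  expect_identical(max(abs(fbpReconstruct(zero)@a1)), 0)
  set.seed(42)
  Aa <- matrix(rnorm(30 * 32), 30, 32); Ab <- matrix(rnorm(30 * 32), 30, 32)
  mk <- function(A) new("BasisSinogram", A1 = A, A2 = A * 0.5,
                        geometry = geo, nonConverged = 0L)
  ra <- fbpReconstruct(mk(Aa)); rb <- fbpReconstruct(mk(Ab))
  rab <- fbpReconstruct(mk(Aa + Ab))
  expect_equal(rab@a1, ra@a1 + rb@a1, tolerance = 1e-12)
  expect_equal(rab@a2, ra@a2 + rb@a2, tolerance = 1e-12)
})

test_that("the noise-free chain recovers a water cylinder quantitatively", {
  vol <- cylinderPhantom("water", diameter = 200, pixelSize = 350 / 256,
                         nPixels = 256L)
  maps <- basisCoefficientMaps(vol, 1)
  geo <- scanGeometry(nViews = 360L, nDetectors = 256L, reconPixels = 128L)
  src <- sourceModel()
  sino <- simulateSinogram(maps, geo, src, noise = FALSE)
  rec <- fbpReconstruct(mlDecompose(sino))
  n <- geo@reconPixels
  xs <- (seq_len(n) - (n + 1) / 2) * (geo@fov / n)
  roi <- outer(xs, xs, function(a, b) a^2 + b^2) <= 50^2
  truthIdx <- which(phantomLabels(vol)[, , 1] == 1)[1]
  expect_lt(abs(mean(rec@a1[roi]) / maps@a1[truthIdx] - 1), 0.01)
  expect_lt(abs(mean(rec@a2[roi]) / maps@a2[truthIdx] - 1), 0.01)
  for (E in c(40, 70))
    expect_lt(abs(mean(makeVMI(rec, E)[roi])), 10)
  # monotone spectral contrast: PVC-rich pixels brighter at 40 than 70 keV
  pv <- cylinderPhantom("pvc", diameter = 40, pixelSize = 2, nPixels = 32L)
  pm <- basisCoefficientMaps(pv, 1)
  expect_gt(makeVMI(pm, 40)[16, 16], makeVMI(pm, 70)[16, 16])
  # vanishing basis coefficients mean vacuum (mu = 0), which sits about
  # 1 HU below air on the water/air scale
  expect_equal(makeVMI(new("BasisCoefficientMaps",
                           a1 = matrix(0, 2, 2), a2 = matrix(0, 2, 2),
                           energies = c(40, 70), pixelSize = 1), 70),
               matrix(-1000, 2, 2), tolerance = 2e-3)
})

test_that("Poisson noise scales as the inverse square root of intensity", {
  vol <- cylinderPhantom("water", diameter = 150, pixelSize = 350 / 128,
                         nPixels = 128L)
  maps <- basisCoefficientMaps(vol, 1)
  geo <- scanGeometry(nViews = 180L, nDetectors = 128L, reconPixels = 64L)
  sdRoi <- function(airCounts) {
    src <- sourceModel(airCounts = airCounts)
    sino <- simulateSinogram(maps, geo, src, noise = TRUE, seed = 99L)
    vmi <- makeVMI(fbpReconstruct(mlDecompose(sino)), 70)
    n <- geo@reconPixels
    xs <- (seq_len(n) - (n + 1) / 2) * (geo@fov / n)
    roi <- outer(xs, xs, function(a, b) a^2 + b^2) <= 40^2
    sd(vmi[roi])
  }
  ratio <- sdRoi(1e4) / sdRoi(1e6)
  expect_gt(ratio, 8); expect_lt(ratio, 12)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  vol <- cylinderPhantom("water", diameter = 30, pixelSize = 2, nPixels = 24L)
  maps <- basisCoefficientMaps(vol, 1)
  s1 <- simulateSinogram(maps, smallGeometry(8L, 16L), noise = TRUE,
                         seed = 123L)
  s2 <- simulateSinogram(maps, smallGeometry(8L, 16L), noise = TRUE,
                         seed = 123L)
  expect_identical(sinogramCounts(s1), sinogramCounts(s2))
  s3 <- simulateSinogram(maps, smallGeometry(8L, 16L), noise = TRUE,
                         seed = 124L)
  expect_false(identical(sinogramCounts(s1), sinogramCounts(s3)))
})
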