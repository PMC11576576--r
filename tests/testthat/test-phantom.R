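# Procedural head phantom: geometry contracts, determinism, ground-truth
# maps and basis-coefficient decomposition.

test_that("phantom generation is deterministic and uses the expected labels", {
  spec <- phantomSpec(headDiameter = 180, nSlices = 4, pixelSize = 1.5,
                      seed = 9)
  v1 <- generateHeadPhantom(spec)
  v2 <- generateHeadPhantom(spec)
  expect_identical(phantomLabels(v1), phantomLabels(v2))
  expect_true(all(unique(as.integer(phantomLabels(v1))) %in% 0:6))
  # all ring materials present in a central slice
  mid <- phantomLabels(v1)[, , 2]
  expect_setequal(sort(unique(as.integer(mid))), 0:6)
})

test_that("in-plane extent matches the requested head diameter", {
  for (d in c(203, 224)) {
    spec <- phantomSpec(headDiameter = d, nSlices = 1, pixelSize = 0.5,
                        seed = 1)
    lab <- phantomLabels(generateHeadPhantom(spec))[, , 1]
    body <- which(rowSums(lab > 0) > 0)
    extent <- (max(body) - min(body) + 1) * spec@pixelSize
    expect_lt(abs(extent - d), spec@pixelSize + 1e-9)
  }
})

test_that("slice cross sections shrink smoothly toward the vertex", {
  spec <- phantomSpec(headDiameter = 160, nSlices = 21, pixelSize = 2,
                      seed = 2)
  vol <- generateHeadPhantom(spec)
  areas <- apply(phantomLabels(vol) > 0, 3, sum)
  expect_lt(areas[1], areas[11])
  expect_lt(areas[21], areas[11])
  expect_true(all(abs(diff(areas)) < 0.15 * max(areas)))
})

test_that("oversized heads are rejected", {
  spec <- phantomSpec(headDiameter = 100, nSlices = 1, pixelSize = 1)
  spec@margin <- -10  # bypass constructor guard to hit the geometry check
  expect_error(phantomSpec(headDiameter = 100, margin = -10), "fit")
})

test_that("ground-truth SPR maps are exact per-material lookups", {
  # uniform water cylinder: SPR 1 inside, 0 in air
  vol <- cylinderPhantom("water", diameter = 40, pixelSize = 2, nPixels = 32L)
  m <- sprValues(sprGroundTruthMap(vol, 1))
  inside <- phantomLabels(vol)[, , 1] == 1
  expect_true(all(m[inside] == 1))
  expect_true(all(m[!inside] == 0))
  # piecewise map for a density-scaled water: SPR = rho_e exactly
  w <- getMaterial("water")
  w11 <- material("water11", 1.1, w@fractions)
  spec <- vol@spec
  vol2 <- new("PhantomVolume", labels = vol@labels,
              materialTable = list("0" = getMaterial("air"), "1" = w11),
              spec = spec)
  m2 <- sprValues(sprGroundTruthMap(vol2, 1))
  expect_equal(unique(m2[inside]), 1.1, tolerance = 1e-12)
  # head slice: every pixel equals its material's scalar oracle, bitwise
  hs <- phantomSpec(headDiameter = 120, nSlices = 1, pixelSize = 1, seed = 5)
  hv <- generateHeadPhantom(hs)
  truth <- sprValues(sprGroundTruthMap(hv, 1))
  lab <- phantomLabels(hv)[, , 1]
  for (id in setdiff(unique(as.integer(lab)), 0L)) {
    nm <- materialTable(hv)[[as.character(id)]]@name
    want <- stoppingPowerRatio(getMaterial(nm))
    expect_identical(unique(truth[lab == id]), want)
  }
})

test_that("basis decomposition solves the two-energy system exactly", {
  pe <- cylinderPhantom("polyethylene", diameter = 20, pixelSize = 2,
                        nPixels = 16L)
  mp <- basisCoefficientMaps(pe, 1)
  inside <- phantomLabels(pe)[, , 1] == 1
  expect_equal(unique(mp@a1[inside]), 1, tolerance = 1e-12)
  expect_equal(unique(mp@a2[inside]), 0, tolerance = 1e-10)
  pv <- cylinderPhantom("pvc", diameter = 20, pixelSize = 2, nPixels = 16L)
  mv <- basisCoefficientMaps(pv, 1)
  expect_equal(unique(mv@a1[inside]), 0, tolerance = 1e-10)
  expect_equal(unique(mv@a2[inside]), 1, tolerance = 1e-12)
  # water: against an independently coded 2x2 solve on the same tables
  wv <- cylinderPhantom("water", diameter = 20, pixelSize = 2, nPixels = 16L)
  mw <- basisCoefficientMaps(wv, 1)
  fr <- list(pe = oracleFractions("polyethylene"),
             pvc = oracleFractions("pvc"), w = oracleFractions("water"))
  M <- matrix(c(oracleMu(fr$pe, oracleDensity("polyethylene"), 40),
                oracleMu(fr$pe, oracleDensity("polyethylene"), 70),
                oracleMu(fr$pvc, oracleDensity("pvc"), 40),
                oracleMu(fr$pvc, oracleDensity("pvc"), 70)), 2, 2)
  y <- c(oracleMu(fr$w, 1, 40), oracleMu(fr$w, 1, 70))
  det0 <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  a1w <- (y[1] * M[2, 2] - M[1, 2] * y[2]) / det0
  a2w <- (M[1, 1] * y[2] - y[1] * M[2, 1]) / det0
  expect_equal(unique(mw@a1[inside]), a1w, tolerance = 1e-10)
  expect_equal(unique(mw@a2[inside]), a2w, tolerance = 1e-10)
})

test_that("basis recombination reproduces attenuation at the fit energies", {
  hs <- phantomSpec(headDiameter = 100, nSlices = 1, pixelSize = 2, seed = 3)
  hv <- generateHeadPhantom(hs)
  mp <- basisCoefficientMaps(hv, 1, energies = c(40, 70))
  pe <- getMaterial("polyethylene"); pvc <- getMaterial("pvc")
  lab <- phantomLabels(hv)[, , 1]
  for (E in c(40, 70)) {
    muMap <- mp@a1 * linearAttenuation(pe, E) +
      mp@a2 * linearAttenuation(pvc, E)
    direct <- matrix(0, nrow(lab), ncol(lab))
    for (id in unique(as.integer(lab))) {
      nm <- materialTable(hv)[[as.character(id)]]
      direct[lab == id] <- linearAttenuation(nm, E)
    }
    expect_lt(max(abs(muMap - direct)), 1e-10)
  }
  # at other energies the two-basis approximation has a small soft-tissue
  # residual (reported, not zero)
  soft <- lab %in% 4:6
  for (E in c(50, 100, 140)) {
    muMap <- mp@a1 * linearAttenuation(pe, E) +
      mp@a2 * linearAttenuation(pvc, E)
    direct <- matrix(0, nrow(lab), ncol(lab))
    for (id in unique(as.integer(lab))) {
      nm <- materialTable(hv)[[as.character(id)]]
      direct[lab == id] <- linearAttenuation(nm, E)
    }
    rel <- abs(muMap - direct)[soft] / direct[soft]
    expect_lt(max(rel), 0.02)
  }
})

test_that("synthetic VMIs encode the expected Hounsfield contrasts", {
  wv <- cylinderPhantom("water", diameter = 30, pixelSize = 2, nPixels = 16L)
  v <- syntheticVMI(wv, 1, 70)
  inside <- phantomLabels(wv)[, , 1] == 1
  expect_equal(unique(v[inside]), 0, tolerance = 1e-9)
  expect_equal(unique(v[!inside]), -1000, tolerance = 1e-9)
  hs <- phantomSpec(headDiameter = 120, nSlices = 1, pixelSize = 1, seed = 5)
  hv <- generateHeadPhantom(hs)
  lab <- phantomLabels(hv)[, , 1]
  v70 <- syntheticVMI(hv, 1, 70)
  expect_gt(min(v70[lab == 2]), max(v70[lab %in% 4:6]))
})

test_that("dataset manifests have the configured cardinality and splits", {
  ds <- makeDataset(diameters = 150, seeds = 1,
                    spec = phantomSpec(nSlices = 10, pixelSize = 2))
  expect_identical(nExamples(ds), 10L)
  ds2 <- makeDataset(diameters = c(150, 160), seeds = 1:2,
                     spec = phantomSpec(nSlices = 25, pixelSize = 2))
  mf <- datasetManifest(ds2)
  expect_identical(nrow(mf), 50L)
  expect_setequal(unique(mf$split), c("train", "val", "test"))
  expect_equal(sum(mf$split == "test") / nrow(mf), 0.2, tolerance = 0.05)
  # reproducibility: same configuration twice gives identical examples
  e1 <- realizeExample(ds2, 7, imageSize = 32)
  e2 <- realizeExample(makeDataset(diameters = c(150, 160), seeds = 1:2,
                                   spec = phantomSpec(nSlices = 25,
                                                      pixelSize = 2)),
                       7, imageSize = 32)
  expect_identical(e1$vmi, e2$vmi)
  expect_identical(sprValues(e1$spr), sprValues(e2$spr))
})
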