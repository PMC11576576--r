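# Independent brute-force oracles. These read the shipped CSV tables
# directly and evaluate the defining formulas with plain scalar loops,
# deliberately sharing no code with the package implementation.

.oracleTables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- function(f) system.file("extdata", f, package = "pcctSPR")
    cache <<- list(
      el = read.csv(path("elements.csv")),
      at = read.csv(path("mass_attenuation.csv")),
      ma = read.csv(path("materials.csv")),
      sp = read.csv(path("spectrum_120kv.csv")))
    cache
  }
})

# mass fractions of a named embedded material, as a named vector
oracleFractions <- function(name) {
  tb <- .oracleTables()
  row <- tb$ma[tb$ma$name == name, ]
  w <- unlist(row[tb$el$symbol])
  w <- w[w > 0]
  w / sum(w)
}

oracleDensity <- function(name) {
  tb <- .oracleTables()
  tb$ma$density_g_cm3[tb$ma$name == name]
}

# absolute electron density, electrons/cm^3, by scalar loop
oracleElectronDensityAbs <- function(fractions, rho) {
  tb <- .oracleTables()
  s <- 0
  for (sym in names(fractions)) {
    i <- which(tb$el$symbol == sym)
    s <- s + fractions[[sym]] * tb$el$Z[i] / tb$el$A[i]
  }
  rho * 6.02214076e23 * s
}

oracleElectronDensity <- function(fractions, rho) {
  wf <- oracleFractions("water")
  oracleElectronDensityAbs(fractions, rho) / oracleElectronDensityAbs(wf, 1.0)
}

# electron-weighted log-average mean ionization energy, eV
oracleMeanIonization <- function(fractions) {
  tb <- .oracleTables()
  num <- 0; den <- 0
  for (sym in names(fractions)) {
    i <- which(tb$el$symbol == sym)
    w <- fractions[[sym]] * tb$el$Z[i] / tb$el$A[i]
    num <- num + w * log(tb$el$I_eV[i])
    den <- den + w
  }
  exp(num / den)
}

# Bethe-Bloch ratio evaluated term by term
oracleSPR <- function(fractions, rho, beta = 0.461376419) {
  rhoE <- oracleElectronDensity(fractions, rho)
  I <- oracleMeanIonization(fractions)
  Iw <- oracleMeanIonization(oracleFractions("water"))
  mec2 <- 510.99895 * 1000 # eV
  num <- log(2 * mec2 * beta^2 / ((1 - beta^2) * I)) - beta^2
  den <- log(2 * mec2 * beta^2 / ((1 - beta^2) * Iw)) - beta^2
  rhoE * num / den
}

# mixture-rule linear attenuation with log-log interpolation, 1/cm
oracleMu <- function(fractions, rho, energy) {
  tb <- .oracleTables()
  total <- 0
  for (sym in names(fractions)) {
    sub <- tb$at[tb$at$symbol == sym, ]
    lx <- log(sub$energy_keV); ly <- log(sub$mu_over_rho_cm2_g)
    j <- max(which(sub$energy_keV <= energy))
    if (sub$energy_keV[j] == energy) mr <- sub$mu_over_rho_cm2_g[j]
    else {
      t <- (log(energy) - lx[j]) / (lx[j + 1] - lx[j])
      mr <- exp(ly[j] + t * (ly[j + 1] - ly[j]))
    }
    total <- total + fractions[[sym]] * mr
  }
  rho * total
}

# ROI metric formulas as plain loops
oracleMetrics <- function(truthVec, estVec) {
  N <- length(estVec)
  T0 <- sum(truthVec) / N
  sq <- 0
  for (i in seq_len(N)) sq <- sq + (truthVec[i] - estVec[i])^2
  rmse <- sqrt(sq / N) * 100
  m <- sum(estVec) / N
  relerr <- abs(T0 - m) / T0 * 100
  ss <- 0
  for (i in seq_len(N)) ss <- ss + (estVec[i] - m)^2
  relsd <- sqrt(ss / (N - 1)) / T0 * 100
  c(rmse = rmse, relerr = relerr, relsd = relsd)
}

# small synthetic training set of head slices rendered at a coarse grid
deskExamples <- function(n = 8, imageSize = 64) {
  ds <- makeDataset()
  tr <- which(datasetManifest(ds)$split == "train")
  idx <- tr[round(seq(1, length(tr), length.out = n))]
  lapply(idx, function(i) {
    ex <- realizeExample(ds, i, imageSize = imageSize)
    list(x1 = ex$vmi$keV40, x2 = ex$vmi$keV70, y = sprValues(ex$spr),
         labels = ex$labels)
  })
}

# a toy perceptual feature extractor (identity features) for loss plumbing
toyExtractor <- function(img) {
  list(features = img, backward = function(df) df)
}
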