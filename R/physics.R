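# Tissue physics: electron density, mean ionization energy, Bethe-Bloch
# stopping-power ratio, linear attenuation, and Hounsfield unit conversion.

#' Physics constants derived from the embedded water and air compositions
#'
#' The water electron density and mean ionization energy are computed from the
#' embedded water composition (H 0.111894, O 0.888106, rho = 1 g/cm^3) at call
#' time; they are never hard-coded.
#'
#' @return a [PhysicsConstants] object
#' @export
physicsConstants <- function() {
  if (!is.null(.pkgEnv$constants)) return(.pkgEnv$constants)
  water <- getMaterial("water")
  air <- getMaterial("air")
  el <- elementTable()
  i <- match(names(water@fractions), el$symbol)
  rhoE <- water@rho * 6.02214076e23 * sum(water@fractions * el$Z[i] / el$A[i])
  cst <- new("PhysicsConstants",
             avogadro = 6.02214076e23, meC2 = 510.99895,
             rhoEWaterAbs = rhoE, IWater = meanIonization(water),
             water = water, air = air)
  .pkgEnv$constants <- cst
  cst
}

#' Relative electron density of a material
#'
#' rho_e = rho * N_A * sum_i(w_i Z_i / A_i), normalized to water.
#'
#' @param mat a [Material]
#' @param constants a [PhysicsConstants] object
#' @return dimensionless electron density relative to water
#' @export
electronDensity <- function(mat, constants = physicsConstants()) {
  stopifnot(is(mat, "Material"))
  el <- elementTable()
  i <- match(names(mat@fractions), el$symbol)
  if (anyNA(i))
    stop("unknown element symbol(s): ",
         paste(names(mat@fractions)[is.na(i)], collapse = ", "))
  mat@rho * constants@avogadro * sum(mat@fractions * el$Z[i] / el$A[i]) /
    constants@rhoEWaterAbs
}

#' Mean ionization energy of a material
#'
#' Electron-weighted logarithmic average of the elemental mean excitation
#' energies: I = exp( sum(w Z/A ln I) / sum(w Z/A) ).
#'
#' @param mat a [Material]
#' @return mean ionization energy in eV
#' @export
meanIonization <- function(mat) {
  stopifnot(is(mat, "Material"))
  el <- elementTable()
  i <- match(names(mat@fractions), el$symbol)
  if (anyNA(i))
    stop("unknown element symbol(s): ",
         paste(names(mat@fractions)[is.na(i)], collapse = ", "))
  w <- mat@fractions * el$Z[i] / el$A[i]
  if (sum(w) <= 0) stop("degenerate material: all electron weights are zero")
  exp(sum(w * log(el$I_eV[i])) / sum(w))
}

#' Proton beam
#'
#' The default uses the study's literal speed ratio beta = 0.461376419
#' (nominally a 100 MeV proton); [betaFromKineticEnergy()] converts a kinetic
#' energy to beta separately.
#'
#' @param beta proton speed relative to light
#' @param kineticEnergy nominal kinetic energy in MeV (informational)
#' @return a [ProtonBeam]
#' @export
protonBeam <- function(beta = 0.461376419, kineticEnergy = 100) {
  new("ProtonBeam", beta = beta, kineticEnergy = kineticEnergy)
}

#' Proton speed ratio from kinetic energy (non-relativistic)
#'
#' beta = sqrt(2 T / m_p c^2).
#'
#' @param kineticEnergy kinetic energy in MeV
#' @param restEnergy proton rest energy in MeV
#' @return beta, strictly below 1
#' @export
betaFromKineticEnergy <- function(kineticEnergy, restEnergy = 938.272) {
  stopifnot(kineticEnergy > 0)
  beta <- sqrt(2 * kineticEnergy / restEnergy)
  if (beta >= 1)
    stop("non-relativistic beta >= 1; kinetic energy too high for this formula")
  beta
}

#' Bethe-Bloch stopping-power ratio relative to water
#'
#' SPR = rho_e * (ln(2 me c^2 beta^2 / ((1 - beta^2) I)) - beta^2) /
#'               (ln(2 me c^2 beta^2 / ((1 - beta^2) I_w)) - beta^2)
#' without shell or density-effect corrections.
#'
#' @param mat a [Material]
#' @param beam a [ProtonBeam]
#' @param constants a [PhysicsConstants]
#' @return dimensionless SPR; exactly 1 for water
#' @export
stoppingPowerRatio <- function(mat, beam = protonBeam(),
                               constants = physicsConstants()) {
  stopifnot(is(mat, "Material"), is(beam, "ProtonBeam"))
  if (mat@rho == 0) return(0)
  rhoE <- electronDensity(mat, constants)
  I <- meanIonization(mat)
  sprFromRhoEI(rhoE, I, beam, constants)
}

#' Stopping-power ratio from electron density and mean ionization energy
#'
#' Scalar core of the Bethe-Bloch ratio, shared by the ground-truth maps and
#' the VMI-pair estimator. Vectorized over `rhoE` and `I`.
#'
#' @param rhoE relative electron density
#' @param I mean ionization energy in eV
#' @param beam a [ProtonBeam]
#' @param constants a [PhysicsConstants]
#' @return SPR values
#' @export
sprFromRhoEI <- function(rhoE, I, beam = protonBeam(),
                         constants = physicsConstants()) {
  b2 <- beam@beta^2
  k <- 2 * constants@meC2 * 1000 * b2 / (1 - b2) # eV
  argM <- k / I
  argW <- k / constants@IWater
  if (any(argM <= 1) || argW <= 1)
    stop("nonphysical mean ionization energy for this beta: log argument <= 1")
  rhoE * (log(argM) - b2) / (log(argW) - b2)
}

#' Linear attenuation coefficient of a material
#'
#' mu(E) = rho * sum_i w_i (mu/rho)_i(E), with log-log interpolation of the
#' embedded elemental tables in energy. Vectorized over `energy`.
#'
#' @param mat a [Material]
#' @param energy photon energy in keV (within the tabulated 10-150 keV range)
#' @return mu in 1/cm
#' @export
linearAttenuation <- function(mat, energy) {
  stopifnot(is(mat, "Material"))
  if (mat@rho == 0) return(rep(0, length(energy)))
  mr <- .muRhoElements(names(mat@fractions), energy)
  mat@rho * as.numeric(mr %*% mat@fractions)
}

#' Hounsfield units from linear attenuation
#'
#' HU = 1000 (mu - mu_w) / (mu_w - mu_a) at the given energy.
#'
#' @param mu linear attenuation in 1/cm (vectorized)
#' @param energy photon energy in keV
#' @param constants a [PhysicsConstants]
#' @return HU values (not rounded)
#' @export
huFromMu <- function(mu, energy, constants = physicsConstants()) {
  muw <- linearAttenuation(constants@water, energy)
  mua <- linearAttenuation(constants@air, energy)
  1000 * (mu - muw) / (muw - mua)
}

#' Linear attenuation from Hounsfield units (inverse of [huFromMu()])
#' @param hu HU values (vectorized)
#' @param energy photon energy in keV
#' @param constants a [PhysicsConstants]
#' @return mu in 1/cm
#' @export
muFromHu <- function(hu, energy, constants = physicsConstants()) {
  muw <- linearAttenuation(constants@water, energy)
  mua <- linearAttenuation(constants@air, energy)
  muw + hu * (muw - mua) / 1000
}
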