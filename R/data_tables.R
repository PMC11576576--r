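# Embedded physics tables: elements, mass attenuation, tissue compositions,
# and the 120 kV source spectrum. All CSVs live in inst/extdata; the
# attenuation tables are parametric (Klein-Nishina incoherent term plus
# photoelectric/coherent power laws anchored to reference water values) --
# see the methods vignette for provenance.

.loadTables <- function() {
  if (!is.null(.pkgEnv$elements)) return(invisible())
  path <- function(f) system.file("extdata", f, package = "pcctSPR", mustWork = TRUE)
  el <- read.csv(path("elements.csv"), stringsAsFactors = FALSE)
  at <- read.csv(path("mass_attenuation.csv"), stringsAsFactors = FALSE)
  ma <- read.csv(path("materials.csv"), stringsAsFactors = FALSE)
  sp <- read.csv(path("spectrum_120kv.csv"), stringsAsFactors = FALSE)
  .pkgEnv$elements <- el
  # matrix of log(mu/rho) on the common energy grid, one column per element
  eg <- sort(unique(at$energy_keV))
  logmu <- sapply(el$symbol, function(s) {
    sub <- at[at$symbol == s, ]
    log(sub$mu_over_rho_cm2_g[order(sub$energy_keV)])
  })
  .pkgEnv$attenGrid <- eg
  .pkgEnv$attenLog <- logmu
  .pkgEnv$materials <- ma
  .pkgEnv$spectrum <- sp
  invisible()
}

#' Element table (Z, A, mean ionization energy)
#'
#' @return data.frame with columns symbol, Z, A, I_eV
#' @export
elementTable <- function() {
  .loadTables()
  .pkgEnv$elements
}

# log-log interpolated elemental mass attenuation, cm^2/g
# symbols: character vector; energy: numeric vector (keV)
# returns matrix [length(energy) x length(symbols)]
.muRhoElements <- function(symbols, energy) {
  .loadTables()
  unknown <- setdiff(symbols, colnames(.pkgEnv$attenLog))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  rng <- range(.pkgEnv$attenGrid)
  if (any(energy < rng[1] | energy > rng[2]))
    stop(sprintf("photon energy out of tabulated range [%g, %g] keV", rng[1], rng[2]))
  le <- log(energy)
  lg <- log(.pkgEnv$attenGrid)
  out <- vapply(symbols, function(s)
    exp(approx(lg, .pkgEnv$attenLog[, s], xout = le)$y),
    numeric(length(energy)))
  matrix(out, nrow = length(energy), dimnames = list(NULL, symbols))
}

#' Construct a Material
#'
#' Mass fractions are normalized to sum to one; elements must exist in the
#' embedded element table.
#'
#' @param name material name
#' @param rho mass density in g/cm^3
#' @param fractions named numeric vector of elemental mass fractions
#' @return a [Material] object
#' @export
material <- function(name, rho, fractions) {
  .loadTables()
  fractions <- fractions[fractions > 0]
  unknown <- setdiff(names(fractions), .pkgEnv$elements$symbol)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  s <- sum(fractions)
  if (s <= 0) stop("material '", name, "' has no positive mass fractions")
  new("Material", name = name, rho = rho, fractions = fractions / s)
}

#' Look up an embedded material by name
#'
#' @param name material name as listed in [materialNames()]
#' @return a [Material]
#' @export
getMaterial <- function(name) {
  .loadTables()
  ma <- .pkgEnv$materials
  i <- match(name, ma$name)
  if (is.na(i)) stop("unknown material: ", name)
  sym <- .pkgEnv$elements$symbol
  fr <- unlist(ma[i, sym])
  material(name, ma$density_g_cm3[i], fr[fr > 0])
}

#' Names and categories of all embedded materials
#' @return data.frame with columns name, category, density_g_cm3
#' @export
materialNames <- function() {
  .loadTables()
  .pkgEnv$materials[, c("name", "category", "density_g_cm3")]
}

#' The ICRU-style reference tissues used throughout the study
#'
#' Returns the head-relevant tissue set: white matter, gray matter, whole
#' brain, skull (cortical-bone-like), adipose, skin, water, the PE/PVC basis
#' materials, and the remaining embedded reference tissues.
#'
#' @param category optional filter: "soft", "bone", "lung", "plastic", "air"
#' @return named list of [Material] objects
#' @export
icruMaterials <- function(category = NULL) {
  .loadTables()
  ma <- .pkgEnv$materials
  keep <- !startsWith(ma$name, "insert_")
  if (!is.null(category)) keep <- keep & ma$category %in% category
  setNames(lapply(ma$name[keep], getMaterial), ma$name[keep])
}

#' The generic calibration-insert material set
#'
#' A self-contained stand-in for a commercial electron-density phantom:
#' lung-, adipose-, solid-water-, muscle-, liver-, inner-bone- and
#' cortical-bone-equivalent plastics with documented synthetic compositions.
#'
#' @return named list of [Material] objects; each carries a "category"
#'   attribute ("lung", "soft" or "bone")
#' @export
insertMaterials <- function() {
  .loadTables()
  ma <- .pkgEnv$materials
  keep <- startsWith(ma$name, "insert_")
  out <- lapply(which(keep), function(i) {
    m <- getMaterial(ma$name[i])
    attr(m, "category") <- ma$category[i]
    m
  })
  setNames(out, ma$name[keep])
}

#' The embedded 120 kV source spectrum
#' @return data.frame with columns energy_keV, relative_fluence
#' @export
sourceSpectrum <- function() {
  .loadTables()
  .pkgEnv$spectrum
}
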