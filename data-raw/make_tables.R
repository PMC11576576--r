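# Generate the embedded physics tables shipped in inst/extdata/.
#
# The per-element mass attenuation tables are SYNTHETIC/parametric: the
# incoherent term is the exact Klein-Nishina total cross section per electron,
# and photoelectric + coherent contributions are power laws in Z and E whose
# constants are fitted to reference water mass attenuation values (NIST grid,
# 10-150 keV). This keeps the whole virtual study self-consistent without
# redistributing third-party tables verbatim.
#
# Run from the repository root: Rscript data-raw/make_tables.R

## ---- elements: Z, A (g/mol), mean ionization energy I (eV, ICRU-37 style) ----
elements <- data.frame(
  symbol = c("H","C","N","O","Na","Mg","Al","Si","P","S","Cl","Ar","K","Ca","Ti","Fe"),
  Z = c(1, 6, 7, 8, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 22, 26),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 26.982, 28.085,
        30.974, 32.06, 35.45, 39.948, 39.098, 40.078, 47.867, 55.845),
  I_eV = c(19.2, 78, 82, 95, 149, 156, 166, 173, 173, 180, 174, 188, 190, 191, 233, 286)
)

## ---- Klein-Nishina total cross section per electron (cm^2) ----
r_e <- 2.8179403262e-13 # classical electron radius, cm
kn_sigma <- function(E_keV) {
  k <- E_keV / 510.99895
  t1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  t2 <- log(1 + 2 * k) / (2 * k)
  t3 <- (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * r_e^2 * (t1 + t2 - t3)
}

## ---- fit photoelectric/coherent constants to water reference values ----
# NIST mass attenuation (with coherent) for liquid water, cm^2/g.
ref <- data.frame(
  E = c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  mu_rho = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
             0.1837, 0.1707, 0.1505)
)
NA_const <- 6.02214076e23

# per-atom model: sigma(E, Z) = Z*KN(E) + Cpe*Z^4.62/E^p + Cco*Z^2.5/E^q  [cm^2]
mu_rho_model <- function(E, Cpe, p, Cco, q) {
  w <- c(H = 0.111894, O = 0.888106)
  out <- 0
  for (s in names(w)) {
    Zi <- elements$Z[elements$symbol == s]
    Ai <- elements$A[elements$symbol == s]
    sig <- Zi * kn_sigma(E) + Cpe * Zi^4.62 / E^p + Cco * Zi^2.5 / E^q
    out <- out + w[[s]] * NA_const / Ai * sig
  }
  out
}

fit <- nls(mu_rho ~ mu_rho_model(E, exp(lCpe), p, exp(lCco), q),
           data = ref,
           start = list(lCpe = log(1e-21), p = 3.2, lCco = log(1e-23), q = 1.9),
           control = nls.control(maxiter = 500, warnOnly = TRUE),
           weights = 1 / ref$mu_rho^2)
co <- coef(fit)
cat("fit coefficients:\n"); print(co)
cat("relative residuals (%):\n")
print(round(100 * (predict(fit) - ref$mu_rho) / ref$mu_rho, 3))

Cpe <- exp(co[["lCpe"]]); p <- co[["p"]]
Cco <- exp(co[["lCco"]]); q <- co[["q"]]

## ---- tabulate per-element mass attenuation, 10-150 keV at 1 keV ----
E_grid <- 10:150
atten <- do.call(rbind, lapply(seq_len(nrow(elements)), function(i) {
  Zi <- elements$Z[i]; Ai <- elements$A[i]
  sig <- Zi * kn_sigma(E_grid) + Cpe * Zi^4.62 / E_grid^p + Cco * Zi^2.5 / E_grid^q
  data.frame(symbol = elements$symbol[i], energy_keV = E_grid,
             mu_over_rho_cm2_g = signif(NA_const / Ai * sig, 8))
}))

## ---- tissue and insert compositions ----
# ICRU Report 46 style adult reference tissues (mass fractions in percent).
mat <- function(name, category, rho, ...) {
  w <- list(...)
  row <- data.frame(name = name, category = category, density_g_cm3 = rho)
  for (s in elements$symbol) row[[s]] <- if (is.null(w[[s]])) 0 else w[[s]]
  row
}
materials <- rbind(
  mat("water",              "soft", 1.000, H = 11.1894, O = 88.8106),
  mat("air",                "air",  0.0012, N = 75.5, O = 23.2, Ar = 1.3),
  mat("brain_white_matter", "soft", 1.04, H = 10.6, C = 19.4, N = 2.5, O = 66.1, Na = 0.2, P = 0.4, S = 0.2, Cl = 0.3, K = 0.3),
  mat("brain_gray_matter",  "soft", 1.04, H = 10.7, C = 9.5, N = 1.8, O = 76.7, Na = 0.2, P = 0.3, S = 0.2, Cl = 0.3, K = 0.3),
  mat("brain_whole",        "soft", 1.04, H = 10.7, C = 14.5, N = 2.2, O = 71.2, Na = 0.2, P = 0.4, S = 0.2, Cl = 0.3, K = 0.3),
  mat("skull_cortical_bone","bone", 1.92, H = 3.4, C = 15.5, N = 4.2, O = 43.5, Na = 0.1, Mg = 0.2, P = 10.3, S = 0.3, Ca = 22.5),
  mat("adipose",            "soft", 0.95, H = 11.4, C = 59.8, N = 0.7, O = 27.8, Na = 0.1, S = 0.1, Cl = 0.1),
  mat("skin",               "soft", 1.09, H = 10.0, C = 20.4, N = 4.2, O = 64.5, Na = 0.2, P = 0.1, S = 0.2, Cl = 0.3, K = 0.1),
  mat("muscle_skeletal",    "soft", 1.05, H = 10.2, C = 14.3, N = 3.4, O = 71.0, Na = 0.1, P = 0.2, S = 0.3, Cl = 0.1, K = 0.4),
  mat("liver",              "soft", 1.06, H = 10.2, C = 13.9, N = 3.0, O = 71.6, Na = 0.2, P = 0.3, S = 0.3, Cl = 0.2, K = 0.3),
  mat("blood_whole",        "soft", 1.06, H = 10.2, C = 11.0, N = 3.3, O = 74.5, Na = 0.1, P = 0.1, S = 0.2, Cl = 0.3, K = 0.2, Fe = 0.1),
  mat("kidney",             "soft", 1.05, H = 10.3, C = 13.2, N = 3.0, O = 72.4, Na = 0.2, P = 0.2, S = 0.2, Cl = 0.2, K = 0.2, Ca = 0.1),
  mat("spleen",             "soft", 1.06, H = 10.3, C = 11.3, N = 3.2, O = 74.1, Na = 0.1, P = 0.3, S = 0.2, Cl = 0.2, K = 0.3),
  mat("pancreas",           "soft", 1.04, H = 10.6, C = 16.9, N = 2.2, O = 69.4, Na = 0.2, P = 0.2, S = 0.1, Cl = 0.2, K = 0.2),
  mat("eye_lens",           "soft", 1.07, H = 9.6, C = 19.5, N = 5.7, O = 64.6, Na = 0.1, P = 0.1, S = 0.3, Cl = 0.1),
  mat("cartilage",          "soft", 1.10, H = 9.6, C = 9.9, N = 2.2, O = 74.4, Na = 0.5, P = 2.2, S = 0.9, Cl = 0.3),
  mat("lung_inflated",      "lung", 0.26, H = 10.3, C = 10.5, N = 3.1, O = 74.9, Na = 0.2, P = 0.2, S = 0.3, Cl = 0.3, K = 0.2),
  mat("spongiosa",          "bone", 1.18, H = 8.5, C = 40.4, N = 2.8, O = 36.7, Na = 0.1, Mg = 0.1, P = 3.4, S = 0.2, Cl = 0.2, K = 0.1, Ca = 7.4, Fe = 0.1),
  mat("bone_femur",         "bone", 1.33, H = 7.0, C = 34.5, N = 2.8, O = 36.8, Na = 0.1, Mg = 0.1, P = 5.5, S = 0.2, Cl = 0.1, K = 0.1, Ca = 12.8),
  mat("bone_cranium",       "bone", 1.61, H = 5.0, C = 21.2, N = 4.0, O = 43.5, Na = 0.1, Mg = 0.2, P = 8.1, S = 0.3, Ca = 17.6),
  # basis materials
  mat("polyethylene",       "plastic", 0.94, H = 14.3716, C = 85.6284),
  mat("pvc",                "plastic", 1.40, H = 4.8382, C = 38.4360, Cl = 56.7258),
  # Generic calibration insert set (synthetic compositions, Gammex-like roles):
  # epoxy-resin bases with CaCO3/Mg loading spanning lung/soft/bone categories.
  mat("insert_lung300",     "lung", 0.30, H = 8.5, C = 59.6, N = 2.0, O = 18.1, Mg = 11.2, Si = 0.6),
  mat("insert_adipose",     "soft", 0.94, H = 9.1, C = 72.3, N = 2.2, O = 16.3, Cl = 0.1),
  mat("insert_breast",      "soft", 0.99, H = 8.6, C = 70.1, N = 2.3, O = 17.9, Ca = 1.0, Cl = 0.1),
  mat("insert_solid_water", "soft", 1.015, H = 8.0, C = 67.2, N = 2.4, O = 19.9, Ca = 2.3, Cl = 0.2),
  mat("insert_muscle",      "soft", 1.05, H = 8.1, C = 67.1, N = 2.6, O = 19.9, Ca = 2.2, Cl = 0.1),
  mat("insert_liver",       "soft", 1.09, H = 8.1, C = 67.0, N = 2.5, O = 20.0, Ca = 2.3, Cl = 0.1),
  mat("insert_inner_bone",  "bone", 1.14, H = 6.7, C = 55.6, N = 2.0, O = 23.5, P = 3.2, Ca = 8.9, Cl = 0.1),
  mat("insert_b200",        "bone", 1.15, H = 6.6, C = 55.5, N = 2.0, O = 23.7, P = 3.2, Ca = 8.9, Cl = 0.1),
  mat("insert_cb2_30",      "bone", 1.33, H = 6.7, C = 53.5, N = 2.1, O = 25.6, Ca = 12.0, Cl = 0.1),
  mat("insert_cb2_50",      "bone", 1.56, H = 4.8, C = 41.6, N = 1.5, O = 32.0, Ca = 20.0, Cl = 0.1),
  mat("insert_cortical",    "bone", 1.82, H = 3.4, C = 31.4, N = 1.8, O = 36.5, Ca = 26.8, Cl = 0.1)
)
# normalize fractions to sum exactly 1 (stored as mass fractions, not percent)
fr <- as.matrix(materials[, elements$symbol])
fr <- fr / rowSums(fr)
materials[, elements$symbol] <- round(fr, 7)

## ---- 120 kV parametric bremsstrahlung spectrum, 6 mm Al filtration ----
al <- subset(atten, symbol == "Al")
mu_al <- approxfun(al$energy_keV, al$mu_over_rho_cm2_g * 2.699) # 1/cm
E_sp <- 10:120
kvp <- 120
S <- pmax(kvp - E_sp, 0) / E_sp * exp(-mu_al(E_sp) * 0.6)
S[E_sp < 15] <- 0                     # below detection threshold region
S <- S / sum(S)
spectrum <- data.frame(energy_keV = E_sp, relative_fluence = signif(S, 7))
cat(sprintf("spectrum mean energy: %.2f keV\n", sum(E_sp * S)))

## ---- write ----
hdr <- function(path, lines) writeLines(lines, path)
write.csv(elements, "inst/extdata/elements.csv", row.names = FALSE, quote = FALSE)
write.csv(atten, "inst/extdata/mass_attenuation.csv", row.names = FALSE, quote = FALSE)
write.csv(materials, "inst/extdata/materials.csv", row.names = FALSE, quote = FALSE)
write.csv(spectrum, "inst/extdata/spectrum_120kv.csv", row.names = FALSE, quote = FALSE)
cat("written.\n")
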