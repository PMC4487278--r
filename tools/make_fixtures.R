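# Generates the packaged fixture data under inst/extdata/:
#   * interaction-coefficient tables (dry air, water vapor, germanium) on a
#     0.5 keV grid, 5-60 keV, in unrenormalized and renormalized
#     photoelectric variants, log-log interpolated from standard XCOM-class
#     anchor values;
#   * the adopted correction-factor / uncertainty registry;
#   * the humid/dry W-ratio parameterization (plateau calibrated so that the
#     envelope-averaged humidity correction equals the adopted 0.9979);
#   * transport-correction basis functions per chamber, calibrated once so
#     the default synthetic spectrum reproduces the adopted values.
# Run from the package root:  Rscript tools/make_fixtures.R [--calibrate]

args <- commandArgs(trailingOnly = TRUE)
do_calibrate <- "--calibrate" %in% args

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

# --- 1. coefficient tables --------------------------------------------------

# Standard mass attenuation / mass energy-transfer anchors, cm^2/g
# (XCOM-class unrenormalized photoelectric cross sections).
anchors <- list(
  dry_air = data.frame(
    E = c(5, 6, 8, 10, 15, 20, 30, 40, 50, 60),
    mu = c(40.27, 23.41, 9.921, 5.120, 1.614, 0.7779, 0.3538, 0.2485,
           0.2080, 0.1875),
    mutr = c(39.31, 22.70, 9.446, 4.742, 1.334, 0.5389, 0.1537, 0.06833,
             0.04098, 0.03041),
    zoa = 0.49919),
  water_vapor = data.frame(
    E = c(5, 6, 8, 10, 15, 20, 30, 40, 50, 60),
    mu = c(42.58, 24.63, 10.37, 5.329, 1.673, 0.8096, 0.3756, 0.2683,
           0.2269, 0.2059),
    mutr = c(41.56, 23.88, 9.915, 4.944, 1.374, 0.5503, 0.1557, 0.06947,
             0.04223, 0.03190),
    zoa = 0.55509),
  germanium = data.frame(
    E = c(5, 6, 8, 10, 11.10, 11.11, 12, 15, 20, 30, 40, 50, 60),
    mu = c(222.0, 138.2, 63.4, 34.8, 26.0, 190.0, 151.0, 77.5, 33.0,
           10.0, 4.40, 2.40, 1.50),
    mutr = NA,  # filled below from a fluorescence-escape model
    zoa = 0.44053)
)

NA_AVOG <- 6.02214076e23
ER <- 510.999
RE2 <- 7.9407877e-26

kn_sigma <- function(E) {
  k <- E / ER
  2 * pi * RE2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) -
                                     log(1 + 2 * k) / k) +
                    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}
# mean fraction of the photon energy transferred to the recoil electron
kn_tr_frac <- function(E) {
  ct <- seq(-1, 1, length.out = 4001)
  k <- E / ER
  Es <- E / (1 + k * (1 - ct))
  w <- (Es / E)^2 * (Es / E + E / Es - (1 - ct^2))
  sum(w * (E - Es)) / (E * sum(w))
}

# Ge mass energy-transfer model: photoelectric minus mean K-fluorescence
# escape above the edge, plus the incoherent energy-transfer part.
ge <- anchors$germanium
sig_inc_ge <- kn_sigma(ge$E) * NA_AVOG * ge$zoa[1]
tau_ge <- pmax(ge$mu - sig_inc_ge, 0)
fl_loss <- ifelse(ge$E > 11.103, 0.88 * 0.535 * 9.93 / ge$E, 0.02)
anchors$germanium$mutr <- tau_ge * (1 - fl_loss) +
  sig_inc_ge * vapply(ge$E, kn_tr_frac, 0)

loglog <- function(x, y, xout) exp(approx(log(x), log(y), xout = log(xout))$y)

grid_e <- seq(5, 60, by = 0.5)
RENORM <- 0.97  # Hartree-Slater -> Hartree-Fock photoelectric scale, low Z

for (mat in names(anchors)) {
  a <- anchors[[mat]]
  e_out <- sort(unique(c(grid_e, a$E)))
  mu <- loglog(a$E, a$mu, e_out)
  mutr <- loglog(a$E, a$mutr, e_out)
  sig_inc <- kn_sigma(e_out) * NA_AVOG * a$zoa[1]
  sig_tr <- sig_inc * vapply(e_out, kn_tr_frac, 0)
  tau <- pmax(mu - sig_inc, 1e-6)
  tau_tr <- pmax(mutr - sig_tr, 1e-6)
  for (variant in c("unrenormalized", "renormalized")) {
    f <- if (variant == "renormalized") RENORM else 1
    d <- data.frame(energy_keV = e_out,
                    mu_rho = signif(f * tau + sig_inc, 6),
                    mu_tr_rho = signif(pmin(f * tau_tr + sig_tr,
                                            f * tau + sig_inc), 6))
    write.csv(d, sprintf("inst/extdata/coeff_%s_%s.csv", mat, variant),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(material = mat, variant = variant,
           provenance = paste("Generated by tools/make_fixtures.R from",
                              "standard XCOM-class anchor values;",
                              "log-log interpolated to a 0.5 keV grid.",
                              "Renormalized variant: photoelectric part",
                              "scaled by 0.97.")),
      sprintf("inst/extdata/coeff_%s_%s.csv.json", mat, variant),
      auto_unbox = TRUE, pretty = TRUE)
  }
}
cat("coefficient tables written\n")

# --- 2. adopted constants registry ------------------------------------------

registry <- list(
  version = "1.0",
  corrections = list(
    lamperti = list(
      values = list(k_ion = 1.0, k_humidity = 0.998, k_att = 1.0087,
                    k_el = 1.0008, k_sc = 0.9987, k_fl = 0.9979,
                    k_br_over_1mg = 1.0, k_ii = 1.0, k_dia = 1.0),
      uncertainties_pct = list(k_ion = 0.03, k_humidity = 0.03, k_att = 0.11,
                               k_el = 0.06, k_sc = 0.03, k_fl = 0.05,
                               k_br_over_1mg = 0.02, k_ii = 0.2,
                               k_dia = 0.10)),
    ritz = list(
      values = list(k_ion = 1.0, k_humidity = 0.998, k_att = 1.0283,
                    k_el = 1.0000, k_sc = 0.9970, k_fl = 0.9969,
                    k_br_over_1mg = 1.0, k_ii = 1.0, k_dia = 1.0),
      uncertainties_pct = list(k_ion = 0.03, k_humidity = 0.03, k_att = 0.36,
                               k_el = 0.08, k_sc = 0.03, k_fl = 0.05,
                               k_br_over_1mg = 0.02, k_ii = 0.2,
                               k_dia = 0.10))),
  alternatives = list(
    k_ii = list(value = 0.9980, u = 0.0004,
                note = paste("Computed compromise from mean-energy analyses;",
                             "the adopted policy value remains 1.0 with a",
                             "0.2 % standard uncertainty."))),
  budget = list(
    type_A = list(v_eff = 0.04, k_ion = 0.03, polarity = 0.02),
    type_B = list(
      lamperti = list(i_net = 0.06, w_over_e = 0.15, rho_0 = 0.03,
                      v_eff = 0.01, k_humidity = 0.03, k_att = 0.11,
                      k_el = 0.06, k_sc = 0.03, k_fl = 0.05,
                      k_br_over_1mg = 0.02, k_ii = 0.04, k_dia = 0.10,
                      k_field_distortion = 0.20),
      ritz = list(i_net = 0.06, w_over_e = 0.15, rho_0 = 0.03,
                  v_eff = 0.01, k_humidity = 0.03, k_att = 0.36,
                  k_el = 0.08, k_sc = 0.03, k_fl = 0.05,
                  k_br_over_1mg = 0.02, k_ii = 0.04, k_dia = 0.10,
                  k_field_distortion = 0.20))))

jsonlite::write_json(registry, "inst/extdata/adopted_constants.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("adopted constants registry written\n")

if (!do_calibrate) quit(save = "no")

# --- 3. calibrated fixtures (need the package code) --------------------------

pkgload::load_all(".", quiet = TRUE)

mdl <- source_model()
spec <- generate_spectrum(mdl, seed = NULL)
cat(sprintf("default spectrum: mean energy %.3f keV\n", mean_energy(spec)))
air <- load_coefficient_table("dry_air", "renormalized")
rho_ref <- air_density_ideal(environmental_conditions()) * 1e-3
katt_l <- k_att(spec, fac_geometry("lamperti"), air, rho_ref)
cat(sprintf("default spectrum: Lamperti k_att %.5f (target 1.0087)\n", katt_l))

# W-ratio parameterization: linear drop to a knee at 0.4 kPa, then a gentle
# decline; calibrate the level so the envelope-averaged k_humidity is 0.9979.
write_w_ratio <- function(knee_ratio) {
  slope2 <- -0.005
  p <- c(0, 0.4, 5.0)
  r <- c(1, knee_ratio, knee_ratio + slope2 * (5.0 - 0.4))
  jsonlite::write_json(list(p_kPa = p, ratio = r,
                            note = paste("Niatel-type humid/dry W ratio,",
                                         "piecewise linear; level calibrated",
                                         "to the adopted mean humidity",
                                         "correction.")),
                       "inst/extdata/w_ratio.json",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
envelope_mean_kh <- function() {
  vals <- c()
  for (rh in seq(0.15, 0.55, by = 0.05))
    for (tt in c(21, 24))
      for (pp in c(98.66, 102.66))
        vals <- c(vals, k_humidity(spec, environmental_conditions(tt, pp, rh)))
  mean(vals)
}
knee <- 0.9973
for (it in 1:4) {
  write_w_ratio(knee)
  assign("cache", NULL, envir = environment(w_ratio_knots))
  m <- envelope_mean_kh()
  cat(sprintf("  W-ratio knee %.5f -> envelope mean k_humidity %.5f\n",
              knee, m))
  knee <- knee + (0.9979 - m)
}

# Basis functions: denominator = kerma weight E * mu_tr/rho; numerator =
# denominator times a smooth linear trend, level set so the default spectrum
# reproduces the adopted transport corrections.
targets <- list(
  lamperti = c(k_el = 1.0008, k_sc = 0.9987, k_fl = 0.9979, k_br = 1.0),
  ritz = c(k_el = 1.0000, k_sc = 0.9970, k_fl = 0.9969, k_br = 1.0))
slopes <- c(k_el = 0.008, k_sc = -0.006, k_fl = -0.005, k_br = 0.002)

eb <- seq(5, 60, by = 0.5)
den_b <- eb * interpolate_coefficient(air, eb, "mu_tr_rho")
keep <- spec$fluence > 0
Ek <- spec$grid$centers[keep]
wk <- spec$fluence[keep] * approx(eb, den_b, xout = Ek)$y
x_mean <- sum(wk * (Ek - 25) / 25) / sum(wk)   # weighted mean of the trend

for (ch in names(targets)) {
  rows <- list()
  for (f in names(targets[[ch]])) {
    a <- targets[[ch]][[f]] - slopes[[f]] * x_mean
    g <- a + slopes[[f]] * (eb - 25) / 25
    rows[[f]] <- data.frame(factor = f, energy_keV = eb,
                            numerator = signif(den_b * g, 8),
                            denominator = signif(den_b, 8))
  }
  write.csv(do.call(rbind, rows), sprintf("inst/extdata/basis_%s.csv", ch),
            row.names = FALSE, quote = FALSE)
}
cat("basis functions written\n")

# report achieved values
basis <- load_basis_functions("lamperti")
for (f in c("k_el", "k_sc", "k_fl", "k_br"))
  cat(sprintf("  lamperti %s on default spectrum: %.5f\n", f,
              transport_correction(spec, basis, f)))
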