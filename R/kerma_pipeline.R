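# Air-kerma realization: measurement equation, reference-condition
# normalization, air-kerma strength, and the uncertainty budget.

#' Physics constants used by the realization chain
#'
#' @return A list of class `physics_constants`: `w_over_e` (mean energy per
#'   ion pair over elementary charge, 33.97 J/C), `rho_0` (dry-air density at
#'   0 degrees C and 101.325 kPa, 1.2929 kg/m^3), `delta_cutoff` (low-energy
#'   kerma cut-off, 5 keV), `t_ref` (22 degrees C) and `p_ref` (101.325 kPa).
#' @export
physics_constants <- function() {
  structure(list(w_over_e = 33.97, rho_0 = 1.2929, delta_cutoff = 5,
                 t_ref = 22, p_ref = 101.325),
            class = "physics_constants")
}

#' Ideal-gas dry-air density
#'
#' `rho_air = rho_0 * (P / 101.325 kPa) * (273.15 / (273.15 + T))` with
#' `rho_0 = 1.2929 kg/m^3`; humidity is handled separately through the
#' humidity correction.
#'
#' @param env An [environmental_conditions()] object (only `temperature` and
#'   `pressure` are used).
#' @param constants A [physics_constants()] list.
#' @return Density in kg/m^3.
#' @examples
#' air_density_ideal(environmental_conditions(0, 101.325))   # 1.2929
#' @export
air_density_ideal <- function(env, constants = physics_constants()) {
  stopifnot(inherits(env, "environmental_conditions"))
  constants$rho_0 * (env$pressure / 101.325) *
    (273.15 / (273.15 + env$temperature))
}

#' Reference-condition normalization factor
#'
#' Measured kerma is stated at 22 degrees C and 101.325 kPa; the measured
#' value is multiplied by `(101.325 / P) * ((273.15 + T) / 295.15)`. Exactly
#' 1 at reference conditions.
#'
#' @inheritParams air_density_ideal
#' @return Dimensionless factor.
#' @export
reference_condition_factor <- function(env, constants = physics_constants()) {
  stopifnot(inherits(env, "environmental_conditions"))
  (constants$p_ref / env$pressure) *
    ((273.15 + env$temperature) / (273.15 + constants$t_ref))
}

#' Free-air-chamber measurement record
#'
#' @param i_net Net ionization current of one sign, corrected for background,
#'   in A (> 0).
#' @param env An [environmental_conditions()] object.
#' @param chamber A [fac_geometry()].
#' @param distance Source-to-aperture distance in cm (default 50).
#' @param polarity Collecting polarity, `+1` or `-1` (metadata).
#' @return An object of class `measurement_record`.
#' @export
measurement_record <- function(i_net, env, chamber, distance = 50,
                               polarity = 1) {
  stopifnot(inherits(env, "environmental_conditions"),
            inherits(chamber, "fac_geometry"))
  if (any(i_net <= 0)) stop("net current must be > 0")
  if (distance <= 0) stop("distance must be > 0")
  structure(list(i_net = i_net, env = env, chamber = chamber,
                 distance = distance, polarity = polarity),
            class = "measurement_record")
}

#' Realize air kerma from a current measurement
#'
#' The free-air-chamber measurement equation:
#' `K_dot = (W/e) * I_net / (rho_air * V_eff * (1 - g_bar)) * prod(k_i)`,
#' with the radiative-loss fraction `g_bar` taken as identically zero for
#' these beams. The rate is also normalized to reference conditions via
#' [reference_condition_factor()].
#'
#' @param rec A [measurement_record()].
#' @param corrections A [correction_set()].
#' @param constants A [physics_constants()] list.
#' @return An object of class `kerma_result`: `kerma_rate` (Gy/s at
#'   measurement conditions), `kerma_rate_ref` (Gy/s at reference
#'   conditions), `distance` (cm) and the inputs used.
#' @export
realize_air_kerma <- function(rec, corrections,
                              constants = physics_constants()) {
  stopifnot(inherits(rec, "measurement_record"),
            inherits(corrections, "correction_set"))
  rho <- air_density_ideal(rec$env, constants) * 1e-3      # g/cm^3
  mass_g <- rho * rec$chamber$v_eff                        # g
  rate <- constants$w_over_e * rec$i_net / (mass_g * 1e-3) *
    correction_product(corrections)                        # Gy/s
  structure(list(kerma_rate = rate,
                 kerma_rate_ref = rate * reference_condition_factor(rec$env,
                                                                    constants),
                 distance = rec$distance,
                 corrections = corrections, env = rec$env,
                 chamber = rec$chamber),
            class = "kerma_result")
}

#' @export
print.kerma_result <- function(x, ...) {
  cat(sprintf("<kerma_result> %.6g Gy/s at %g cm (%.6g Gy/s at reference conditions)\n",
              x$kerma_rate, x$distance, x$kerma_rate_ref))
  invisible(x)
}

#' Relative air kerma from a photon spectrum
#'
#' Spectrum-weighted kerma integral `sum(Phi(E) * E * mu_tr/rho)` above the
#' low-energy cut-off `delta`, in relative units (the spectra are relative
#' fluence distributions).
#'
#' @param spec A [spectrum_ph()].
#' @param air_table Dry-air [coefficient_table()].
#' @param delta Low-energy cut-off in keV (default 5).
#' @return Relative kerma (arbitrary units).
#' @export
kerma_from_spectrum <- function(spec,
                                air_table = load_coefficient_table("dry_air"),
                                delta = 5) {
  stopifnot(inherits(spec, "spectrum_ph"))
  keep <- spec$fluence > 0 & spec$grid$centers >= delta
  if (!any(keep)) return(0)
  E <- spec$grid$centers[keep]
  sum(spec$fluence[keep] * E *
        interpolate_coefficient(air_table, E, "mu_tr_rho"))
}

#' In-vacuo to in-air kerma ratio
#'
#' The bracket converting the air-kerma rate measured through `path` cm of
#' air into its in-vacuo value: the measured spectrum is un-attenuated by
#' `exp(+mu(E) * path * rho)` and the kerma integral ratio formed. Always
#' >= 1 and increasing in the path length.
#'
#' @param spec_in_air A [spectrum_ph()] measured in air.
#' @param air_table Dry-air [coefficient_table()].
#' @param path Air path in cm (default 50, the reference distance).
#' @param rho_air Air density in g/cm^3 (default reference conditions).
#' @param delta Low-energy cut-off in keV.
#' @return Dimensionless ratio `K_vacuo / K_air`.
#' @export
vacuum_ratio <- function(spec_in_air,
                         air_table = load_coefficient_table("dry_air"),
                         path = 50,
                         rho_air = air_density_ideal(environmental_conditions()) * 1e-3,
                         delta = 5) {
  stopifnot(inherits(spec_in_air, "spectrum_ph"))
  if (path < 0) stop("path must be >= 0")
  keep <- spec_in_air$fluence > 0 & spec_in_air$grid$centers >= delta
  if (!any(keep)) stop("empty spectrum above the cut-off")
  E <- spec_in_air$grid$centers[keep]
  S <- spec_in_air$fluence[keep]
  mutr <- interpolate_coefficient(air_table, E, "mu_tr_rho")
  mu <- interpolate_coefficient(air_table, E, "mu_rho") * rho_air
  sum(S * exp(mu * path) * E * mutr) / sum(S * E * mutr)
}

#' Air-kerma strength
#'
#' `S_K = K_dot_vacuo(d) * d^2`, reported both in SI units (Gy m^2/s) and in
#' the conventional unit U (1 U = 1 uGy m^2/h).
#'
#' @param kerma_rate_vac In-vacuo air-kerma rate in Gy/s at distance
#'   `distance`.
#' @param distance Distance in cm.
#' @return A list with elements `gy_m2_s` and `U`.
#' @examples
#' air_kerma_strength(1e-6 / 3600, 100)  # 1 uGy/h at 1 m -> 1 U
#' @export
air_kerma_strength <- function(kerma_rate_vac, distance) {
  if (any(kerma_rate_vac <= 0) || any(distance <= 0))
    stop("rate and distance must be > 0")
  d_m <- distance / 100
  si <- kerma_rate_vac * d_m^2
  list(gy_m2_s = si, U = si * 1e6 * 3600)
}

# ---------------------------------------------------------------------------
# Uncertainty budget
# ---------------------------------------------------------------------------

#' Uncertainty budget for the air-kerma realization
#'
#' Returns the budget of relative standard uncertainty components (percent)
#' for the named chamber from the packaged registry: Type A components
#' (effective volume, recombination, polarity) and Type B components (net
#' current, W/e, air density, effective volume, the correction factors, and
#' electric-field distortion).
#'
#' @param chamber `"lamperti"` or `"ritz"`.
#' @return An object of class `uncertainty_budget`: a data frame with
#'   columns `component`, `type` (`"A"`/`"B"`) and `u_pct`.
#' @export
uncertainty_budget <- function(chamber = c("lamperti", "ritz")) {
  chamber <- match.arg(chamber)
  reg <- adopted_registry()
  b <- reg$budget
  comp <- rbind(
    data.frame(component = names(b$type_A), type = "A",
               u_pct = unlist(b$type_A), row.names = NULL),
    data.frame(component = names(b$type_B[[chamber]]), type = "B",
               u_pct = unlist(b$type_B[[chamber]]), row.names = NULL))
  structure(comp, chamber = chamber,
            class = c("uncertainty_budget", "data.frame"))
}

#' Combine an uncertainty budget in quadrature
#'
#' Root-sum-square combination within each type and overall, with no
#' effective-degrees-of-freedom machinery.
#'
#' @param budget An [uncertainty_budget()] (or any data frame with columns
#'   `type` and `u_pct`).
#' @return A list with `type_A`, `type_B` and `combined` relative standard
#'   uncertainties in percent.
#' @export
combine_uncertainty <- function(budget) {
  if (any(budget$u_pct < 0)) stop("uncertainty components must be >= 0")
  rss <- function(x) sqrt(sum(x^2))
  a <- rss(budget$u_pct[budget$type == "A"])
  b <- rss(budget$u_pct[budget$type == "B"])
  list(type_A = a, type_B = b, combined = rss(c(a, b)))
}

#' Well-chamber calibration coefficient
#'
#' Transfer-standard arithmetic: the calibration coefficient is the
#' reference-condition air-kerma rate divided by the well-chamber current,
#' in Gy/(A s). The relative standard uncertainty is the quadrature
#' combination of the air-kerma-rate uncertainty with the residual
#' well-chamber components.
#'
#' @param kerma_rate_ref Air-kerma rate at reference conditions, Gy/s (> 0).
#' @param well_current Well-chamber current, A (> 0).
#' @param u_kerma_pct Relative uncertainty of the kerma rate, percent.
#' @param u_residual_pct Residual well-chamber uncertainty, percent.
#' @return A list with `coefficient` (Gy/(A s)) and `u_pct`.
#' @export
well_chamber_coefficient <- function(kerma_rate_ref, well_current,
                                     u_kerma_pct = 0, u_residual_pct = 0) {
  if (any(kerma_rate_ref <= 0) || any(well_current <= 0))
    stop("rate and current must be > 0")
  list(coefficient = kerma_rate_ref / well_current,
       u_pct = sqrt(u_kerma_pct^2 + u_residual_pct^2))
}

#' Compute the per-measurement correction set for a spectrum
#'
#' Mirrors laboratory practice: the attenuation and humidity corrections are
#' computed for the measured spectrum and conditions, the four in-chamber
#' transport corrections are evaluated from the basis functions, and the
#' remaining factors (recombination, bremsstrahlung, initial ion, diaphragm
#' scatter) take their adopted values. Uncertainties are carried over from
#' the adopted registry.
#'
#' @param spec A [spectrum_ph()].
#' @param chamber `"lamperti"` or `"ritz"`.
#' @param env An [environmental_conditions()] object.
#' @param air_table Dry-air [coefficient_table()].
#' @param vapor_table Water-vapor [coefficient_table()].
#' @param basis A [load_basis_functions()] result for the chamber.
#' @return A [correction_set()].
#' @export
compute_corrections <- function(spec, chamber = c("lamperti", "ritz"),
                                env = environmental_conditions(),
                                air_table = load_coefficient_table("dry_air"),
                                vapor_table = load_coefficient_table("water_vapor"),
                                basis = load_basis_functions(chamber)) {
  chamber <- match.arg(chamber)
  geom <- fac_geometry(chamber)
  adopted <- adopted_corrections(chamber)
  rho <- air_density_ideal(env) * 1e-3
  vals <- adopted$values
  vals[["k_att"]] <- k_att(spec, geom, air_table, rho)
  vals[["k_humidity"]] <- k_humidity(spec, env, air_table, vapor_table)
  for (w in c("k_el", "k_sc", "k_fl"))
    vals[[w]] <- transport_correction(spec, basis, w)
  vals[["k_br_over_1mg"]] <- transport_correction(spec, basis, "k_br")
  correction_set(vals, adopted$uncertainties_pct)
}
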