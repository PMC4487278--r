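# Synthetic 50 kV source spectra, forward-modeled pulse-height distributions
# and simulated chamber currents: every stage of the realization chain can be
# exercised without laboratory data.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state so
# that generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic 50 kV source model
#'
#' Parametric model of the photon-fluence spectrum of a miniature 50 kV
#' x-ray source: a Kramers-type bremsstrahlung continuum `(E0 - E)/E`
#' multiplied by an effective filtration term `exp(-b / E^3)` (absorbing the
#' anode self-filtration and the cooling-catheter transmission), plus
#' resolution-width Gaussian characteristic lines of the yttrium K series
#' (14.958, 16.738 keV) and tungsten L series (8.398, 9.672, 11.286 keV).
#' The default filtration and line intensities are calibrated once so that
#' the fluence-weighted mean energy of the ensemble is about 25.3 keV and the
#' kerma-weighted attenuation behaviour matches the measured-source range;
#' per-source variability enters as log-normal jitter on the filtration
#' parameter and the line intensities, reproducing the observed 23.3-27.9 keV
#' spread of mean energies.
#'
#' @param tube_potential Tube potential in kV (spectrum endpoint).
#' @param filtration Effective filtration parameter `b` in keV^3.
#' @param lines Data frame with columns `energy_keV` and `intensity` (line
#'   fluence relative to the total continuum fluence). All lines must lie
#'   below the tube potential.
#' @param e_cutoff Low-energy cut-off in keV (effective value 6-8 for these
#'   sources).
#' @param line_width_fwhm FWHM of the lines in keV (the spectra are still
#'   convolved with the detector resolution, about 0.5 keV).
#' @param jitter_filtration Standard deviation of the log-normal per-source
#'   jitter on `filtration`.
#' @param jitter_lines Standard deviation of the log-normal per-source jitter
#'   on each line intensity.
#' @param jitter_cutoff Half-width (keV) of the uniform per-source jitter on
#'   `e_cutoff`, reflecting the 6-8 keV range of effective cut-offs seen
#'   across sources.
#' @return An object of class `source_model`.
#' @export
source_model <- function(tube_potential = 50,
                         filtration = 12766,
                         lines = default_source_lines(),
                         e_cutoff = 7,
                         line_width_fwhm = 0.5,
                         jitter_filtration = 0.25,
                         jitter_lines = 0.45,
                         jitter_cutoff = 1) {
  stopifnot(is.data.frame(lines),
            all(c("energy_keV", "intensity") %in% names(lines)))
  if (any(lines$energy_keV >= tube_potential))
    stop("characteristic lines must lie below the tube potential")
  if (e_cutoff >= tube_potential) stop("cut-off must be below the endpoint")
  structure(list(tube_potential = tube_potential, filtration = filtration,
                 lines = lines, e_cutoff = e_cutoff,
                 line_width_fwhm = line_width_fwhm,
                 jitter_filtration = jitter_filtration,
                 jitter_lines = jitter_lines,
                 jitter_cutoff = jitter_cutoff),
            class = "source_model")
}

#' @rdname source_model
#' @export
default_source_lines <- function() {
  data.frame(
    energy_keV = c(8.398, 9.672, 11.286, 14.958, 16.738),
    intensity = c(0.010, 0.025, 0.012, 0.2924, 0.0594),
    label = c("W La", "W Lb", "W Lg", "Y Ka", "Y Kb"))
}

#' Generate a synthetic source spectrum
#'
#' Evaluates the [source_model()] on an energy grid; with a `seed`, per-source
#' jitter is drawn reproducibly (the caller's RNG state is untouched), while
#' `seed = NULL` returns the noise-free default spectrum. The returned
#' fluence is normalized to unit total (spectra are relative).
#'
#' @param model A [source_model()].
#' @param seed Integer seed for the per-source jitter, or `NULL` for the
#'   jitter-free default spectrum.
#' @param grid An [energy_grid()].
#' @return A [spectrum_ph()].
#' @examples
#' s <- generate_spectrum(source_model(), seed = 1)
#' mean_energy(s)
#' @export
generate_spectrum <- function(model = source_model(), seed = NULL,
                              grid = energy_grid()) {
  stopifnot(inherits(model, "source_model"), inherits(grid, "energy_grid"))
  b <- model$filtration
  amps <- model$lines$intensity
  cutoff <- model$e_cutoff
  if (!is.null(seed)) {
    jit <- with_seed(seed, list(
      fb = stats::rnorm(1, 0, model$jitter_filtration),
      fl = stats::rnorm(length(amps), 0, model$jitter_lines),
      fc = stats::runif(1, -model$jitter_cutoff, model$jitter_cutoff)))
    # mean-preserving log-normal jitter
    b <- b * exp(jit$fb - model$jitter_filtration^2 / 2)
    amps <- amps * exp(jit$fl - model$jitter_lines^2 / 2)
    cutoff <- cutoff + jit$fc
  }
  E <- grid$centers
  E0 <- model$tube_potential
  inside <- E >= cutoff & E <= E0
  cont <- numeric(grid$n)
  cont[inside] <- (E0 - E[inside]) / E[inside] * exp(-b / E[inside]^3)
  tot_cont <- sum(cont)
  sigma <- model$line_width_fwhm / (2 * sqrt(2 * log(2)))
  flu <- cont
  for (i in seq_along(amps)) {
    line <- stats::dnorm(E, model$lines$energy_keV[i], sigma) * grid$bin_width
    flu <- flu + amps[i] * tot_cont * line
  }
  flu[!inside] <- 0
  flu <- flu / sum(flu)
  spectrum_ph(grid, flu, e_cutoff = cutoff, e_endpoint = E0)
}

#' Acquisition model for the forward pulse-height simulator
#'
#' @param fwhm Intrinsic detector resolution FWHM in keV (default 0.5).
#' @param dead_time_fraction Dead-time fraction in `[0, 1)`; measured
#'   acquisitions ranged from about 0.005 to 0.35.
#' @param pileup_amp Amplitude of the straight-line pile-up background
#'   relative to the peak counts, scaled by the dead-time fraction.
#' @param total_counts Expected total counts in the distribution (sets the
#'   Poisson noise scale); `NA` keeps the incident normalization and disables
#'   Poisson noise.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(fwhm = 0.5, dead_time_fraction = 0.02,
                              pileup_amp = 0.1, total_counts = 2e6) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (dead_time_fraction < 0 || dead_time_fraction >= 1)
    stop("dead_time_fraction must be in [0, 1)")
  structure(list(fwhm = fwhm, dead_time_fraction = dead_time_fraction,
                 pileup_amp = pileup_amp, total_counts = total_counts),
            class = "acquisition_model")
}

# Discrete Gaussian smearing of a counts vector (FWHM in keV).
smear_gaussian <- function(counts, grid, fwhm) {
  if (fwhm <= 0) return(counts)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / grid$bin_width))
  kern <- stats::dnorm(seq(-half, half) * grid$bin_width, 0, sigma)
  kern <- kern / sum(kern)
  n <- length(counts)
  padded <- c(numeric(half), counts, numeric(half))
  out <- numeric(n)
  for (k in seq_along(kern))
    out <- out + kern[k] * padded[seq_len(n) + (k - 1L)]
  out
}

#' Forward-model a spectrum into a pulse-height distribution
#'
#' Convolves the incident spectrum with the detector energy-deposition
#' response, applies Gaussian resolution smearing, adds a straight-line
#' pile-up background proportional to the dead-time fraction (extending above
#' the spectrum endpoint, as pile-up does), and draws Poisson counting noise.
#'
#' @param spec A [spectrum_ph()].
#' @param response A `response_matrix` on the same grid.
#' @param acq An [acquisition_model()].
#' @param seed Integer seed for the Poisson noise, or `NULL`.
#' @param source_id Label recorded in the result.
#' @return A [pulse_height_distribution()].
#' @export
forward_pulse_height <- function(spec, response, acq = acquisition_model(),
                                 seed = NULL, source_id = "synthetic") {
  stopifnot(inherits(spec, "spectrum_ph"), inherits(acq, "acquisition_model"))
  counts <- apply_response(spec, response)
  counts <- smear_gaussian(counts, spec$grid, acq$fwhm)
  if (acq$dead_time_fraction > 0 && acq$pileup_amp > 0) {
    E <- spec$grid$centers
    ramp <- (spec$grid$e_max - E) / (spec$grid$e_max - spec$grid$e_min)
    counts <- counts + acq$pileup_amp * acq$dead_time_fraction *
      max(counts) * ramp
  }
  if (is.finite(acq$total_counts)) {
    counts <- counts / sum(counts) * acq$total_counts
    counts <- with_seed(seed, stats::rpois(length(counts), counts))
  }
  pulse_height_distribution(spec$grid, counts,
                            dead_time_fraction = acq$dead_time_fraction,
                            source_id = source_id,
                            tube_potential = spec$e_endpoint)
}

#' Simulate free-air-chamber current measurements
#'
#' Inverts the measurement equation to produce net currents consistent with a
#' known true air-kerma rate:
#' `i_net = K_dot * rho_air * V_eff / ((W/e) * prod(k_i)) * (1 + noise)`,
#' so that [realize_air_kerma()] recovers the truth exactly at zero noise and
#' independently of the simulated temperature and pressure.
#'
#' @param truth_kerma_rate True air-kerma rate in Gy/s (> 0).
#' @param chamber A [fac_geometry()].
#' @param env An [environmental_conditions()] object.
#' @param corrections A [correction_set()].
#' @param noise_rel Relative (Gaussian) current noise, e.g. 0.001 for 0.1 %.
#' @param n Number of repeat measurements.
#' @param seed Integer seed, or `NULL`.
#' @param constants A [physics_constants()] list.
#' @return A [measurement_record()] whose `i_net` has length `n`.
#' @export
simulate_measurement <- function(truth_kerma_rate, chamber,
                                 env = environmental_conditions(),
                                 corrections = adopted_corrections(chamber$name),
                                 noise_rel = 0, n = 1, seed = NULL,
                                 constants = physics_constants()) {
  stopifnot(inherits(chamber, "fac_geometry"))
  if (truth_kerma_rate <= 0) stop("truth rate must be > 0")
  rho <- air_density_ideal(env, constants) * 1e-3            # g/cm^3
  mass_kg <- rho * chamber$v_eff * 1e-3
  i0 <- truth_kerma_rate * mass_kg /
    (constants$w_over_e * correction_product(corrections))
  noise <- if (noise_rel > 0)
    with_seed(seed, stats::rnorm(n, 0, noise_rel)) else numeric(n)
  measurement_record(i0 * (1 + noise), env, chamber)
}
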