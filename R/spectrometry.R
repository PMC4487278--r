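# Spectrometry: HPGe pulse-height distributions, detector response model and
# the backward-stripping deconvolution.

GE_K_EDGE <- 11.103      # keV, Ge K absorption edge
GE_KALPHA <- 9.886       # keV, Ge K-alpha x ray (alpha1/alpha2 merged)
GE_KBETA <- 10.982       # keV, Ge K-beta x ray
GE_DENSITY <- 5.323      # g/cm^3
GE_OMEGA_K <- 0.535      # K fluorescence yield
GE_FRAC_K <- 0.88        # K-shell share of photoelectric above the edge
GE_KB_SHARE <- 0.13      # K-beta branch of K x rays
ELECTRON_REST <- 510.999 # keV
R_E2 <- 7.9407877e-26    # classical electron radius squared, cm^2

# ---------------------------------------------------------------------------
# Containers
# ---------------------------------------------------------------------------

#' Photon spectrum on an energy grid
#'
#' Relative photon fluence per energy bin. Fluence must be non-negative and is
#' forced to zero outside `[e_cutoff, e_endpoint]`; spectra are relative
#' (shape-only) quantities throughout, as only ratios of spectrum-weighted
#' integrals enter the correction factors.
#'
#' @param grid An [energy_grid()].
#' @param fluence Non-negative fluence per bin (length `grid$n`).
#' @param e_cutoff,e_endpoint Support limits in keV; default to the span of
#'   the nonzero bins.
#' @return An object of class `spectrum_ph`.
#' @export
spectrum_ph <- function(grid, fluence, e_cutoff = NULL, e_endpoint = NULL) {
  stopifnot(inherits(grid, "energy_grid"), length(fluence) == grid$n)
  if (any(fluence < 0)) stop("fluence must be >= 0")
  nz <- which(fluence > 0)
  if (is.null(e_cutoff))
    e_cutoff <- if (length(nz)) grid$centers[nz[1L]] - grid$bin_width / 2 else grid$e_min
  if (is.null(e_endpoint))
    e_endpoint <- if (length(nz)) grid$centers[nz[length(nz)]] + grid$bin_width / 2 else grid$e_max
  fluence[grid$centers < e_cutoff | grid$centers > e_endpoint] <- 0
  structure(list(grid = grid, fluence = as.numeric(fluence),
                 e_cutoff = e_cutoff, e_endpoint = e_endpoint),
            class = "spectrum_ph")
}

#' @export
print.spectrum_ph <- function(x, ...) {
  tot <- sum(x$fluence)
  cat(sprintf("<spectrum_ph> support [%.2f, %.2f] keV, total fluence %.4g",
              x$e_cutoff, x$e_endpoint, tot))
  if (tot > 0) cat(sprintf(", mean energy %.2f keV", mean_energy(x)))
  cat("\n")
  invisible(x)
}

#' Pulse-height distribution
#'
#' Detector counts per pulse-height bin with acquisition metadata. The
#' distribution is the convolution of the incident photon spectrum with the
#' detector energy-deposition response and the intrinsic resolution function.
#'
#' @param grid An [energy_grid()] (shared with the stripping response).
#' @param counts Non-negative counts per bin.
#' @param dead_time_fraction Fraction of acquisition time lost to pulse
#'   processing, in `[0, 1)`.
#' @param live_time Optional live time in seconds.
#' @param source_id Optional source label.
#' @param tube_potential Tube potential in kV (spectrum endpoint).
#' @return An object of class `pulse_height_distribution`.
#' @export
pulse_height_distribution <- function(grid, counts, dead_time_fraction = 0,
                                      live_time = NA_real_, source_id = "",
                                      tube_potential = 50) {
  stopifnot(inherits(grid, "energy_grid"), length(counts) == grid$n)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (dead_time_fraction < 0 || dead_time_fraction >= 1)
    stop("dead_time_fraction must be in [0, 1)")
  structure(list(grid = grid, counts = as.numeric(counts),
                 dead_time_fraction = dead_time_fraction,
                 live_time = live_time, source_id = source_id,
                 tube_potential = tube_potential),
            class = "pulse_height_distribution")
}

#' @export
print.pulse_height_distribution <- function(x, ...) {
  cat(sprintf(
    "<pulse_height_distribution> %s%d bins, %.4g counts, dead time %.1f%%\n",
    if (nzchar(x$source_id)) paste0(x$source_id, ": ") else "",
    x$grid$n, sum(x$counts), 100 * x$dead_time_fraction))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Detector response
# ---------------------------------------------------------------------------

# Klein-Nishina total cross section per electron (cm^2), E in keV.
kn_total <- function(E) {
  k <- E / ELECTRON_REST
  2 * pi * R_E2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) -
                                      log(1 + 2 * k) / k) +
                     log(1 + 2 * k) / (2 * k) -
                     (1 + 3 * k) / (1 + 2 * k)^2)
}

# Escape probability of a secondary photon emitted isotropically from the
# interaction depth of the primary, in a 1-D slab model along the crystal
# thickness t: primary attenuation mu, secondary attenuation mux (both 1/cm).
escape_prob_1d <- function(mu, mux, t) {
  pint <- 1 - exp(-mu * t)
  front <- mu / (mu + mux) * (1 - exp(-(mu + mux) * t))
  dd <- mu - mux
  back <- ifelse(abs(dd) < 1e-9,
                 mu * t * exp(-mu * t),
                 mu / ifelse(abs(dd) < 1e-9, 1, dd) * exp(-mux * t) *
                   (1 - exp(-dd * t)))
  0.5 * (front + back) / pint
}

#' Build the HPGe energy-deposition response matrix
#'
#' Schematizes the detector response for photons normally incident at the
#' center of a cylindrical HPGe crystal: a photopeak (full-energy deposition),
#' Ge K-alpha/K-beta x-ray escape peaks for incident energies above the Ge K
#' edge, and a Compton continuum from single incoherent scatters whose
#' scattered photon escapes the crystal. Escape of secondaries is evaluated
#' with a one-dimensional slab model along the crystal thickness; the single
#' Compton scatter uses the free-electron Klein-Nishina distribution. The
#' result is lower triangular: no probability mass lies above the incident
#' energy.
#'
#' @param grid An [energy_grid()]; must lie within the germanium table range.
#' @param ge_table Germanium [coefficient_table()].
#' @param thickness Crystal thickness in cm (default 1.0).
#' @param diameter Active crystal diameter in cm (metadata; the escape model
#'   is one-dimensional).
#' @return An object of class `response_matrix` with elements
#'   `photopeak_prob` (per incident bin), `downscatter` (lower-triangular
#'   matrix of deposition probability density per keV, `[deposit, incident]`)
#'   and `undetected` (per incident bin: photons that do not interact or whose
#'   deposits fall below the grid).
#' @export
build_response_matrix <- function(grid, ge_table = load_coefficient_table("germanium"),
                                  thickness = 1.0, diameter = 1.13) {
  stopifnot(inherits(grid, "energy_grid"),
            inherits(ge_table, "coefficient_table"))
  rng <- range(ge_table$energy_keV)
  if (grid$centers[1L] < rng[1L] || grid$centers[grid$n] > rng[2L])
    stop("grid extends beyond the germanium coefficient table")
  if (grid$bin_width > (GE_KBETA - GE_KALPHA))
    warning("bin width exceeds the Ge K-alpha/K-beta separation; escape peaks merge")

  E <- grid$centers
  n <- grid$n
  h <- grid$bin_width
  mu <- interpolate_coefficient(ge_table, E, "mu_rho") * GE_DENSITY  # 1/cm
  # electron density factor: Z/A for Ge times Avogadro times density
  ne_fac <- 0.44053 * 6.02214076e23 * GE_DENSITY
  kn_mu <- kn_total(E) * ne_fac                                      # 1/cm
  kn_mu <- pmin(kn_mu, 0.999 * mu)
  f_compton <- kn_mu / mu
  f_photo <- 1 - f_compton

  p_int <- 1 - exp(-mu * thickness)
  photopeak <- numeric(n)
  undetected <- 1 - p_int
  down <- matrix(0, n, n)

  mu_ka <- interpolate_coefficient(ge_table, GE_KALPHA, "mu_rho") * GE_DENSITY
  mu_kb <- interpolate_coefficient(ge_table, GE_KBETA, "mu_rho") * GE_DENSITY

  # Klein-Nishina recoil-energy shape sampled over scattering angle
  ct <- seq(-1, 1, length.out = 1024L)
  for (i in seq_len(n)) {
    Ei <- E[i]
    peak <- p_int[i] * f_photo[i]
    esc_mass_ka <- esc_mass_kb <- 0
    if (Ei > GE_K_EDGE) {
      pk <- GE_FRAC_K * GE_OMEGA_K
      esc_ka <- escape_prob_1d(mu[i], mu_ka, thickness)
      esc_kb <- escape_prob_1d(mu[i], mu_kb, thickness)
      esc_mass_ka <- p_int[i] * f_photo[i] * pk * (1 - GE_KB_SHARE) * esc_ka
      esc_mass_kb <- p_int[i] * f_photo[i] * pk * GE_KB_SHARE * esc_kb
      peak <- peak - esc_mass_ka - esc_mass_kb
    }
    # Compton: scattered-photon escape puts the recoil energy in the continuum
    k <- Ei / ELECTRON_REST
    Esc <- Ei / (1 + k * (1 - ct))           # scattered photon energy
    Tdep <- Ei - Esc                         # deposited recoil energy
    w <- (Esc / Ei)^2 * (Esc / Ei + Ei / Esc - (1 - ct^2))  # dsigma/dOmega shape
    mu_sc <- interpolate_coefficient(ge_table,
                                     pmax(Esc, ge_table$energy_keV[1L]),
                                     "mu_rho") * GE_DENSITY
    q_esc <- escape_prob_1d(mu[i], mu_sc, thickness)
    we <- w * q_esc
    cont_mass <- p_int[i] * f_compton[i] * sum(we) / sum(w)
    peak <- peak + p_int[i] * f_compton[i] * (1 - sum(we) / sum(w))
    if (cont_mass > 0) {
      j <- round((Tdep - grid$e_min) / h + 0.5)
      ok <- j >= 1 & j < i                    # strictly below the incident bin
      wesum <- sum(we)
      if (any(ok)) {
        add <- tapply(we[ok], j[ok], sum) / wesum * cont_mass
        jj <- as.integer(names(add))
        down[jj, i] <- down[jj, i] + as.numeric(add) / h
      }
      undetected[i] <- undetected[i] + cont_mass * sum(we[!ok]) / wesum
    }
    for (esc in list(c(GE_KALPHA, esc_mass_ka), c(GE_KBETA, esc_mass_kb))) {
      if (esc[2L] <= 0) next
      Edep <- Ei - esc[1L]
      j <- round((Edep - grid$e_min) / h + 0.5)
      if (j >= 1 && j < i) down[j, i] <- down[j, i] + esc[2L] / h
      else undetected[i] <- undetected[i] + esc[2L]
    }
    photopeak[i] <- peak
  }
  structure(list(grid = grid, photopeak_prob = photopeak, downscatter = down,
                 undetected = undetected, thickness = thickness,
                 diameter = diameter),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d bins, photopeak prob %.3f-%.3f\n",
              x$grid$n, min(x$photopeak_prob), max(x$photopeak_prob)))
  invisible(x)
}

#' Identity response matrix
#'
#' A degenerate response with unit photopeak probability and no downscatter;
#' stripping with it returns the input counts unchanged. Useful for tests and
#' as the no-detector limit.
#'
#' @param grid An [energy_grid()].
#' @return A `response_matrix`.
#' @export
identity_response <- function(grid) {
  structure(list(grid = grid, photopeak_prob = rep(1, grid$n),
                 downscatter = matrix(0, grid$n, grid$n),
                 undetected = rep(0, grid$n),
                 thickness = NA_real_, diameter = NA_real_),
            class = "response_matrix")
}

#' Forward-convolve a spectrum through a response matrix
#'
#' Computes the noiseless energy-deposition histogram for an incident
#' spectrum: photopeak term plus downscatter contributions. This is the
#' forward model whose triangular inverse is [strip()].
#'
#' @param spec A [spectrum_ph()].
#' @param response A [build_response_matrix()] result on the same grid.
#' @return Numeric vector of expected counts per bin.
#' @export
apply_response <- function(spec, response) {
  stopifnot(inherits(spec, "spectrum_ph"), inherits(response, "response_matrix"))
  if (!same_grid(spec$grid, response$grid)) stop("grids do not match")
  response$photopeak_prob * spec$fluence +
    as.numeric(response$downscatter %*% spec$fluence) * spec$grid$bin_width
}

# ---------------------------------------------------------------------------
# Backward stripping
# ---------------------------------------------------------------------------

#' Backward-strip a pulse-height distribution
#'
#' Top-down triangular deconvolution: starting at the highest bin at or below
#' `strip_start`, the photopeak delta function is normalized to the remaining
#' counts in that bin and the so-normalized deposition spectrum is subtracted
#' from all lower bins; the bin-by-bin normalizations form the incident photon
#' spectrum, still convolved with the (narrow) intrinsic resolution function,
#' which is deliberately not deconvolved. Negative remainders arising from
#' noise are clipped to zero; the total clipped counts are recorded in the
#' `clipped` attribute as a quality metric.
#'
#' @param phd A [pulse_height_distribution()].
#' @param response A `response_matrix` on the same grid.
#' @param strip_start Energy (keV) at which stripping starts; the actual start
#'   is the highest nonzero bin if that is lower.
#' @return A [spectrum_ph()] with attribute `clipped`.
#' @export
strip <- function(phd, response, strip_start = 60) {
  stopifnot(inherits(phd, "pulse_height_distribution"),
            inherits(response, "response_matrix"))
  if (!same_grid(phd$grid, response$grid)) stop("grids do not match")
  grid <- phd$grid
  h <- grid$bin_width
  rem <- phd$counts
  flu <- numeric(grid$n)
  nz <- which(rem > 0)
  if (!length(nz)) {
    out <- spectrum_ph(grid, flu)
    attr(out, "clipped") <- 0
    return(out)
  }
  i_top <- if (strip_start >= grid$e_max) grid$n else grid_index(grid, strip_start)
  i_start <- min(i_top, nz[length(nz)])
  clipped <- 0
  pp <- response$photopeak_prob
  down <- response$downscatter
  for (i in seq(i_start, 1L)) {
    ci <- rem[i]
    if (ci <= 0) {
      clipped <- clipped - min(ci, 0)
      next
    }
    if (pp[i] <= 0)
      stop(sprintf("zero photopeak probability at %.2f keV with nonzero counts",
                   grid$centers[i]))
    f <- ci / pp[i]
    flu[i] <- f
    if (i > 1L) {
      jj <- seq_len(i - 1L)
      rem[jj] <- rem[jj] - f * down[jj, i] * h
    }
  }
  out <- spectrum_ph(grid, flu)
  attr(out, "clipped") <- clipped
  out
}

#' Subtract the straight-line pile-up background
#'
#' At high count rates, pulse pile-up contaminates the stripped spectrum. A
#' straight line through the stripped-spectrum values at `e_high` (the
#' spectrum endpoint, 50 keV) and `e_low` (about 7 keV) is subtracted over
#' that interval, negatives are clipped to zero, and the spectrum is zeroed
#' outside the interval, leaving a spectrum cleanly extending from about
#' 7 keV to 50 keV.
#'
#' @param spec A [spectrum_ph()].
#' @param e_low,e_high Anchor energies in keV (`e_low < e_high`, both inside
#'   the grid).
#' @return A [spectrum_ph()] with support limited to `[e_low, e_high]`.
#' @export
subtract_pileup_background <- function(spec, e_low = 7, e_high = 50) {
  stopifnot(inherits(spec, "spectrum_ph"))
  if (e_low >= e_high) stop("'e_low' must be below 'e_high'")
  grid <- spec$grid
  i_lo <- grid_index(grid, e_low)
  i_hi <- grid_index(grid, e_high)
  y_lo <- spec$fluence[i_lo]
  y_hi <- spec$fluence[i_hi]
  if (y_hi > y_lo && y_hi > 0.01 * max(spec$fluence))
    warning("background at the endpoint exceeds the low-energy anchor; pathological pile-up")
  f <- spec$fluence
  idx <- i_lo:i_hi
  xc <- grid$centers[idx]
  line <- y_lo + (y_hi - y_lo) * (xc - grid$centers[i_lo]) /
    (grid$centers[i_hi] - grid$centers[i_lo])
  f[idx] <- pmax(f[idx] - line, 0)
  f[-idx] <- 0
  spectrum_ph(grid, f, e_cutoff = e_low, e_endpoint = e_high)
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param spec A [spectrum_ph()] with positive total fluence.
#' @return Mean energy in keV.
#' @export
mean_energy <- function(spec) {
  stopifnot(inherits(spec, "spectrum_ph"))
  tot <- sum(spec$fluence)
  if (tot <= 0) stop("empty spectrum")
  sum(spec$grid$centers * spec$fluence) / tot
}

# ---------------------------------------------------------------------------
# Plain-text I/O
# ---------------------------------------------------------------------------

#' Write / read spectra and pulse-height distributions as CSV
#'
#' Two-column CSV (`energy_keV`, `value`) with a JSON metadata sidecar
#' (`<path>.json`) carrying the grid definition and acquisition metadata.
#'
#' @param x A `spectrum_ph` or `pulse_height_distribution`.
#' @param path CSV file path.
#' @return `write_energy_table()` returns `path` invisibly;
#'   `read_spectrum()` and `read_pulse_heights()` return the reconstructed
#'   object.
#' @export
write_energy_table <- function(x, path) {
  UseMethod("write_energy_table")
}

#' @export
write_energy_table.spectrum_ph <- function(x, path) {
  utils::write.csv(data.frame(energy_keV = x$grid$centers, value = x$fluence),
                   path, row.names = FALSE)
  meta <- list(kind = "spectrum", e_min = x$grid$e_min, e_max = x$grid$e_max,
               bin_width = x$grid$bin_width, e_cutoff = x$e_cutoff,
               e_endpoint = x$e_endpoint)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_energy_table.pulse_height_distribution <- function(x, path) {
  utils::write.csv(data.frame(energy_keV = x$grid$centers, value = x$counts),
                   path, row.names = FALSE)
  meta <- list(kind = "pulse_height_distribution", e_min = x$grid$e_min,
               e_max = x$grid$e_max, bin_width = x$grid$bin_width,
               dead_time_fraction = x$dead_time_fraction,
               live_time = x$live_time, source_id = x$source_id,
               tube_potential = x$tube_potential)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) stop("metadata sidecar not found: ", sc)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' @rdname write_energy_table
#' @export
read_spectrum <- function(path) {
  meta <- read_sidecar(path)
  d <- utils::read.csv(path)
  g <- energy_grid(meta$e_min, meta$e_max, meta$bin_width)
  spectrum_ph(g, d$value, e_cutoff = meta$e_cutoff,
              e_endpoint = meta$e_endpoint)
}

#' @rdname write_energy_table
#' @export
read_pulse_heights <- function(path) {
  meta <- read_sidecar(path)
  d <- utils::read.csv(path)
  g <- energy_grid(meta$e_min, meta$e_max, meta$bin_width)
  pulse_height_distribution(g, d$value,
                            dead_time_fraction = meta$dead_time_fraction,
                            live_time = meta$live_time,
                            source_id = meta$source_id,
                            tube_potential = meta$tube_potential)
}
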