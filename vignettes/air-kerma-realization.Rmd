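---
title: "Realizing air kerma for 50 kV electronic brachytherapy sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Realizing air kerma for 50 kV electronic brachytherapy sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kermalab)
```

## The measurement problem

Miniature x-ray tubes operated at tube potentials up to about 50 kV are used
for interstitial radiation therapy ("electronic brachytherapy"). Their
dosimetry is anchored to a primary standard: the air kerma rate realized at a
reference distance of 50 cm with a parallel-plate free-air ionization chamber
(FAC). A FAC measures the ionization charge liberated in a geometrically
defined air volume; converting that charge to air kerma requires the mean
energy expended per ion pair, the air mass in the collecting volume, and a
chain of multiplicative corrections:

$$\dot K_\mathrm{air} \;=\; \frac{W/e \; I_\mathrm{net}}
 {\rho_\mathrm{air} V_\mathrm{eff}\,(1-\bar g)} \prod_i k_i ,$$

with $W/e = 33.97$ J/C, $V_\mathrm{eff}$ the product of the defining-aperture
area and the collector length, and $\bar g$ (the radiative-loss fraction)
taken as identically zero at these energies. The nine corrections $k_i$
cover ion recombination, humidity, air attenuation between the aperture and
the collecting volume, electron loss, photon scatter, fluorescence and
bremsstrahlung reabsorption, initial-ion production, and diaphragm scatter.
Results are stated for dry air at reference conditions (22 °C, 101.325 kPa).

Two proven national-standard chambers are modeled as presets: the Lamperti
FAC (attenuation length $L$ = 3.9 cm) and the larger Ritz FAC
($L$ = 12.7 cm). `kermalab` implements the full chain — spectrometry,
corrections, realization, uncertainty — plus a synthetic-source module that
stands in for laboratory data.

## Spectrometry and backward stripping

Several corrections are spectrum-weighted integrals, so the incident photon
spectrum must be recovered from an HPGe pulse-height distribution. The
pulse-height distribution is the convolution of the incident spectrum with
the detector's energy-deposition response: a photopeak, Ge K x-ray escape
peaks (for incident energies above the K edge at 11.103 keV), and a Compton
continuum from single scatters whose scattered photon leaves the crystal.
With ~0.08 keV bins and a ~0.5 keV FWHM intrinsic resolution, full matrix
inversion is impractical and unnecessary; `strip()` instead walks from the
highest occupied bin downward, normalizing the photopeak to the remaining
counts in each bin and subtracting the bin's full deposition spectrum from
all lower bins. On noise-free input this back-substitution is the exact
algebraic inverse of the forward convolution (the test suite verifies
bin-by-bin recovery to 1e-6). The intrinsic resolution is deliberately *not*
deconvolved: the recovered spectrum stays convolved with a ~0.5 keV kernel,
which is far too narrow to matter in any of the integrals formed from it.

Response-model choices, stated as such:

* the escape of Ge K x rays and of Compton-scattered photons is computed
  with a one-dimensional slab model along the crystal thickness (isotropic
  emission split into front/back hemispheres); a full Monte Carlo response
  would differ in detail, and the model is validated only through round-trip
  identities and the qualitative shape of the stripped-to-raw ratio;
* Ge K$\alpha$/K$\beta$ escape energies are fixed at 9.886 and 10.982 keV;
  if the grid is coarser than their separation the peaks merge (a warning);
* the Compton recoil distribution is free-electron Klein–Nishina, sampled
  over scattering angle and histogrammed onto the deposit grid;
* negative remainders produced by counting noise during stripping are
  clipped to zero; the clipped total is reported in the `clipped` attribute
  as a quality metric.

Pulse pile-up at high dead time contaminates the stripped spectrum; the
package follows the pragmatic straight-line model: a line through the
stripped values at 50 keV and (about) 7 keV is subtracted and the spectrum
zeroed outside that interval. Both anchors are arguments (and CLI flags),
since the low anchor is only nominally 7 keV.

## Interaction coefficients

All spectrum integrals draw on packaged tables of mass attenuation and mass
energy-transfer coefficients for dry air, water vapor and germanium on a
0.5 keV grid spanning 5–60 keV, generated once from standard XCOM-class
anchor values and interpolated log–log (the standard choice for smooth,
photoelectric-dominated coefficients away from edges; the air tables have no
edge in this range, and the germanium table carries bracketing points at the
K edge). Interpolation never extrapolates. Each table exists in two
variants, because the photoelectric cross section in this range can be taken
as-calculated (unrenormalized) or renormalized towards Hartree–Fock values;
the package models the renormalized variant by scaling the photoelectric
component by 0.97, which reproduces the documented sub-percent sensitivity
of the attenuation correction and of the vacuum ratio to this choice. The
renormalized variant is the default used for the adopted attenuation
corrections. Humid air is a mass-fraction mixture of the dry-air and
water-vapor tables (simple additivity).

## Correction factors

**Ion recombination.** The chamber-specific rate parameterizations are
provided (`k_ion_parametric()`), together with the continuous-beam
two-voltage estimator (`k_ion_two_voltage()`). At the kerma rates of these
sources both give values indistinguishable from unity, and the adopted
policy is $k_\mathrm{ion} = 1$ with a 0.03 % uncertainty.

**Humidity.** `k_humidity()` multiplies three ratios: dry-to-humid air
density (CIPM humid-air density with enhancement factor and
compressibility), the humid-to-dry $W$ ratio, and the ratio of
kerma-weighted integrals with dry versus humid coefficients. The $W$ ratio
is a piecewise-linear fixture (knots in `inst/extdata/w_ratio.json`): unity
at zero vapor pressure, a knee near 0.4 kPa, and a plateau near 0.9945 whose
level was calibrated once so the correction averaged over the laboratory
envelope (RH 15–55 %, 21–24 °C, 98.66–102.66 kPa) equals the adopted 0.9979.
The factor is exactly 1 for dry air and decreases monotonically with
humidity over the working range.

**Air attenuation.** `k_att()` forms the ratio of the unattenuated to the
attenuated kerma integral, with the attenuation averaged analytically over
the collector length. Integrals use the midpoint rule on the spectrum grid;
on the 0.08 keV grid the quadrature error is orders of magnitude below the
quoted precision. The effective coefficient `mu_rho_eff()` is
$\ln(k_\mathrm{att})$ per *mass* thickness $\rho_\mathrm{air} L$: the
logarithmic relation is evaluated per mass thickness so the result is in
cm²/g, which reproduces the adopted 1.85 (Lamperti) and 1.83 (Ritz) cm²/g
from the adopted corrections at reference-condition density.
`interpolate_mu_eff_vs_L()` interpolates the chamber family in $L$
(quadratic through three chambers) to estimate the coefficient for an
intermediate-length chamber, reflecting beam hardening along the path.

**In-chamber transport.** Electron loss, photon scatter, fluorescence
reabsorption and the bremsstrahlung term are each the ratio of two
spectrum-weighted integrals of chamber-specific basis functions. Genuine
basis functions come from Monte Carlo transport, which is out of scope here;
the packaged CSVs are smooth fixtures — the kerma weight $E\,\mu_{tr}/\rho$
times a gentle linear trend in energy — whose levels were calibrated once so
the default synthetic spectrum reproduces the adopted values (e.g. Lamperti
$k_{el}$ = 1.0008, $k_{sc}$ = 0.9987, $k_{fl}$ = 0.9979). The integrator
is generic: drop-in CSVs from a real transport calculation work unchanged.

**Initial ion and diaphragm scatter.** Both are adopted as exactly 1. The
registry stores the alternative initial-ion analysis (0.9980) with a
provenance note; the adopted-unity policy carries a 0.2 % standard
uncertainty in the correction registry, while the published budget table's
0.04 % component is kept verbatim in the budget so that its combined totals
reproduce exactly. These two uncertainty conventions coexist in the sources
we follow; the package keeps each where it was adopted rather than
harmonizing them.

## Realization, strength and uncertainty

`realize_air_kerma()` applies the measurement equation and reports the rate
both at measurement conditions and normalized to 22 °C / 101.325 kPa. The
primary reported quantity is the reference air-kerma rate at 50 cm in air;
air-kerma strength $S_K = \dot K^{vac}(d)\, d^2$ is derived output, using
the in-vacuo bracket `vacuum_ratio()` — the measured spectrum un-attenuated
over the 50 cm air path, kerma-integrated above the 5 keV cut-off, divided
by the as-measured integral. For the synthetic ensemble this bracket is
1.12–1.13 with a seed-to-seed scatter of about 1–1.5 %.

`combine_uncertainty()` is plain root-sum-square within Type A and Type B
and overall, with no effective-degrees-of-freedom machinery — matching how
such budgets are actually combined. `well_chamber_coefficient()` implements
the transfer-standard arithmetic (reference kerma rate over well-chamber
current) with quadrature propagation.

## What the synthetic generator does and does not emulate

`generate_spectrum()` produces a Kramers-type continuum $(E_0-E)/E$ filtered
by $\exp(-b/E^3)$ with $b$ = 12766 keV³, plus Gaussian lines of the Y K
series (14.96, 16.74 keV) and W L series (8.40, 9.67, 11.29 keV), cut off at
7 keV and at the 50 keV endpoint on a 0.08 keV grid. The central parameters
were fit once to two ensemble targets — a mean fluence-weighted mean energy
of 25.3 keV and a Lamperti attenuation correction of 1.0087 — and per-source
variability is mean-preserving log-normal jitter on the filtration (SD 0.25)
and line intensities (SD 0.45) plus a uniform ±1 keV jitter on the cut-off,
sized to reproduce the observed source-to-source spreads (mean-energy SD
≈ 1.1 keV, attenuation-correction relative SD ≈ 0.1 %). All generators are
pure functions of (parameters, seed).

The generator emulates the *statistical structure* of measured source
spectra: endpoint, cut-off, line positions, mean-energy distribution, and
the kerma-weighted attenuation behaviour. It does not emulate electron
transport in the anode, the detailed catheter transmission (absorbed into
$b$), pulse-processing electronics, or any correlation between dead time and
spectrum shape. Passing tests therefore demonstrate the correctness and
internal consistency of the analysis chain under realistic spectral shapes —
not the detector physics of any particular instrument.

`forward_pulse_height()` runs the response forward, smears with the 0.5 keV
resolution, adds a straight-line pile-up background scaled by the dead-time
fraction (extending above the endpoint, as pile-up does) and draws Poisson
counts. `simulate_measurement()` inverts the measurement equation to
produce currents with optional Gaussian noise, so recovery is exact at zero
noise and independent of the simulated temperature and pressure.

## Problem sizes and numerical conventions

* Default grid: 688 bins of 0.08 keV spanning 4.96–60 keV (bin centers
  5.00–59.96 keV); response matrix built once per session (~0.5 s).
* Ensemble sizes in tests and in the acceptance script: 30 sources for
  attenuation and vacuum-ratio summaries, 100 for mean-energy statistics,
  26 × 10 repeats for the current-repeatability simulation — matching the
  scale of the measured campaigns they emulate while keeping the whole suite
  in seconds.
* Midpoint-rule quadrature everywhere on the uniform grid; log–log
  interpolation for coefficients; linear interpolation for basis functions.
* Stripping starts at the highest occupied bin at or below 60 keV; negative
  remainders are clipped and accounted; a zero photopeak probability under
  nonzero counts is an error, not a silent skip.
* Degenerate inputs error early: empty spectra, non-positive currents or
  densities, extrapolation requests, mismatched grids or table variants.

## Known limitations

* The coefficient tables are fixture data interpolated from standard anchor
  values, not a cross-section computation; absolute coefficient accuracy is
  a few tenths of a percent to a few percent between anchors, which is
  inconsequential for the ratio-type quantities computed here but would
  matter for absolute fluence dosimetry.
* The transport-correction basis functions are calibrated fixtures; only
  their integrator is physics, and conclusions about chamber-specific
  transport require real Monte Carlo tables.
* The detector response is a schematized single-scatter model; stripping
  accuracy on real instruments depends on response details not modeled here.
* The two-voltage recombination estimator assumes general (continuous-beam)
  recombination; initial recombination is outside its model.
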