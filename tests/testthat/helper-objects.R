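# Shared lazily-built fixtures for the test suite. The detector response on
# the full 0.08 keV grid is built once and reused.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.cache[[name]])) .cache[[name]] <- builder()
  .cache[[name]]
}

default_grid <- function() cached("grid", function() energy_grid())

air_renorm <- function() cached("air_renorm", function()
  load_coefficient_table("dry_air", "renormalized"))

air_unrenorm <- function() cached("air_unrenorm", function()
  load_coefficient_table("dry_air", "unrenormalized"))

vapor_renorm <- function() cached("vapor_renorm", function()
  load_coefficient_table("water_vapor", "renormalized"))

ge_table <- function() cached("ge", function()
  load_coefficient_table("germanium", "renormalized"))

full_response <- function() cached("response", function()
  build_response_matrix(default_grid(), ge_table()))

default_spectrum <- function() cached("default_spectrum", function()
  generate_spectrum(source_model(), seed = NULL, default_grid()))

rho_ref <- function() air_density_ideal(environmental_conditions()) * 1e-3

# single-bin (monoenergetic) spectrum at the bin nearest `energy`
mono_spectrum <- function(energy, grid = default_grid()) {
  flu <- numeric(grid$n)
  i <- round((energy - grid$e_min) / grid$bin_width + 0.5)
  flu[i] <- 1
  spectrum_ph(grid, flu)
}
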