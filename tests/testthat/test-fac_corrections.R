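test_that("parametric recombination corrections have the right limits", {
  expect_equal(k_ion_parametric(0, "lamperti"), 0.9996)
  expect_equal(k_ion_parametric(0, "ritz"), 1.0)
  expect_equal(k_ion_parametric(1e-3, "lamperti", policy = "adopted"), 1.0)
  expect_error(k_ion_parametric(-1, "lamperti"), ">= 0")
})

test_that("two-voltage recombination recovers a known collection loss", {
  expect_equal(k_ion_two_voltage(1, 1), 1.0)
  # algebraic oracle: root-solve the two-voltage relation independently
  ratio <- 1.001
  root <- uniroot(function(k) (4 - 1) / k - (4 - ratio), c(0.9, 1.1),
                  tol = 1e-12)$root
  expect_equal(k_ion_two_voltage(1.001, 1), root, tolerance = 1e-10)
  # forward simulation: general-recombination efficiency 1/(1 + c/V^2)
  k_true <- 1.0005
  a <- k_true - 1                    # c/V^2 at the operating voltage
  i_full <- 1 / (1 + a)
  i_half <- 1 / (1 + 4 * a)
  expect_equal(k_ion_two_voltage(i_full, i_half), k_true, tolerance = 1e-4)
  expect_error(k_ion_two_voltage(4.1, 1), "saturation")
  expect_error(k_ion_two_voltage(-1, 1), "> 0")
})

test_that("humid-air density hits the standard anchors", {
  # dry air at 0 C and 101.325 kPa: 1.2929 kg/m^3 within 0.02 %
  rho0 <- suppressWarnings(
    humid_air_density(environmental_conditions(0, 101.325, 0)))
  expect_equal(rho0, 1.2929, tolerance = 2e-4)
  # dry air at 22 C: matches the ideal-gas expression within 0.05 %
  rho22 <- humid_air_density(environmental_conditions(22, 101.325, 0))
  expect_equal(rho22, air_density_ideal(environmental_conditions(22, 101.325)),
               tolerance = 5e-4)
  # density decreases strictly with humidity at fixed T, P
  rhs <- seq(0, 1, by = 0.1)
  dens <- vapply(rhs, function(r)
    humid_air_density(environmental_conditions(22, 101.325, r)), 0)
  expect_true(all(diff(dens) < 0))
})

test_that("humidity correction is exactly 1 when dry and decreases with humidity", {
  s <- default_spectrum()
  expect_identical(k_humidity(s, environmental_conditions(22, 101.325, 0)), 1)
  rhs <- seq(0, 0.6, by = 0.1)
  kh <- vapply(rhs, function(r)
    k_humidity(s, environmental_conditions(22, 101.325, r)), 0)
  expect_true(all(diff(kh) < 0))
  expect_true(all(kh <= 1 & kh > 0.995))
})

test_that("attenuation correction reduces to the closed form for one line", {
  air <- air_renorm()
  geom <- fac_geometry("lamperti")
  rho <- rho_ref()
  s <- mono_spectrum(20)
  E <- s$grid$centers[which(s$fluence > 0)]
  mu <- interpolate_coefficient(air, E, "mu_rho") * rho
  expected <- exp(mu * geom$d_offset) * mu * geom$collector_length /
    (1 - exp(-mu * geom$collector_length))
  expect_equal(k_att(s, geom, air, rho), expected, tolerance = 1e-12)
  # small-mu limit: k_att ~ 1 + mu * L
  expect_equal(expected, 1 + mu * geom$attenuation_length, tolerance = 1e-5)
})

test_that("attenuation correction is scale invariant and monotone in density and L", {
  air <- air_renorm()
  geom <- fac_geometry("lamperti")
  s <- default_spectrum()
  s10 <- spectrum_ph(s$grid, 10 * s$fluence)
  expect_equal(k_att(s10, geom, air), k_att(s, geom, air), tolerance = 1e-12)

  rhos <- rho_ref() * c(0.8, 1.0, 1.2)
  ks <- vapply(rhos, function(r) k_att(s, geom, air, r), 0)
  expect_true(all(diff(ks) > 0))

  geos <- list(fac_geometry("lamperti"), fac_geometry("ritz"),
               fac_geometry("long", 1, 7, 9, 9, 30.8))
  kl <- vapply(geos, function(g) k_att(s, g, air), 0)
  expect_true(all(diff(kl) > 0))
})

test_that("renormalization variant shifts k_att by less than the per-source spread", {
  s <- default_spectrum()
  geom <- fac_geometry("lamperti")
  d <- abs(k_att(s, geom, air_renorm()) - k_att(s, geom, air_unrenorm()))
  expect_lt(d, 1.0110 - 1.0064)
})

test_that("effective attenuation coefficient inverts a single-line k_att exactly", {
  geom <- fac_geometry("lamperti")
  rho <- rho_ref()
  mu_in <- 1.85                       # cm^2/g
  katt <- exp(mu_in * rho * geom$attenuation_length)
  expect_equal(mu_rho_eff(katt, geom, rho), mu_in, tolerance = 1e-12)
  expect_error(mu_rho_eff(0.999, geom), "exceed 1")
})

test_that("mu_eff versus attenuation length interpolates the chamber family", {
  air <- air_renorm()
  rho <- rho_ref()
  s <- default_spectrum()
  geos <- list(fac_geometry("lamperti"), fac_geometry("ritz"),
               fac_geometry("wyckoff_attix_like", 1, 7, 9, 9, 30.8))
  L <- vapply(geos, function(g) g$attenuation_length, 0)
  mu <- vapply(geos, function(g) mu_rho_eff(k_att(s, g, air, rho), g, rho), 0)
  # supplied point reproduced; linear data interpolated exactly
  expect_equal(interpolate_mu_eff_vs_L(L, mu, 12.7), mu[2], tolerance = 1e-9)
  expect_equal(interpolate_mu_eff_vs_L(c(1, 2), c(1, 3), 1.5), 2,
               tolerance = 1e-12)
  # an intermediate-length chamber (L = 19 cm) lands in the measured range
  mu19 <- interpolate_mu_eff_vs_L(L, mu, 19)
  expect_gt(mu19, 1.513)
  expect_lt(mu19, 1.936)
  expect_error(interpolate_mu_eff_vs_L(L, mu, 40), "xtrapolation")
})

test_that("transport corrections are weighted-ratio integrals", {
  s <- default_spectrum()
  e <- seq(5, 60, by = 0.5)
  flat <- list(k_el = data.frame(energy_keV = e, numerator = e,
                                 denominator = e))
  expect_equal(transport_correction(s, flat, "k_el"), 1.0, tolerance = 1e-12)

  basis <- load_basis_functions("lamperti")
  m <- mono_spectrum(20)
  E <- m$grid$centers[which(m$fluence > 0)]
  b <- basis$k_sc
  pointwise <- approx(b$energy_keV, b$numerator, xout = E)$y /
    approx(b$energy_keV, b$denominator, xout = E)$y
  expect_equal(transport_correction(m, basis, "k_sc"), pointwise,
               tolerance = 1e-9)

  # invariance under common rescaling of both basis functions
  scaled <- basis
  scaled$k_el$numerator <- scaled$k_el$numerator * 7
  scaled$k_el$denominator <- scaled$k_el$denominator * 7
  expect_equal(transport_correction(s, scaled, "k_el"),
               transport_correction(s, basis, "k_el"), tolerance = 1e-12)
})

test_that("default spectrum reproduces the adopted transport corrections", {
  s <- default_spectrum()
  for (ch in c("lamperti", "ritz")) {
    basis <- load_basis_functions(ch)
    adopted <- adopted_corrections(ch)$values
    expect_equal(transport_correction(s, basis, "k_el"),
                 unname(adopted[["k_el"]]), tolerance = 5e-4)
    expect_equal(transport_correction(s, basis, "k_sc"),
                 unname(adopted[["k_sc"]]), tolerance = 5e-4)
    expect_equal(transport_correction(s, basis, "k_fl"),
                 unname(adopted[["k_fl"]]), tolerance = 5e-4)
    expect_equal(transport_correction(s, basis, "k_br"), 1.0,
                 tolerance = 5e-4)
  }
})

test_that("correction sets validate their contents", {
  vals <- adopted_corrections("lamperti")$values
  bad <- vals
  bad[["k_att"]] <- 1.2
  expect_error(correction_set(bad), "0.95")
  expect_error(correction_set(vals[-3]), "missing")
  # the adopted registry stores the alternative initial-ion analysis
  alt <- attr(adopted_corrections("lamperti"), "alternatives")
  expect_equal(alt$k_ii$value, 0.9980)
})

test_that("chamber presets carry the standard dimensions", {
  lam <- fac_geometry("lamperti")
  ritz <- fac_geometry("ritz")
  expect_equal(lam$d_offset, 3.4)
  expect_equal(ritz$d_offset, 9.2)
  expect_equal(lam$v_eff, pi * 0.25^2 * 1.0)
  expect_equal(ritz$v_eff, pi * 0.5^2 * 7.0)
  expect_error(fac_geometry("unknown"), "preset")
})
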