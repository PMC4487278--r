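test_that("ideal-gas density anchors and proportionality", {
  expect_equal(air_density_ideal(environmental_conditions(0, 101.325)), 1.2929)
  expect_equal(air_density_ideal(environmental_conditions(22, 101.325)),
               1.2929 * 273.15 / 295.15)
  full <- air_density_ideal(environmental_conditions(22, 101.325))
  half <- air_density_ideal(environmental_conditions(22, 101.325 / 2))
  expect_equal(half, full / 2, tolerance = 1e-12)
})

test_that("reference-condition factor is 1 at reference conditions", {
  expect_identical(reference_condition_factor(environmental_conditions(22, 101.325)), 1)
  expect_gt(reference_condition_factor(environmental_conditions(25, 101.325)), 1)
  expect_lt(reference_condition_factor(environmental_conditions(22, 103)), 1)
})

test_that("measurement equation: constructed identity and correction product", {
  env <- environmental_conditions()
  lam <- fac_geometry("lamperti")
  unity <- correction_set(stats::setNames(rep(1, 9),
    c("k_ion", "k_humidity", "k_att", "k_el", "k_sc", "k_fl",
      "k_br_over_1mg", "k_ii", "k_dia")))
  consts <- physics_constants()
  rho <- air_density_ideal(env) * 1e-3             # g/cm^3
  i_identity <- rho * lam$v_eff * 1e-3 / consts$w_over_e
  rec <- measurement_record(i_identity, env, lam)
  res <- realize_air_kerma(rec, unity)
  expect_equal(res$kerma_rate, 1.0, tolerance = 1e-12)
  expect_equal(res$kerma_rate_ref, 1.0, tolerance = 1e-12)

  # the adopted corrections multiply the uncorrected kerma by their product
  res_adopted <- realize_air_kerma(rec, adopted_corrections("lamperti"))
  expect_equal(res_adopted$kerma_rate,
               correction_product(adopted_corrections("lamperti")),
               tolerance = 1e-12)
})

test_that("realized kerma is linear in current and in each correction", {
  env <- environmental_conditions(23.5, 99.8)
  lam <- fac_geometry("lamperti")
  cs <- adopted_corrections("lamperti")
  r1 <- realize_air_kerma(measurement_record(1e-12, env, lam), cs)$kerma_rate
  r3 <- realize_air_kerma(measurement_record(3e-12, env, lam), cs)$kerma_rate
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
  cs2 <- cs
  cs2$values[["k_att"]] <- cs$values[["k_att"]] * 1.001
  r2 <- realize_air_kerma(measurement_record(1e-12, env, lam), cs2)$kerma_rate
  expect_equal(r2, r1 * 1.001, tolerance = 1e-12)
})

test_that("reference normalization cancels the simulated temperature and pressure", {
  lam <- fac_geometry("lamperti")
  cs <- adopted_corrections("lamperti")
  truth <- 2.5e-4
  rates <- sapply(list(c(18, 97), c(22, 101.325), c(26, 104)), function(tp) {
    env <- environmental_conditions(tp[1], tp[2])
    rec <- simulate_measurement(truth, lam, env, cs)
    realize_air_kerma(rec, cs)$kerma_rate
  })
  # the density in the simulated current cancels the density in the
  # measurement equation: the recovered rate does not depend on (T, P)
  expect_lt(diff(range(rates)) / mean(rates), 1e-12)
  expect_equal(rates[[1]], truth, tolerance = 1e-12)
})

test_that("spectrum kerma integral reduces to the single-bin product", {
  air <- air_renorm()
  s <- mono_spectrum(30)
  i <- which(s$fluence > 0)
  E <- s$grid$centers[i]
  expect_equal(kerma_from_spectrum(s, air),
               E * interpolate_coefficient(air, E, "mu_tr_rho"),
               tolerance = 1e-12)
  s2 <- spectrum_ph(s$grid, 2 * s$fluence)
  expect_equal(kerma_from_spectrum(s2, air), 2 * kerma_from_spectrum(s, air),
               tolerance = 1e-12)
  # the cut-off removes everything below delta
  expect_equal(kerma_from_spectrum(s, air, delta = 40), 0)
})

test_that("vacuum ratio: limits, closed form and monotonicity", {
  air <- air_renorm()
  s <- default_spectrum()
  expect_equal(vacuum_ratio(s, air, path = 0), 1.0, tolerance = 1e-12)
  m <- mono_spectrum(25)
  E <- m$grid$centers[which(m$fluence > 0)]
  mu <- interpolate_coefficient(air, E, "mu_rho") * rho_ref()
  expect_equal(vacuum_ratio(m, air, path = 50, rho_air = rho_ref()),
               exp(mu * 50), tolerance = 1e-12)
  paths <- c(0, 10, 30, 50, 80)
  vr <- vapply(paths, function(p) vacuum_ratio(s, air, path = p), 0)
  expect_true(all(vr >= 1))
  expect_true(all(diff(vr) > 0))
})

test_that("air-kerma strength units and inverse-square invariance", {
  # 1 uGy/h at 1 m is the definition of 1 U
  sk <- air_kerma_strength(1e-6 / 3600, 100)
  expect_equal(sk$U, 1.0, tolerance = 1e-12)
  # the same physical source expressed at 50 cm gives the same strength
  rate_1m <- 3e-7
  sk_1m <- air_kerma_strength(rate_1m, 100)
  sk_50 <- air_kerma_strength(rate_1m * 4, 50)
  expect_equal(sk_50$gy_m2_s, sk_1m$gy_m2_s, tolerance = 1e-12)
  expect_error(air_kerma_strength(-1, 50), "> 0")
})

test_that("uncertainty combination is RSS, permutation invariant and monotone", {
  b <- data.frame(type = c("A", "A", "B"), u_pct = c(0.03, 0.04, 0.2))
  out <- combine_uncertainty(b)
  expect_equal(out$type_A, sqrt(0.03^2 + 0.04^2))
  expect_equal(out$combined, sqrt(out$type_A^2 + out$type_B^2))
  out_perm <- combine_uncertainty(b[c(3, 1, 2), ])
  expect_equal(out_perm$combined, out$combined)
  # single component passes through
  expect_equal(combine_uncertainty(data.frame(type = "B", u_pct = 0.5))$combined,
               0.5)
  # monotone in every component
  b2 <- b
  b2$u_pct[2] <- 0.05
  expect_gt(combine_uncertainty(b2)$combined, out$combined)
  expect_error(combine_uncertainty(data.frame(type = "A", u_pct = -1)), ">= 0")
})

test_that("well-chamber coefficient arithmetic and uncertainty", {
  wc <- well_chamber_coefficient(2e-4, 2e-4)
  expect_equal(wc$coefficient, 1.0)
  expect_equal(well_chamber_coefficient(2e-4, 4e-4)$coefficient, 0.5)
  # quadrature: a 0.7 % kerma component with the residual reproduces 0.75 %
  resid <- sqrt(0.75^2 - 0.7^2)
  expect_equal(well_chamber_coefficient(1, 1, 0.7, resid)$u_pct, 0.75,
               tolerance = 1e-9)
})
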