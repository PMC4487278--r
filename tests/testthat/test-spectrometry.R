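test_that("response matrix is triangular with exact probability balance", {
  r <- full_response()
  n <- r$grid$n
  # no deposition at or above the incident energy
  expect_true(all(r$downscatter[lower.tri(r$downscatter, diag = TRUE)] == 0))
  expect_true(all(r$photopeak_prob >= 0))
  expect_true(all(r$downscatter >= 0))
  # per-column balance: photopeak + tail + undetected = 1
  bal <- r$photopeak_prob + colSums(r$downscatter) * r$grid$bin_width +
    r$undetected
  expect_lt(max(abs(bal - 1)), 1e-9)
})

test_that("no escape peaks below the Ge K edge", {
  r <- full_response()
  g <- r$grid
  # incident bin just below the K edge at 11.103 keV: Compton recoils all
  # fall below the grid, so the in-grid downscatter column must be empty
  i <- round((10.5 - g$e_min) / g$bin_width + 0.5)
  expect_equal(sum(r$downscatter[, i]), 0)
  expect_gt(r$photopeak_prob[i], 0.5)
  # incident bin at 20 keV: escape peaks at 20 - 9.886 and 20 - 10.982 keV
  i20 <- round((20 - g$e_min) / g$bin_width + 0.5)
  E20 <- g$centers[i20]
  j_ka <- round((E20 - 9.886 - g$e_min) / g$bin_width + 0.5)
  j_kb <- round((E20 - 10.982 - g$e_min) / g$bin_width + 0.5)
  expect_gt(r$downscatter[j_ka, i20], 0)
  expect_gt(r$downscatter[j_kb, i20], 0)
  expect_gt(r$downscatter[j_ka, i20], r$downscatter[j_kb, i20])  # Ka dominates
})

test_that("stripping with the identity response returns the input counts", {
  g <- default_grid()
  counts <- numeric(g$n)
  counts[100:500] <- 1000 * exp(-(100:500 - 300)^2 / 2e4)
  phd <- pulse_height_distribution(g, counts)
  out <- strip(phd, identity_response(g))
  expect_equal(out$fluence, counts, tolerance = 1e-12)
  expect_equal(attr(out, "clipped"), 0)
})

test_that("strip is the exact inverse of forward convolution", {
  r <- full_response()
  for (seed in c(3L, 17L)) {
    s <- generate_spectrum(source_model(), seed = seed, default_grid())
    phd <- pulse_height_distribution(default_grid(), apply_response(s, r))
    rec <- strip(phd, r)
    nz <- s$fluence > 0
    # relative error floored at 1e-9 of the peak: bins dozens of orders of
    # magnitude below the peak carry no information and only amplify
    # cancellation noise
    err <- abs(rec$fluence - s$fluence) /
      pmax(s$fluence, 1e-9 * max(s$fluence))
    expect_lt(max(err[nz]), 1e-6)
    expect_lt(max(abs(rec$fluence[!nz])), 1e-9 * max(s$fluence))
  }
})

test_that("a single line's escape peaks are fully removed by stripping", {
  r <- full_response()
  g <- default_grid()
  s <- mono_spectrum(20, g)
  i20 <- which(s$fluence > 0)
  counts <- apply_response(s, r)
  j_ka <- round((g$centers[i20] - 9.886 - g$e_min) / g$bin_width + 0.5)
  expect_gt(counts[j_ka], 0)            # raw distribution shows the artifact
  rec <- strip(pulse_height_distribution(g, counts), r)
  expect_equal(rec$fluence[j_ka], 0)    # stripped spectrum does not
  expect_equal(rec$fluence[i20], s$fluence[i20], tolerance = 1e-9)
})

test_that("stripped-to-raw ratio approaches the inverse photopeak efficiency near the endpoint", {
  r <- full_response()
  g <- default_grid()
  s <- default_spectrum()
  counts <- apply_response(s, r)
  rec <- strip(pulse_height_distribution(g, counts), r)
  i45 <- round((45 - g$e_min) / g$bin_width + 0.5)
  ratio <- rec$fluence[i45] / counts[i45]
  expect_equal(ratio, 1 / r$photopeak_prob[i45], tolerance = 0.1)
})

test_that("strip flags zero photopeak probability and mismatched grids", {
  g <- energy_grid(5, 10, 0.5)
  r <- identity_response(g)
  r$photopeak_prob[3] <- 0
  counts <- rep(1, g$n)
  expect_error(strip(pulse_height_distribution(g, counts), r),
               "zero photopeak")
  g2 <- energy_grid(5, 10, 0.25)
  expect_error(strip(pulse_height_distribution(g2, rep(1, g2$n)),
                     identity_response(g)), "grids")
})

test_that("pile-up background subtraction removes a linear contaminant", {
  g <- default_grid()
  E <- g$centers
  base <- ifelse(E >= 7 & E <= 50, pmax(0, sin((E - 7) / 43 * pi)), 0)
  s0 <- spectrum_ph(g, base, e_cutoff = 7, e_endpoint = 50)
  # already zero at both anchors -> unchanged on the interior
  out0 <- subtract_pileup_background(s0)
  inner <- E > 7.1 & E < 49.9
  expect_equal(out0$fluence[inner], s0$fluence[inner], tolerance = 1e-9)

  # pure straight line between the anchors -> identically zero
  i_lo <- round((7 - g$e_min) / g$bin_width + 0.5)
  i_hi <- round((50 - g$e_min) / g$bin_width + 0.5)
  line <- numeric(g$n)
  line[i_lo:i_hi] <- seq(2, 0.5, length.out = i_hi - i_lo + 1L)
  out_line <- subtract_pileup_background(spectrum_ph(g, line))
  expect_lt(max(out_line$fluence), 1e-12)

  # spectrum plus that contaminant -> spectrum back (up to clipping)
  contaminated <- spectrum_ph(g, base + line)
  out <- subtract_pileup_background(contaminated)
  expect_equal(out$fluence[inner], base[inner], tolerance = 1e-9)
})

test_that("mean energy reduces to the obvious cases", {
  g <- default_grid()
  s1 <- mono_spectrum(17, g)
  expect_equal(mean_energy(s1), g$centers[which(s1$fluence > 0)])
  # two equal bins placed symmetrically about 25 keV
  flu <- numeric(g$n)
  i <- round((10 - g$e_min) / g$bin_width + 0.5)
  j <- which.min(abs(g$centers - (50 - g$centers[i])))
  flu[i] <- flu[j] <- 3
  expect_equal(mean_energy(spectrum_ph(g, flu)), 25, tolerance = 1e-12)
  expect_error(mean_energy(spectrum_ph(g, numeric(g$n))), "empty")
})

test_that("spectra and pulse-height distributions survive a CSV round trip", {
  tmp <- withr::local_tempdir()
  s <- generate_spectrum(source_model(), seed = 5)
  p1 <- file.path(tmp, "spec.csv")
  write_energy_table(s, p1)
  s2 <- read_spectrum(p1)
  expect_equal(s2$fluence, s$fluence, tolerance = 1e-12)
  expect_equal(s2$e_cutoff, s$e_cutoff, tolerance = 1e-9)

  phd <- pulse_height_distribution(s$grid, s$fluence * 1e5,
                                   dead_time_fraction = 0.12,
                                   source_id = "src-1")
  p2 <- file.path(tmp, "phd.csv")
  write_energy_table(phd, p2)
  phd2 <- read_pulse_heights(p2)
  expect_equal(phd2$counts, phd$counts, tolerance = 1e-12)
  expect_equal(phd2$dead_time_fraction, 0.12)
  expect_equal(phd2$source_id, "src-1")
})
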