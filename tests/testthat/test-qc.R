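cal_disk <- function() {
  calibration_disk(cbind(seq(5.9, 7.0, by = 0.2),
                         seq(5.9, 7.0, by = 0.2) + 0.1))
}

test_that("radial calibration recovers injected offsets and step-size scale errors", {
  disk <- cal_disk()
  rr <- seq(5.8, 7.2, by = 1e-3) # dense calibration sweep
  c0 <- fit_radial_calibration(
    simulate_calibration_scan(disk, radii = rr, noise = TRUE,
                              amplitude = 2e4), disk)
  expect_lt(abs(c0$offset), 5)
  expect_lt(c0$residual_rms, 10)
  expect_lt(abs(c0$scale - 1), 2e-4)
  c80 <- fit_radial_calibration(
    simulate_calibration_scan(disk, radii = rr, offset = 80,
                              noise = TRUE, amplitude = 2e4), disk)
  expect_within(c80$offset - c0$offset, 80, 10)
  # 0.1% scale error recovered within 0.02%
  csc <- fit_radial_calibration(
    simulate_calibration_scan(disk, radii = rr, scale = 1.001,
                              noise = FALSE), disk)
  expect_within(csc$scale, 1.001, 2e-4)
  # at the standard 50 um scan step the shift is still seen within 10 um
  c50 <- fit_radial_calibration(
    simulate_calibration_scan(disk, radii = seq(5.8, 7.2, by = 5e-3),
                              offset = 80, noise = TRUE,
                              amplitude = 2e4), disk)
  expect_within(c50$offset, 80, 10)
})

test_that("fewer than three detected edges is an error", {
  one_gap <- calibration_disk(cbind(6.4, 6.6))
  sc <- simulate_calibration_scan(one_gap, radii = seq(6.3, 6.7, by = 5e-3),
                                  noise = FALSE)
  expect_error(fit_radial_calibration(sc, one_gap), "3 edges")
})

test_that("sedimentation-coefficient error from a radial offset matches the closed form and stays below 0.2%", {
  expect_equal(sedimentation_error_from_offset(0, method = "analytic"), 0)
  e_an <- sedimentation_error_from_offset(100, method = "analytic")
  expect_within(e_an, 0.16, 0.005)
  e_rf <- sedimentation_error_from_offset(100, method = "refit")
  expect_lt(e_rf, 0.2)
  expect_within(e_rf / e_an, 1, 0.1)
  # linear in the offset to first order
  e50 <- sedimentation_error_from_offset(50, method = "analytic")
  expect_within(e_an / e50, 2, 0.01)
  # simulate-and-refit agrees with the closed form up to 200 um
  e200 <- sedimentation_error_from_offset(200, method = "refit")
  expect_within(e200 / sedimentation_error_from_offset(200, method = "analytic"),
                1, 0.1)
})

test_that("z-scan classification is monotone in the attenuation strength", {
  inst405 <- instrument_model(laser_nm = 405, photons_per_unit = 2e4)
  classify <- function(c0) {
    sp <- species("s", s = 0.3, c0 = c0,
                  emission = gaussian_emission(530, 60), eps_exc = 1)
    assess_zscan(simulate_zscan(sp, inst405, noise = FALSE),
                 inst405)$classification
  }
  cls <- vapply(c(0.05, 0.5, 2, 5, 10), classify, character(1))
  flagged <- cls == "too concentrated"
  expect_equal(cls[1], "suitable")
  expect_true(any(flagged))
  # once flagged, stays flagged at higher concentration
  expect_true(all(flagged[which(flagged)[1]:length(flagged)]))
})

test_that("SNR regimes have slopes 1 and 0.5 with the crossover near sigma_read^2", {
  inst <- instrument_model(read_noise_e = 7, adc_gain = 1)
  hi <- simulate_detector_replicates(10^seq(2, 4, length.out = 9), inst,
                                     n_rep = 4000, seed = 31)
  lo <- simulate_detector_replicates(10^seq(log10(0.5), 1, length.out = 8),
                                     inst, n_rep = 20000, seed = 32)
  curve <- snr_characterize(dplyr::bind_rows(lo, hi), offset = 100)
  expect_within(curve$slope_high, 0.5, 0.05)
  expect_within(curve$slope_low, 1.0, 0.1)
  # shot noise = read noise at ~ sigma^2 photoelectrons (49 counts)
  expect_gt(curve$crossover, 49 / 2.5)
  expect_lt(curve$crossover, 49 * 2.5)
  expect_error(snr_characterize(
    simulate_detector_replicates(c(10, 100), inst, n_rep = 20), offset = 100),
    "replicates")
  # shot-only detector: slope 1/2 everywhere
  shot <- simulate_detector_replicates(10^seq(1, 4, length.out = 7),
                                       instrument_model(read_noise_e = 0),
                                       n_rep = 4000, seed = 33)
  cs <- snr_characterize(shot, offset = 100, low_range = c(0, 30),
                         high_range = c(30, 1e4))
  expect_within(cs$slope_high, 0.5, 0.05)
})

test_that("the printed concentration-exposure grid spans at least five decades of linear amplitude", {
  inst <- instrument_model(read_noise_e = 7, adc_gain = 4)
  grid <- simulate_linearity_grid(inst, seed = 5)
  lin <- linearity_range(grid, inst)
  expect_gte(lin$decades, 5)
  expect_within(lin$slope, 1, 0.02)
  # saturating points are excluded from the span
  expect_false(any(lin$table$mean_raw >= 0.95 * 65535))
  # an (ideal) noiseless linear detector is limited only by the grid
  ideal <- dplyr::mutate(grid,
                         mean = 120 * conc * exposure / 4,
                         sd = 1e-9, mean_raw = mean + 100)
  lin2 <- linearity_range(ideal, inst)
  expect_gte(lin2$decades, 6.5)
})

test_that("edge response is set by the excitation spot, not the collection spot", {
  w <- edge_response_width(simulate_edge_scan())
  expect_within(w, 40, 3)
  expect_lt(w, 70) # far below the 135 um collection spot
  # zero-width excitation spot: sampling-floor width of about one step
  tiny <- instrument_model(laser_spot_diameter = 0.5)
  w0 <- edge_response_width(simulate_edge_scan(tiny))
  expect_lt(w0, 55)
  expect_error(edge_response_width(
    simulate_edge_scan(radii = seq(6, 6.4, by = 5e-3), edge_radius = 9)),
    "edge")
})

test_that("band integration improves SNR between the read- and shot-limited bounds", {
  inst <- instrument_model(grating = 150, read_noise_e = 7)
  pitch <- diff(inst$window) / 1600
  wl <- seq(inst$window[1] + pitch / 2, inst$window[2] - pitch / 2,
            length.out = 1600)
  in_band <- wl >= 485 & wl <= 650
  expect_equal(sum(in_band), 487, tolerance = 3) # the integration band
  # coumarin-like band filling 485-650 nm at low amplitude
  spec <- exp(-0.5 * ((wl - 540) / 35)^2)
  mu <- 3 * spec
  set.seed(21)
  reps <- t(vapply(1:400, function(k)
    as.numeric(detect(mu, inst)) - 100, numeric(1600)))
  g <- band_integration_gain(reps, wl, band = c(485, 650))
  expect_gte(g$gain, g$bound_read * 0.7)
  expect_lte(g$gain, g$bound_shot * 1.3)
  expect_gt(g$gain, 4) # order-10 improvement for a band-filling spectrum
  # a single-pixel spectrum cannot gain from integration
  mu1 <- numeric(1600); mu1[800] <- 50
  reps1 <- t(vapply(1:400, function(k)
    as.numeric(detect(mu1, inst)) - 100, numeric(1600)))
  g1 <- band_integration_gain(reps1, wl, band = wl[c(795, 805)])
  expect_lte(g1$gain, 1.1)
  expect_error(band_integration_gain(reps, wl, band = c(1000, 1100)),
               "outside")
})
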