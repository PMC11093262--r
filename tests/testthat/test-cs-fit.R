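test_that("penalty-free fit equals dense brute-force nonnegative least squares", {
  tp <- toy_problem(noise_sd = 0.01)
  cfg <- tp$cfg; cfg$confidence <- 1e-9 # F bound < 1: no penalty accepted
  fit <- fit_cs(list(radii = tp$radii, times = tp$prot$times, Y = tp$Y),
                tp$kern, cfg)
  expect_equal(fit$alpha, 0)
  dense <- pracma::lsqnonneg(tp$kern$K, as.numeric(tp$Y))$x
  expect_lt(max(abs(fit$distribution$c - dense)), 1e-8 * max(dense))
})

test_that("regularization selection respects the F-ratio bound and its monotonicities", {
  tp <- toy_problem(noise_sd = 0.02)
  slice <- list(radii = tp$radii, times = tp$prot$times, Y = tp$Y)
  LtL <- crossprod(mweauc:::second_diff_matrix(8))
  Kp <- tp$kern$K
  G <- crossprod(Kp); b <- as.numeric(crossprod(Kp, as.numeric(tp$Y)))
  yty <- sum(tp$Y^2)
  df <- length(tp$Y)
  rss_fun <- function(a) mweauc:::nnls_compressed(G, b, yty, a, LtL)$rss
  rss0 <- rss_fun(0)
  a68 <- select_regularization(rss_fun, 0.683, rss0, df)
  bound <- rss0 * qf(0.683, df, df)
  expect_lte(rss_fun(a68), bound)
  expect_gt(rss_fun(a68 * 1.05), bound) # largest admissible penalty
  # dense-sweep oracle
  alphas <- 10^seq(log10(a68) - 2, log10(a68) + 2, length.out = 200)
  a_star <- max(alphas[vapply(alphas, rss_fun, numeric(1)) <= bound])
  expect_within(log10(a68), log10(a_star), 0.05)
  # higher confidence admits a larger chi^2 ratio, hence stronger smoothing
  a95 <- select_regularization(rss_fun, 0.95, rss0, df)
  expect_gte(a95, a68)
  # exact data: no penalty
  expect_equal(select_regularization(rss_fun, 0.683, 0, df), 0)
  # peak breadth is nondecreasing in the penalty weight
  breadth <- function(a) {
    cc <- mweauc:::nnls_compressed(G, b, yty, a, LtL)$c
    sum(cc >= 0.05 * max(cc))
  }
  bs <- vapply(c(0, a68, 100 * a68), breadth, numeric(1))
  expect_true(all(diff(bs) >= 0))
})

test_that("noise-free single species is recovered at its s with near-zero rmsd", {
  sp <- species("p", s = 4, ff0 = 1.2, vbar = 0.73, c0 = 1,
                emission = gaussian_emission(700, 50))
  prot <- rotor_protocol(n_scans = 12, scan_interval = 600)
  inst <- instrument_model(laser_nm = 405, photons_per_unit = 1000)
  ds <- simulate_sv_dataset(sp, protocol = prot, instrument = inst,
                            lambda_range = c(690, 710), lambda_step = 10,
                            noise = FALSE, seed = 2)
  cfg <- fit_config(s_min = 1.5, s_max = 10, n_s = 50, ff0 = 1.2,
                    vbar = 0.73, window = c(6.0, 6.9))
  fit <- fit_cs(ds, config = cfg, wavelength = 700)
  pk <- peak_table(fit)
  expect_equal(nrow(pk), 1)
  grid_step <- max(diff(cfg$s_grid[cfg$s_grid < 4.5]))
  expect_within(pk$s_peak, 4, grid_step)
  expect_lt(fit$rmsd, 0.01 * max(scan_slice(ds, 700)$Y))
})

test_that("injected RI and TI noise are recovered up to the documented degeneracy", {
  sp <- species("p", s = 4, ff0 = 1.2, vbar = 0.73, c0 = 1,
                emission = gaussian_emission(700, 50))
  prot <- rotor_protocol(n_scans = 12, scan_interval = 600)
  inst <- instrument_model(laser_nm = 405, photons_per_unit = 4000,
                           adc_gain = 4)
  ds <- simulate_sv_dataset(sp, protocol = prot, instrument = inst,
                            lambda_range = c(690, 710), lambda_step = 10,
                            noise = TRUE, ti_amplitude = 40, ri_sd = 25,
                            seed = 8)
  cfg <- fit_config(s_min = 1.5, s_max = 10, n_s = 40, ff0 = 1.2,
                    vbar = 0.73, window = c(6.0, 6.9))
  fit <- fit_cs(ds, config = cfg, wavelength = 700)
  amp <- max(scan_slice(ds, 700)$Y)
  # RI: per-scan offsets, absolute up to the constant exchanged with TI
  ri_err <- (fit$ri$ri - mean(fit$ri$ri)) -
    (ds$ground_truth$ri - mean(ds$ground_truth$ri))
  expect_lt(max(abs(ri_err)), 0.01 * amp)
  # TI: zero-mean convention over the analysis window
  idx <- match(round(fit$ti$radius, 6), round(prot$radii, 6))
  ti_true <- ds$ground_truth$ti[idx]
  ti_err <- fit$ti$ti - (ti_true - mean(ti_true))
  expect_lt(max(abs(ti_err)), 0.01 * amp)
  expect_equal(mean(fit$ti$ti), 0, tolerance = 1e-9)
})

test_that("all-zero data yield a zero distribution, not an error", {
  tp <- toy_problem()
  fit <- fit_cs(list(radii = tp$radii, times = tp$prot$times,
                     Y = matrix(0, length(tp$radii), 3)),
                tp$kern, tp$cfg)
  expect_true(all(fit$distribution$c == 0))
  expect_equal(fit$rmsd, 0)
})

test_that("kernel columns deplete over time for fast species", {
  tp <- toy_problem()
  K <- tp$kern$K
  nr <- length(tp$radii)
  col_fast <- matrix(K[, 8], nr, 3)
  norms <- sqrt(colSums(col_fast^2))
  expect_true(all(diff(norms) < 0))
  # f/f0 = 1 is the compact-sphere (maximal diffusion) boundary
  expect_gt(diffusion_from_s(4, 1, 0.73, solvent()),
            diffusion_from_s(4, 1.5, 0.73, solvent()))
})

test_that("close species are separated by the inversion; smoothing limits the regularized resolution", {
  # 15% apart in s: the inversion itself separates them cleanly, while
  # second-derivative smoothing at confidence 0.683 merges such close
  # neighbours into one broad peak (species with only slightly different
  # s are not distinguishable under this regularization)
  sps <- list(
    species("m", s = 4.0, ff0 = 1.2, vbar = 0.73, c0 = 1,
            emission = gaussian_emission(700, 50)),
    species("d", s = 4.6, ff0 = 1.2, vbar = 0.73, c0 = 0.9,
            emission = gaussian_emission(700, 50)))
  prot <- rotor_protocol(n_scans = 25, scan_interval = 450)
  inst <- instrument_model(laser_nm = 405, photons_per_unit = 5000,
                           adc_gain = 4)
  ds <- simulate_sv_dataset(sps, protocol = prot, instrument = inst,
                            lambda_range = c(690, 710), lambda_step = 10,
                            noise = TRUE, ri_sd = 3, seed = 12)
  cfg <- fit_config(s_min = 2, s_max = 9, n_s = 70, ff0 = 1.2,
                    vbar = 0.73, window = c(6.0, 6.9))
  cfg0 <- cfg; cfg0$confidence <- 1e-9 # penalty-free
  pk0 <- dplyr::arrange(peak_table(fit_cs(ds, config = cfg0,
                                          wavelength = 700)), s_peak)
  expect_gte(nrow(pk0), 2)
  expect_within(pk0$s_peak[1], 4.0, 0.1)
  expect_within(pk0$s_peak[nrow(pk0)], 4.6, 0.1)
  fit_r <- fit_cs(ds, config = cfg, wavelength = 700)
  expect_within(peak_table(fit_r)$s_peak[1],
                weighted.mean(c(4.0, 4.6), c(1, 0.9)), 0.1)
})

test_that("monomer-dimer-like species 50% apart are baseline separated by the regularized fit", {
  sps <- list(
    species("monomer", s = 4.3, ff0 = 1.3, vbar = 0.73, c0 = 1,
            emission = gaussian_emission(550, 40)),
    species("dimer", s = 6.5, ff0 = 1.45, vbar = 0.73, c0 = 0.5,
            emission = gaussian_emission(550, 40)))
  prot <- rotor_protocol(n_scans = 25, scan_interval = 450)
  inst <- instrument_model(laser_nm = 405, photons_per_unit = 5000,
                           adc_gain = 4)
  ds <- simulate_sv_dataset(sps, protocol = prot, instrument = inst,
                            lambda_range = c(545, 560), lambda_step = 5,
                            noise = TRUE, ri_sd = 3, seed = 13)
  cfg <- fit_config(s_min = 2, s_max = 12, n_s = 70, ff0 = 1.35,
                    vbar = 0.73, window = c(6.0, 6.9))
  pk <- dplyr::arrange(peak_table(fit_cs(ds, config = cfg,
                                         wavelength = 550)), s_peak)
  expect_equal(nrow(pk), 2)
  expect_within(pk$s_peak[1], 4.3, 0.25)
  expect_within(pk$s_peak[2], 6.5, 0.4)
})

test_that("maximum-entropy regularization recovers the same peak position", {
  ds <- single_species_dataset()
  cfg <- fit_config(s_min = 1.5, s_max = 10, n_s = 40, ff0 = 1.2,
                    vbar = 0.73, regularization = "maximum_entropy",
                    window = c(6.0, 6.9))
  fit <- fit_cs(ds, config = cfg, wavelength = 700)
  expect_within(peak_table(fit)$s_peak[1], 4, 0.1)
  expect_gte(fit$rmsd, fit$rmsd_unreg * 0.999)
})
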