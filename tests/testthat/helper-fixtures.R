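# shared fixtures, built once per session and memoised

`%||%` <- function(x, y) if (is.null(x)) y else x

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# gold-nanocluster-like two-species dataset: 3.4 S / 3.9 S, emission
# maxima 800 / 705 nm, 405 nm excitation, shared vbar 0.547 and f/f0 1
aunc_species <- function() {
  list(
    species("AuNC-3.4S", s = 3.4, ff0 = 1.0, vbar = 0.547, c0 = 1.0,
            emission = gaussian_emission(800, 60)),
    species("AuNC-3.9S", s = 3.9, ff0 = 1.0, vbar = 0.547, c0 = 0.8,
            emission = gaussian_emission(705, 50)))
}

aunc_instrument <- function() {
  instrument_model(laser_nm = 405, grating = 150,
                   photons_per_unit = 20000, adc_gain = 4)
}

aunc_dataset <- function() fixture("aunc_ds", function() {
  simulate_sv_dataset(aunc_species(),
                      protocol = rotor_protocol(n_scans = 60,
                                                scan_interval = 300),
                      instrument = aunc_instrument(),
                      lambda_range = c(640, 880), lambda_step = 6,
                      noise = TRUE, ri_sd = 5, seed = 7)
})

aunc_config <- function(n_s = 80) {
  fit_config(s_min = 1.5, s_max = 8, n_s = n_s, ff0 = 1.0, vbar = 0.547,
             window = c(6.0, 6.9))
}

aunc_c2d <- function() fixture("aunc_c2d", function() {
  fit_cs_lambda(aunc_dataset(), aunc_config(), lambda_step = 6)
})

# single protein-like species dataset at one narrow band
single_species_dataset <- function() fixture("single_ds", function() {
  sp <- species("probe", s = 4, ff0 = 1.2, vbar = 0.73, c0 = 1,
                emission = gaussian_emission(700, 50))
  simulate_sv_dataset(sp,
                      protocol = rotor_protocol(n_scans = 15,
                                                scan_interval = 600),
                      instrument = instrument_model(laser_nm = 405,
                                                    photons_per_unit = 5000,
                                                    adc_gain = 4),
                      lambda_range = c(680, 720), lambda_step = 10,
                      noise = TRUE, ri_sd = 3, seed = 4)
})

single_species_kernel <- function(cfg) {
  ds <- single_species_dataset()
  sl <- scan_slice(ds, 700)
  win <- cfg$window %||% c(6.0, 6.9)
  keep <- sl$radii >= win[1] & sl$radii <= win[2]
  build_lamm_kernel(cfg$s_grid, cfg$ff0, cfg$vbar, solvent(),
                    ds$protocol, sl$radii[keep], sl$times)
}

expect_within <- function(value, target, tol) {
  expect_lt(abs(value - target), tol)
}

# tiny inversion problem (3 scans x ~20 radii, two discrete species) for
# brute-force oracle comparisons
toy_problem <- function(noise_sd = 0, seed = 1) {
  prot <- rotor_protocol(meniscus = 6.0, bottom = 6.2, radial_step = 100,
                         n_scans = 3, scan_interval = 1500)
  cfg <- fit_config(s_min = 2, s_max = 8, n_s = 8, ff0 = 1.2, vbar = 0.73,
                    fit_ti = FALSE, fit_ri = FALSE,
                    window = c(6.0, 6.19))
  radii <- prot$radii[prot$radii <= 6.19]
  kern <- build_lamm_kernel(cfg$s_grid, 1.2, 0.73, solvent(), prot,
                            radii, prot$times)
  c_true <- numeric(8); c_true[c(3, 6)] <- c(2, 1)
  y <- as.numeric(kern$K %*% c_true)
  if (noise_sd > 0) { set.seed(seed); y <- y + rnorm(length(y), 0, noise_sd) }
  list(prot = prot, cfg = cfg, kern = kern, radii = radii,
       c_true = c_true, Y = matrix(y, length(radii), 3))
}
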