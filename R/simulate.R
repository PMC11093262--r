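# ---- scan containers --------------------------------------------------

new_scan <- function(radius, wavelength, counts, time = 0, speed = 0,
                     z = NA_real_, exposure = NA_real_, meta = list()) {
  counts <- as.matrix(counts)
  if (length(radius) != nrow(counts) || length(wavelength) != ncol(counts))
    abort("counts must be a radius x wavelength matrix")
  if (is.unsorted(radius, strictly = TRUE))
    abort("radii must be strictly increasing")
  if (any(counts < 0) || any(counts > 65535))
    abort("counts must lie in [0, 65535]")
  structure(list(time = time, speed = speed, z = z, radius = radius,
                 wavelength = wavelength, counts = counts,
                 exposure = exposure, meta = meta),
            class = "mwe_scan")
}

#' @export
print.mwe_scan <- function(x, ...) {
  cat(sprintf("<mwe_scan> t = %g s, %d radii x %d wavelengths, %g rpm\n",
              x$time, length(x$radius), length(x$wavelength), x$speed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mwe_scan <- function(x, ...) {
  tibble(time = x$time,
         radius = rep(x$radius, times = length(x$wavelength)),
         wavelength = rep(x$wavelength, each = length(x$radius)),
         counts = as.numeric(x$counts))
}

new_scan_set <- function(scans, instrument, protocol, wavelength,
                         ground_truth = NULL) {
  structure(list(scans = scans, instrument = instrument,
                 protocol = protocol, wavelength = wavelength,
                 ground_truth = ground_truth),
            class = "mwe_scan_set")
}

#' @export
print.mwe_scan_set <- function(x, ...) {
  cat(sprintf("<mwe_scan_set> %d scans, %d radii x %d wavelengths, %g rpm\n",
              length(x$scans), length(x$scans[[1]]$radius),
              length(x$wavelength), x$protocol$speed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mwe_scan_set <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$scans, function(sc, i) {
    dplyr::mutate(tidy(sc), scan = i, .before = 1)
  }))
}

#' Single-wavelength slice of a scan set
#'
#' @param scanset An `mwe_scan_set`.
#' @param wavelength Wavelength (nm); the nearest grid wavelength is used.
#'   `NULL` integrates counts over all wavelengths (offset removed once
#'   per wavelength).
#' @param offset_subtract Subtract the instrument's electronic offset.
#' @return List with `radii`, `times`, and `Y` (radius x scan matrix).
#' @export
scan_slice <- function(scanset, wavelength = NULL, offset_subtract = TRUE) {
  off <- if (offset_subtract) scanset$instrument$offset_counts else 0
  radii <- scanset$scans[[1]]$radius
  times <- purrr::map_dbl(scanset$scans, "time")
  if (is.null(wavelength)) {
    Y <- vapply(scanset$scans,
                function(sc) rowSums(sc$counts - off),
                numeric(length(radii)))
  } else {
    j <- which.min(abs(scanset$wavelength - wavelength))
    Y <- vapply(scanset$scans, function(sc) sc$counts[, j] - off,
                numeric(length(radii)))
  }
  list(radii = radii, times = times, Y = Y)
}

# run code with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- radial optics ----------------------------------------------------

# radial point response: Gaussian excitation (1/e^2 diameter = spot) times
# the flat-top collection acceptance. x in um. unnormalised.
radial_psf <- function(instrument, x) {
  w <- instrument$laser_spot_diameter / 2 # 1/e^2 radius, um
  g <- exp(-2 * x^2 / w^2)
  g[abs(x) > instrument$collection_spot / 2] <- 0
  g
}

#' Simulate a radial scan of a static intensity pattern
#'
#' Convolves a radial fluorophore pattern with the instrument's radial
#' response (Gaussian excitation spot inside the flat-top collection
#' spot) and samples at the scan radii. Used for calibration-disk and
#' edge-response scans.
#'
#' @param pattern Function of radius (cm) returning relative fluorophore
#'   density.
#' @param instrument An [instrument_model()].
#' @param radii Scan radii (cm).
#' @param amplitude Expected peak photoelectrons for `pattern = 1`.
#' @param noise Apply [detect()] noise.
#' @return An `mwe_scan` with a single wavelength column at the grating
#'   window centre.
#' @export
simulate_radial_scan <- function(pattern, instrument = instrument_model(),
                                 radii, amplitude = 1e4, noise = FALSE) {
  half_um <- instrument$collection_spot / 2
  xs <- seq(-half_um, half_um, by = 1) # um
  w <- radial_psf(instrument, xs)
  w <- w / sum(w)
  sig <- vapply(radii, function(r) sum(w * pattern(r + xs * 1e-4)),
                numeric(1))
  ne <- amplitude * sig
  counts <- if (noise) detect(ne, instrument)
            else detect(ne, instrument, noise = FALSE)
  new_scan(radii, mean(instrument$window), matrix(counts, ncol = 1),
           exposure = instrument$exposure_ms)
}

#' Calibration disk gap layout
#'
#' Transparent gaps over a fluorescent backing; fluorescence is high in
#' the gaps and blocked under the opaque bars.
#'
#' @param gaps Two-column matrix or data frame of gap (start, end) radii
#'   in cm, disjoint and ordered.
#' @return An object of class `mwe_disk`; `edges` holds all gap edges.
#' @export
calibration_disk <- function(gaps) {
  g <- as.matrix(gaps)
  if (ncol(g) != 2 || any(g[, 2] <= g[, 1]))
    abort("gaps must be (start, end) pairs with end > start")
  if (nrow(g) > 1 && any(g[-1, 1] <= g[-nrow(g), 2]))
    abort("gaps must be disjoint and ordered")
  structure(list(gaps = g, edges = sort(as.numeric(t(g)))),
            class = "mwe_disk")
}

#' Simulate a radial scan of the calibration disk
#'
#' @param disk A [calibration_disk()].
#' @param instrument An [instrument_model()].
#' @param radii Commanded scan radii (cm).
#' @param offset True radial offset in um (physical = commanded * scale +
#'   offset).
#' @param scale True step-size scale factor.
#' @inheritParams simulate_radial_scan
#' @return An `mwe_scan`.
#' @export
simulate_calibration_scan <- function(disk, instrument = instrument_model(),
                                      radii = seq(5.8, 7.2, by = 5e-3),
                                      offset = 0, scale = 1,
                                      amplitude = 1e4, noise = FALSE) {
  g <- disk$gaps
  pattern <- function(r) {
    p <- r * scale + offset * 1e-4
    inside <- rep(0, length(p))
    for (k in seq_len(nrow(g)))
      inside <- inside + as.numeric(p >= g[k, 1] & p <= g[k, 2])
    pmin(inside, 1)
  }
  simulate_radial_scan(pattern, instrument, radii, amplitude, noise)
}

#' Simulate a radial scan across a sharp fluorophore step
#'
#' Fixture for the radial-resolution (edge response) measurement: the
#' fluorophore density steps from 0 to 1 at `edge_radius`. By default the
#' step is placed midway between two scan samples so the interpolated
#' 10-90% width reflects the optical response rather than sampling phase.
#'
#' @inheritParams simulate_calibration_scan
#' @param edge_radius Step position (cm); default midway between two
#'   samples near the cell centre.
#' @return An `mwe_scan`.
#' @export
simulate_edge_scan <- function(instrument = instrument_model(),
                               radii = seq(6.0, 7.0, by = 5e-3),
                               edge_radius = NULL, amplitude = 1e4,
                               noise = FALSE) {
  if (is.null(edge_radius)) {
    mid <- radii[length(radii) %/% 2]
    edge_radius <- mid + (radii[2] - radii[1]) / 2
  }
  pattern <- function(r) as.numeric(r >= edge_radius)
  simulate_radial_scan(pattern, instrument, radii, amplitude, noise)
}

# ---- z scans ----------------------------------------------------------

new_zscan <- function(z, wavelength, counts, radius, speed = 0,
                      meta = list()) {
  counts <- as.matrix(counts)
  if (is.unsorted(z, strictly = TRUE)) abort("z grid must be strictly increasing")
  if (any(counts < 0) || any(counts > 65535))
    abort("counts must lie in [0, 65535]")
  structure(list(z = z, wavelength = wavelength, counts = counts,
                 radius = radius, speed = speed, meta = meta),
            class = "mwe_zscan")
}

#' @export
print.mwe_zscan <- function(x, ...) {
  cat(sprintf("<mwe_zscan> %d z positions at r = %g cm, %d wavelengths\n",
              length(x$z), x$radius, length(x$wavelength)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mwe_zscan <- function(x, ...) {
  tibble(z = rep(x$z, times = length(x$wavelength)),
         wavelength = rep(x$wavelength, each = length(x$z)),
         counts = as.numeric(x$counts), radius = x$radius)
}

#' Simulate a z-scan through the measurement cell
#'
#' Moves the confocal volume along the optical axis and records the
#' collected fluorescence. The collection weight along z is a flat-top of
#' width `confocal_depth`; excitation is attenuated with depth by the
#' primary inner-filter effect and emitted light is reabsorbed on its way
#' out by the secondary effect. Dilute samples give a symmetric profile
#' peaked at the cell centre; concentrated samples shift the peak toward
#' the incident cell face.
#'
#' @param sp A [species()]; `c0`, `eps_exc`, `eps_em` and the emission
#'   spectrum are used. The concentration is uniform over the cell depth.
#' @param instrument An [instrument_model()].
#' @param z Commanded z grid in mm.
#' @param wavelengths Emission wavelengths (nm) to record; default the
#'   species' emission maximum.
#' @param cell_face_z Commanded z of the cell face nearest the optics
#'   under ambient conditions (mm).
#' @param vacuum If `TRUE`, the cell is shifted by the instrument's
#'   `z_vacuum_shift`.
#' @param speed Rotor speed (rpm), recorded as metadata.
#' @param noise Apply detection noise.
#' @param n_avg Number of averaged acquisitions when `noise = TRUE`.
#' @param seed Optional RNG seed.
#' @return An `mwe_zscan`.
#' @export
simulate_zscan <- function(sp, instrument = instrument_model(),
                           z = seq(8, 17, by = 0.1), wavelengths = NULL,
                           cell_face_z = 9.4, vacuum = TRUE, speed = 3000,
                           noise = TRUE, n_avg = 1, seed = NULL) {
  face <- cell_face_z + if (vacuum) instrument$z_vacuum_shift else 0
  depth_cm <- instrument$cell_depth / 10
  zg <- seq(0, depth_cm, length.out = 241) # depth inside cell, cm
  conc <- rep(sp$c0, length(zg))
  if (is.null(wavelengths)) {
    pk <- sp$emission$wavelength[which.max(sp$emission$intensity)]
    wavelengths <- pk
  }
  spec <- disperse_spectrum(sp$emission, instrument,
                            wavelengths = wavelengths)
  half <- instrument$confocal_depth / 10 / 2 # cm
  iexc <- excitation_profile(zg, conc, sp$eps_exc)
  counts <- with_seed(seed, {
    cnt <- matrix(0, length(z), length(wavelengths))
    for (j in seq_along(wavelengths)) {
      esc <- emission_escape(zg, conc, sp$eps_em(wavelengths[j]))
      integrand <- iexc * conc * esc
      sig <- vapply(z, function(zc) {
        d <- (zc - face) / 10 # commanded mm -> depth cm
        w <- as.numeric(abs(zg - d) <= half)
        pracma::trapz(zg, w * integrand)
      }, numeric(1))
      ne <- instrument$photons_per_unit * instrument$exposure_ms *
        sp$exc_eff * spec$intensity[j] * sig / depth_cm
      cnt[, j] <- if (noise) {
        acc <- matrix(detect(rep(ne, n_avg), instrument),
                      nrow = length(ne))
        rowMeans(acc)
      } else detect(ne, instrument, noise = FALSE)
    }
    cnt
  })
  new_zscan(z, wavelengths, counts, radius = 6.6, speed = speed,
            meta = list(cell_face_z = cell_face_z, vacuum = vacuum,
                        seed = seed))
}

# ---- sedimentation-velocity datasets ----------------------------------

#' Simulate a multiwavelength sedimentation-velocity dataset
#'
#' Composes the Lamm-equation solution for each species with its
#' dispersed emission spectrum, optional inner-filter attenuation and the
#' EMCCD detection chain into a time series of radius x wavelength count
#' matrices. Injected time-invariant (TI, fixed radial pattern) and
#' radial-invariant (RI, per-scan offset) noise components are recorded
#' as ground truth, as is the seed.
#'
#' @param species_list A [species()] or list of species.
#' @param solv A [solvent()].
#' @param protocol A [rotor_protocol()].
#' @param instrument An [instrument_model()].
#' @param lambda_range Emission wavelength range recorded (nm); default
#'   the active grating window.
#' @param lambda_step Wavelength bin width (nm), default 1.5.
#' @param noise Apply detection noise.
#' @param ti_amplitude Amplitude (counts) of an injected fixed radial
#'   signal pattern.
#' @param ri_sd Standard deviation (counts) of injected per-scan offsets.
#' @param beam_drift Amplitude (counts) of a linear signal ramp over the
#'   radial range (first-generation beam-drift artefact; off by default).
#' @param measure_depth Depth of the confocal volume centre inside the
#'   cell (cm) used for inner-filter attenuation; default mid-cell.
#' @param seed RNG seed recorded in the ground truth.
#' @return An `mwe_scan_set` with a `ground_truth` sidecar (species
#'   table, injected TI/RI vectors, seed).
#' @export
simulate_sv_dataset <- function(species_list, solv = solvent(),
                                protocol = rotor_protocol(),
                                instrument = instrument_model(),
                                lambda_range = NULL, lambda_step = 1.5,
                                noise = TRUE, ti_amplitude = 0, ri_sd = 0,
                                beam_drift = 0, measure_depth = NULL,
                                seed = 1L) {
  if (inherits(species_list, "mwe_species")) species_list <- list(species_list)
  win <- instrument$window
  lambda_range <- lambda_range %||% win
  wl <- seq(max(lambda_range[1], win[1] + lambda_step / 2),
            min(lambda_range[2], win[2] - lambda_step / 2), by = lambda_step)
  if (length(wl) < 1) abort("wavelength grid is empty for this grating")
  radii <- protocol$radii
  times <- protocol$times
  depth <- measure_depth %||% (instrument$cell_depth / 10 / 2)
  nr <- length(radii); nt <- length(times); nw <- length(wl)

  expected <- array(0, dim = c(nr, nw, nt))
  truth_species <- purrr::map_dfr(species_list, function(sp) {
    tibble(name = sp$name, s = sp$s, ff0 = sp$ff0, vbar = sp$vbar,
           c0 = sp$c0,
           lambda_max = sp$emission$wavelength[which.max(sp$emission$intensity)])
  })
  for (sp in species_list) {
    prof <- profiles_matrix(solve_lamm(sp, solv, protocol, times = times))
    spec <- disperse_spectrum(sp$emission, instrument, wavelengths = wl)
    att <- if (sp$eps_exc > 0)
      10^(-sp$eps_exc * prof * depth) else 1
    base <- instrument$photons_per_unit * instrument$exposure_ms *
      sp$exc_eff
    for (j in seq_len(nt)) {
      amp <- base * prof[, j] * (if (is.matrix(att)) att[, j] else 1)
      expected[, , j] <- expected[, , j] + outer(amp, spec$intensity)
    }
  }
  ti <- ti_amplitude * sin(3 * pi * (radii - radii[1]) /
                             (radii[nr] - radii[1])) +
    beam_drift * (radii - radii[1]) / (radii[nr] - radii[1])
  scans <- with_seed(seed, {
    ri <- if (ri_sd > 0) rnorm(nt, 0, ri_sd) else rep(0, nt)
    out <- vector("list", nt)
    for (j in seq_len(nt)) {
      ne <- expected[, , j, drop = FALSE]
      dim(ne) <- c(nr, nw)
      if (noise) {
        e <- matrix(rpois(nr * nw, as.numeric(ne)), nr, nw) +
          matrix(rnorm(nr * nw, 0, instrument$read_noise_e), nr, nw)
        cnt <- round(e / instrument$adc_gain + ti + ri[j]) +
          instrument$offset_counts
      } else {
        cnt <- ne / instrument$adc_gain + ti + ri[j] +
          instrument$offset_counts
      }
      cnt <- pmin(pmax(cnt, 0), instrument$adc_max)
      out[[j]] <- new_scan(radii, wl, cnt, time = times[j],
                           speed = protocol$speed,
                           exposure = instrument$exposure_ms)
    }
    attr(out, "ri") <- ri
    out
  })
  ri <- attr(scans, "ri"); attr(scans, "ri") <- NULL
  new_scan_set(scans, instrument, protocol, wl,
               ground_truth = list(species = truth_species, ti = ti,
                                   ri = ri, seed = seed, noise = noise))
}
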