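.grating_table <- tibble::tibble(
  lines_mm = c(150, 600, 1800),
  window_lo = c(400, 515, 525),
  window_hi = c(937, 643, 558),
  resolution = c(2.0, 0.51, 0.14) # FWHM, nm
)

# fibre image magnification: a 200 um core maps to a 135 um collection spot
.imaging_magnification <- 0.675

#' Confocal collection geometry from the fibre core
#'
#' The collection spot in the sample is the image of the multi-mode fibre
#' core (fixed imaging magnification 0.675, so a 200 um core gives a
#' 135 um spot, four times the 50 um-core spot). The confocal depth is
#' anchored to the two characterised cores (50 um -> 0.7 mm, 200 um ->
#' 1.5 mm) with linear interpolation in between.
#'
#' @param fiber_core Fibre core diameter in um.
#' @param magnification Imaging magnification from fibre to sample.
#' @return Tibble with `collection_spot` (um) and `confocal_depth` (mm).
#' @export
confocal_geometry <- function(fiber_core, magnification = .imaging_magnification) {
  if (any(fiber_core <= 0)) abort("fibre core diameter must be positive")
  if (!all(fiber_core %in% c(50, 200)))
    warn("confocal depth is characterised for 50 and 200 um cores; interpolating")
  depth <- 0.7 + (fiber_core - 50) * (1.5 - 0.7) / (200 - 50)
  tibble(collection_spot = fiber_core * magnification,
         confocal_depth = pmax(depth, 0.05))
}

#' Rayleigh length of the excitation beam
#'
#' z_R = pi (d/2)^2 / lambda for a Gaussian beam of waist diameter d.
#'
#' @param waist_diameter Beam waist (1/e^2) diameter in um.
#' @param wavelength Wavelength in nm.
#' @return Rayleigh length in mm.
#' @export
rayleigh_length <- function(waist_diameter, wavelength) {
  if (any(waist_diameter <= 0) || any(wavelength <= 0))
    abort("waist diameter and wavelength must be positive")
  w_um <- waist_diameter / 2
  lam_um <- wavelength / 1000
  pi * w_um^2 / lam_um / 1000 # um -> mm
}

#' Instrument model for the multiwavelength emission detector
#'
#' Collects every optics and detector parameter driving the forward model:
#' excitation laser, confocal geometry, grating dispersion and the EMCCD
#' detection chain.
#'
#' @param laser_nm Excitation laser wavelength, 405 or 520 nm.
#' @param laser_spot_diameter Excitation spot 1/e^2 diameter at the sample
#'   (um); sets the radial resolution.
#' @param beam_waist_diameter Laser beam waist diameter (um), for the
#'   Rayleigh-length estimate.
#' @param fiber_core Signal fibre core diameter, 50 or 200 um; sets the
#'   collection spot and confocal depth via [confocal_geometry()].
#' @param grating Grating groove density: 150, 600 or 1800 lines/mm with
#'   spectral windows 400-937, 515-643, 525-558 nm and resolutions 2.0,
#'   0.51, 0.14 nm FWHM on a 1600-pixel sensor.
#' @param read_noise_e Camera read noise, electrons rms (7 at 1 MHz ADC,
#'   4 at 100 kHz).
#' @param adc_gain ADC gain, electrons per count (1 or 4).
#' @param exposure_ms Camera exposure per scan point, <= 500 ms.
#' @param offset_counts Stable electronic offset added to every read.
#' @param cell_depth Optical path (z) depth of the measurement cell, mm.
#' @param z_vacuum_shift Shift of the cell z-position when the chamber is
#'   evacuated (mm); commanded z maps to physical z minus this shift.
#' @param longpass_cutoff Long-pass filter edge (nm); emission below it is
#'   blocked. Default 10 nm above the laser line.
#' @param photons_per_unit Photon budget: expected band-integrated
#'   photoelectrons per unit concentration per ms exposure for a species
#'   at unit excitation efficiency.
#' @return An object of class `mwe_instrument`.
#' @export
instrument_model <- function(laser_nm = 520, laser_spot_diameter = 40,
                             beam_waist_diameter = 35, fiber_core = 200,
                             grating = 150, read_noise_e = 7, adc_gain = 1,
                             exposure_ms = 100, offset_counts = 100,
                             cell_depth = 3, z_vacuum_shift = 2.0,
                             longpass_cutoff = laser_nm + 10,
                             photons_per_unit = 100) {
  if (!grating %in% .grating_table$lines_mm)
    abort("grating must be one of 150, 600, 1800 L/mm")
  if (exposure_ms <= 0 || exposure_ms > 500)
    abort("exposure must be in (0, 500] ms")
  if (read_noise_e < 0 || adc_gain <= 0) abort("invalid detector parameters")
  geo <- confocal_geometry(fiber_core)
  g <- .grating_table[.grating_table$lines_mm == grating, ]
  structure(
    list(laser_nm = laser_nm, laser_spot_diameter = laser_spot_diameter,
         beam_waist_diameter = beam_waist_diameter, fiber_core = fiber_core,
         collection_spot = geo$collection_spot,
         confocal_depth = geo$confocal_depth,
         grating = grating, window = c(g$window_lo, g$window_hi),
         resolution = g$resolution, n_pixels = 1600L,
         read_noise_e = read_noise_e, adc_gain = adc_gain, adc_bits = 16L,
         adc_max = 65535L, exposure_ms = exposure_ms,
         offset_counts = offset_counts, cell_depth = cell_depth,
         z_vacuum_shift = z_vacuum_shift, longpass_cutoff = longpass_cutoff,
         photons_per_unit = photons_per_unit),
    class = "mwe_instrument")
}

#' @export
print.mwe_instrument <- function(x, ...) {
  cat(sprintf(paste0(
    "<mwe_instrument> %g nm laser (spot %g um), fibre %g um ",
    "(collection %g um, depth %g mm)\n  grating %g L/mm: %g-%g nm @ %g nm, ",
    "read %g e-, gain %g e-/count, %g ms\n"),
    x$laser_nm, x$laser_spot_diameter, x$fiber_core, x$collection_spot,
    x$confocal_depth, x$grating, x$window[1], x$window[2], x$resolution,
    x$read_noise_e, x$adc_gain, x$exposure_ms))
  invisible(x)
}

#' Excitation intensity through the cell depth (primary inner filter)
#'
#' Beer-Lambert attenuation of the excitation beam entering the cell at
#' z = 0 (the face nearest the optics): I(z) = 10^(-eps_exc * int_0^z c dz').
#'
#' @param z Depth grid in cm, increasing into the cell from the incident
#'   face.
#' @param conc Concentration at each z.
#' @param eps_exc Decadic attenuation coefficient per unit concentration
#'   per cm at the excitation wavelength.
#' @return Relative intensity I(z), monotone nonincreasing.
#' @export
excitation_profile <- function(z, conc, eps_exc) {
  if (eps_exc < 0) abort("eps_exc must be >= 0")
  if (any(conc < 0)) abort("concentrations must be >= 0")
  if (eps_exc == 0) return(rep(1, length(z)))
  cum <- pracma::cumtrapz(z, conc)
  as.numeric(10^(-eps_exc * cum))
}

#' Escape fraction of emitted light (secondary inner filter)
#'
#' Fraction of fluorescence emitted at depth z that leaves the cell
#' through the incident face without reabsorption:
#' 10^(-eps_em(lambda) * int_0^z c dz').
#'
#' @inheritParams excitation_profile
#' @param eps_em Decadic attenuation coefficient at the emission
#'   wavelength.
#' @return Escape fraction in (0, 1], equal to 1 when `eps_em = 0`.
#' @export
emission_escape <- function(z, conc, eps_em) {
  if (any(eps_em < 0)) abort("eps_em must be >= 0")
  if (any(conc < 0)) abort("concentrations must be >= 0")
  if (all(eps_em == 0)) return(rep(1, length(z)))
  cum <- pracma::cumtrapz(z, conc)
  as.numeric(10^(-eps_em * cum))
}

#' Disperse an emission spectrum onto the sensor
#'
#' Maps spectral density onto the active grating's 1600-pixel window and
#' blurs with a Gaussian kernel of the grating's resolution (FWHM). Total
#' intensity is conserved up to truncation at the window edges; emission
#' below the long-pass cutoff is blocked.
#'
#' @param emission Data frame with columns `wavelength` (nm), `intensity`.
#' @param instrument An [instrument_model()].
#' @param wavelengths Optional output wavelength grid (nm); defaults to
#'   the full 1600-pixel grid of the active grating.
#' @return Tibble with `wavelength` (pixel/bin centre, nm) and `intensity`
#'   (expected fraction of the input intensity landing in each bin).
#' @export
disperse_spectrum <- function(emission, instrument = instrument_model(),
                              wavelengths = NULL) {
  em <- as_tibble(emission)
  win <- instrument$window
  if (is.null(wavelengths)) {
    pitch <- diff(win) / instrument$n_pixels
    wavelengths <- seq(win[1] + pitch / 2, win[2] - pitch / 2,
                       length.out = instrument$n_pixels)
  }
  if (any(wavelengths < win[1] - 1e-9) || any(wavelengths > win[2] + 1e-9))
    abort("requested wavelengths fall outside the grating window")
  step <- if (length(wavelengths) > 1) diff(wavelengths[1:2]) else
    diff(win)
  keep <- em$wavelength >= instrument$longpass_cutoff
  total <- sum(em$intensity)
  if (total > 0 &&
      sum(em$intensity[keep & em$wavelength >= win[1] &
                         em$wavelength <= win[2]]) < 0.999 * total)
    warn("part of the emission spectrum falls outside the grating window or below the long-pass cutoff; it is truncated")
  em <- em[keep, , drop = FALSE]
  sigma <- instrument$resolution / (2 * sqrt(2 * log(2)))
  edges <- c(wavelengths - step / 2, wavelengths[length(wavelengths)] + step / 2)
  out <- numeric(length(wavelengths))
  if (nrow(em) > 0 && sum(em$intensity) > 0) {
    # distribute each spectral sample over bins with the resolution kernel
    cdf <- stats::pnorm(outer(edges, em$wavelength, "-") / sigma)
    frac <- cdf[-1, , drop = FALSE] - cdf[-nrow(cdf), , drop = FALSE]
    out <- as.numeric(frac %*% em$intensity)
  }
  tibble(wavelength = wavelengths, intensity = out)
}

#' EMCCD detection of expected photoelectrons
#'
#' Applies Poisson shot noise, Gaussian read noise, ADC gain, the stable
#' electronic offset and 16-bit clipping:
#' counts = clip(round((Pois(Ne) + N(0, sigma_read)) / gain) + offset,
#' 0, 65535). Dark current is neglected (exposures <= 500 ms).
#'
#' @param ne Expected photoelectrons (any shape; vectorised).
#' @param instrument An [instrument_model()].
#' @param noise If `FALSE`, return the noise-free mean response
#'   (ne / gain + offset, clipped) without rounding.
#' @return Counts with the same shape as `ne`.
#' @export
detect <- function(ne, instrument = instrument_model(), noise = TRUE) {
  if (any(ne < 0)) abort("expected photoelectrons must be >= 0")
  g <- instrument$adc_gain
  if (!noise) {
    out <- ne / g + instrument$offset_counts
  } else {
    n <- length(ne)
    e <- rpois(n, as.numeric(ne)) + rnorm(n, 0, instrument$read_noise_e)
    out <- round(e / g) + instrument$offset_counts
  }
  out <- pmin(pmax(out, 0), instrument$adc_max)
  if (is.matrix(ne)) out <- matrix(out, nrow(ne), ncol(ne),
                                   dimnames = dimnames(ne))
  out
}
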