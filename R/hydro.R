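#' Define a sedimenting fluorescent species
#'
#' A species couples hydrodynamics (sedimentation coefficient, frictional
#' ratio, partial specific volume) to an emission spectrum and to the
#' attenuation coefficients that drive inner-filter effects.
#'
#' @param name Label.
#' @param s Sedimentation coefficient in Svedberg (1 S = 1e-13 s).
#' @param ff0 Frictional ratio f/f0 (>= 1, 1 for a compact sphere).
#' @param vbar Partial specific volume in cm^3/g.
#' @param c0 Loading concentration in arbitrary signal-equivalent units.
#' @param emission Data frame with columns `wavelength` (nm) and `intensity`
#'   (relative emission density). Normalised internally to unit area on its
#'   grid. Defaults to a Gaussian band via [gaussian_emission()].
#' @param exc_eff Relative excitation efficiency at the laser line (0-1).
#' @param eps_exc Decadic attenuation coefficient at the excitation
#'   wavelength, per unit concentration per cm (drives the primary
#'   inner-filter effect).
#' @param eps_em Either a single number, or a function of wavelength (nm),
#'   giving the decadic attenuation coefficient at emission wavelengths
#'   (secondary inner-filter effect). Default 0.
#' @return An object of class `mwe_species`.
#' @examples
#' sp <- species("GFP-like", s = 2.8, ff0 = 1.2, vbar = 0.73, c0 = 1,
#'               emission = gaussian_emission(511, fwhm = 35))
#' @export
species <- function(name, s, ff0 = 1.2, vbar = 0.73, c0 = 1,
                    emission = gaussian_emission(550, fwhm = 50),
                    exc_eff = 1, eps_exc = 0, eps_em = 0) {
  stopifnot(is.numeric(s), length(s) == 1L)
  if (s < 0) abort("sedimentation coefficient must be >= 0")
  if (ff0 < 1) abort("frictional ratio f/f0 must be >= 1")
  if (vbar <= 0 || vbar >= 1.2) abort("vbar must lie in (0, 1.2) cm^3/g")
  if (c0 < 0) abort("loading concentration must be >= 0")
  if (exc_eff < 0 || exc_eff > 1) abort("exc_eff must be in [0, 1]")
  if (eps_exc < 0) abort("eps_exc must be >= 0")
  em <- as_tibble(emission)
  if (!all(c("wavelength", "intensity") %in% names(em)))
    abort("emission must have columns wavelength, intensity")
  if (any(em$intensity < 0)) abort("emission intensities must be >= 0")
  area <- sum(em$intensity)
  if (area <= 0) abort("emission spectrum must have positive area")
  em$intensity <- em$intensity / area
  eps_fun <- if (is.function(eps_em)) eps_em else {
    if (any(eps_em < 0)) abort("eps_em must be >= 0")
    e <- eps_em
    function(wl) rep_len(e, length(wl))
  }
  structure(
    list(name = name, s = s, ff0 = ff0, vbar = vbar, c0 = c0,
         emission = em, exc_eff = exc_eff, eps_exc = eps_exc,
         eps_em = eps_fun),
    class = "mwe_species")
}

#' Gaussian emission band
#'
#' @param center Peak wavelength (nm).
#' @param fwhm Full width at half maximum (nm).
#' @param range Wavelength range covered (nm).
#' @param step Grid step (nm).
#' @return Tibble with columns `wavelength`, `intensity` (unit area).
#' @export
gaussian_emission <- function(center, fwhm = 50,
                              range = center + c(-3, 3) * fwhm, step = 1) {
  wl <- seq(range[1], range[2], by = step)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  tibble(wavelength = wl,
         intensity = exp(-0.5 * ((wl - center) / sigma)^2))
}

#' @export
print.mwe_species <- function(x, ...) {
  cat(sprintf("<mwe_species> %s: s = %g S, f/f0 = %g, vbar = %g cm^3/g, c0 = %g\n",
              x$name, x$s, x$ff0, x$vbar, x$c0))
  invisible(x)
}

#' Solvent model
#'
#' @param density Solvent density in g/cm^3.
#' @param viscosity Solvent viscosity in mPa s (1 mPa s = 0.01 poise).
#'   The default 1.002 mPa s is water at 20 degrees C.
#' @param temperature Temperature in K.
#' @return An object of class `mwe_solvent`.
#' @export
solvent <- function(density = 1.000, viscosity = 1.002,
                    temperature = 293.15) {
  if (density <= 0 || viscosity <= 0 || temperature <= 0)
    abort("solvent parameters must be positive")
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature),
            class = "mwe_solvent")
}

#' @export
print.mwe_solvent <- function(x, ...) {
  cat(sprintf("<mwe_solvent> rho = %g g/cm^3, eta = %g mPa s, T = %g K\n",
              x$density, x$viscosity, x$temperature))
  invisible(x)
}

buoyancy <- function(vbar, solv) 1 - vbar * solv$density

#' Rotor and scan protocol
#'
#' @param speed Rotor speed in rpm.
#' @param meniscus Air/solution interface radius in cm.
#' @param bottom Cell bottom radius in cm.
#' @param radial_step Radial scan step in micrometres.
#' @param scan_interval Time between scans in seconds.
#' @param n_scans Number of scans.
#' @param start_delay Time of the first scan after speed is reached (s).
#' @return An object of class `mwe_protocol` with the derived angular
#'   velocity `omega` (rad/s), scan `times` (s) and radial grid (cm).
#' @export
rotor_protocol <- function(speed = 40000, meniscus = 6.0, bottom = 7.2,
                           radial_step = 50, scan_interval = 90,
                           n_scans = 100, start_delay = 0) {
  if (speed <= 0) abort("rotor speed must be positive")
  if (meniscus >= bottom) abort("meniscus must lie inside the bottom radius")
  if (radial_step <= 0) abort("radial step must be positive")
  omega <- 2 * pi * speed / 60
  h <- radial_step * 1e-4 # um -> cm
  radii <- seq(meniscus, bottom, by = h)
  times <- start_delay + scan_interval * seq_len(n_scans)
  structure(list(speed = speed, omega = omega, meniscus = meniscus,
                 bottom = bottom, radial_step = radial_step,
                 scan_interval = scan_interval, n_scans = n_scans,
                 start_delay = start_delay, radii = radii, times = times),
            class = "mwe_protocol")
}

#' @export
print.mwe_protocol <- function(x, ...) {
  cat(sprintf("<mwe_protocol> %g rpm, r = [%g, %g] cm @ %g um, %d scans every %g s\n",
              x$speed, x$meniscus, x$bottom, x$radial_step, x$n_scans,
              x$scan_interval))
  invisible(x)
}

#' Molar mass from the Svedberg relation
#'
#' M = s R T / (D (1 - vbar rho)).
#'
#' @param s Sedimentation coefficient in Svedberg.
#' @param D Diffusion coefficient in cm^2/s.
#' @param vbar Partial specific volume in cm^3/g.
#' @param solv A [solvent()].
#' @return Molar mass in kg/mol.
#' @export
svedberg_mass <- function(s, D, vbar, solv = solvent()) {
  if (any(D <= 0)) abort("D must be positive")
  b <- buoyancy(vbar, solv)
  if (any(abs(b) < 1e-12))
    abort("neutral buoyancy: 1 - vbar * rho = 0, molar mass undefined")
  # D cm^2/s -> m^2/s
  (s * 1e-13) * .R_gas * solv$temperature / (D * 1e-4 * b)
}

#' Diffusion coefficient implied by (s, f/f0, vbar)
#'
#' The scaling used by c(s) analysis: the Stokes radius of the equivalent
#' compact sphere follows from s, vbar and f/f0, and D = kT / (6 pi eta
#' f/f0 R0), giving D proportional to s^(-1/2).
#'
#' @inheritParams svedberg_mass
#' @param ff0 Frictional ratio.
#' @return Diffusion coefficient in cm^2/s.
#' @export
diffusion_from_s <- function(s, ff0, vbar, solv = solvent()) {
  if (any(s <= 0)) abort("s must be positive")
  if (any(ff0 < 1)) abort("f/f0 must be >= 1")
  b <- buoyancy(vbar, solv)
  if (any(b <= 0))
    abort("1 - vbar * rho must be positive (species would float)")
  eta <- solv$viscosity * 0.01 # mPa s -> poise (g/cm/s)
  s_sec <- s * 1e-13
  r0 <- sqrt(4.5 * s_sec * eta * ff0 * vbar / b) # cm
  .kB_erg * solv$temperature / (6 * pi * eta * ff0 * r0)
}

#' Diffusion-free boundary position
#'
#' Radius of an ideal (D = 0) sedimentation boundary, r_m exp(s w^2 t).
#'
#' @param s Sedimentation coefficient in Svedberg.
#' @param omega Angular velocity in rad/s.
#' @param meniscus Meniscus radius in cm.
#' @param t Time in s (vectorised).
#' @return Boundary radius in cm.
#' @export
faxen_boundary <- function(s, omega, meniscus, t) {
  if (any(s < 0) || any(t < 0)) abort("s and t must be >= 0")
  meniscus * exp(s * 1e-13 * omega^2 * t)
}

#' Plateau dilution factor
#'
#' Square-dilution rule for sector-shaped cells: the plateau concentration
#' decays as exp(-2 s w^2 t) as the boundary moves outward.
#'
#' @inheritParams faxen_boundary
#' @return Dilution factor in (0, 1].
#' @export
radial_dilution <- function(s, omega, t) {
  if (any(s < 0) || any(t < 0)) abort("s and t must be >= 0")
  exp(-2 * s * 1e-13 * omega^2 * t)
}

# Bernoulli function x / (exp(x) - 1) of the Scharfetter-Gummel flux,
# numerically safe near 0.
.bernoulli <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-10
  out[small] <- 1 - x[small] / 2
  xs <- x[!small]
  out[!small] <- xs / expm1(xs)
  out
}

# Finite-volume transport operator L with dc/dt = L c for the Lamm equation
# in sector geometry, exponential-fitted (Scharfetter-Gummel) fluxes,
# closed boundaries. r: cell-centre radii (uniform step h).
.lamm_operator <- function(r, h, s_sec, omega, D) {
  n <- length(r)
  rf <- (r[-n] + r[-1]) / 2            # interior face radii
  v <- s_sec * omega^2 * rf            # sedimentation velocity at faces
  if (D > 0) {
    pe <- v * h / D
    bm <- .bernoulli(-pe)              # multiplies left cell
    bp <- .bernoulli(pe)               # multiplies right cell
    fl <- (D / h) * bm                 # J = fl*c_i - fr*c_{i+1}
    fr <- (D / h) * bp
  } else {
    fl <- pmax(v, 0)
    fr <- pmax(-v, 0)
  }
  L <- matrix(0, n, n)
  # face k sits between cells k and k+1; flux J_k = fl[k] c_k - fr[k] c_{k+1}
  # dc_i/dt = -(rf_i J_i - rf_{i-1} J_{i-1}) / (r_i h)
  for (k in seq_len(n - 1)) {
    a <- rf[k] / (r[k] * h)
    b <- rf[k] / (r[k + 1] * h)
    L[k, k]         <- L[k, k]         - a * fl[k]
    L[k, k + 1]     <- L[k, k + 1]     + a * fr[k]
    L[k + 1, k]     <- L[k + 1, k]     + b * fl[k]
    L[k + 1, k + 1] <- L[k + 1, k + 1] - b * fr[k]
  }
  L
}

#' Solve the Lamm equation in a sector-shaped cell
#'
#' Finite-volume discretisation with exponential-fitted (upwind-stable)
#' fluxes and an implicit theta time step, closed boundaries at meniscus
#' and bottom, uniform initial loading. Sector mass is conserved to
#' machine precision by construction.
#'
#' @param sp A [species()] (only `s`, `ff0`, `vbar`, `c0` are used), or a
#'   list with those fields.
#' @param solv A [solvent()].
#' @param protocol A [rotor_protocol()].
#' @param times Output times in s; defaults to `protocol$times`.
#' @param D Diffusion coefficient in cm^2/s; by default derived from the
#'   species via [diffusion_from_s()]. `D = 0` gives the ideal
#'   (diffusion-free) boundary.
#' @param theta Implicitness of the time step (1 = backward Euler, the
#'   default, monotone; 0.5 = Crank-Nicolson).
#' @param courant Target advective Courant number controlling the internal
#'   time step.
#' @return Tibble with columns `time`, `radius`, `conc`.
#' @export
solve_lamm <- function(sp, solv = solvent(), protocol = rotor_protocol(),
                       times = NULL, D = NULL, theta = 1, courant = 0.4) {
  times <- times %||% protocol$times
  times <- sort(unique(times))
  if (any(times < 0)) abort("times must be >= 0")
  r <- protocol$radii
  n <- length(r)
  if (n < 20)
    abort(paste0("radial grid too coarse for a stable Lamm solution (",
                 n, " points); refine the radial step"))
  h <- r[2] - r[1]
  s_sec <- sp$s * 1e-13
  if (is.null(D)) {
    D <- if (sp$s > 0) diffusion_from_s(sp$s, sp$ff0, sp$vbar, solv) else 1e-7
  }
  if (D < 0) abort("D must be >= 0")
  omega <- protocol$omega
  L <- .lamm_operator(r, h, s_sec, omega, D)
  vmax <- s_sec * omega^2 * r[n]
  dt_adv <- if (vmax > 0) courant * h / vmax else Inf
  dt_dif <- if (D > 0) 5 * h^2 / D else Inf # implicit: diffusion not limiting
  dt <- min(dt_adv, dt_dif, if (length(times) > 1) min(diff(times)) else Inf,
            max(times[times > 0], 1))
  if (!is.finite(dt)) dt <- max(times, 1)
  Ienty <- diag(n)
  A1 <- Ienty - dt * theta * L
  A0 <- Ienty + dt * (1 - theta) * L
  P <- solve(A1, A0) # one-step propagator
  conc <- rep(sp$c0, n)
  out <- matrix(NA_real_, n, length(times))
  t_now <- 0
  for (j in seq_along(times)) {
    target <- times[j]
    nstep <- floor((target - t_now) / dt + 1e-9)
    if (nstep > 0) for (k in seq_len(nstep)) conc <- P %*% conc
    t_now <- t_now + nstep * dt
    rem <- target - t_now
    cj <- conc
    if (rem > 1e-9) {
      Ar <- solve(Ienty - rem * theta * L, Ienty + rem * (1 - theta) * L)
      cj <- Ar %*% conc
      conc <- cj
      t_now <- target
    }
    out[, j] <- pmax(as.numeric(cj), 0)
  }
  tibble(time = rep(times, each = n),
         radius = rep(r, length(times)),
         conc = as.numeric(out))
}

# matrix of profiles (radius x time) from the tidy solve_lamm output
profiles_matrix <- function(lamm_tbl) {
  times <- unique(lamm_tbl$time)
  radii <- unique(lamm_tbl$radius)
  matrix(lamm_tbl$conc, nrow = length(radii), ncol = length(times))
}

#' Sector mass of a radial concentration profile
#'
#' Integral of c(r) r dr, proportional to the amount of solute in a
#' sector-shaped cell; used to check conservation. On a uniform grid the
#' midpoint (finite-volume) rule is used, matching the solver's discrete
#' conservation law; otherwise the trapezoid rule.
#'
#' @param radius,conc Radial grid (cm) and concentrations.
#' @return The sector integral.
#' @export
sector_mass <- function(radius, conc) {
  h <- diff(radius)
  if (diff(range(h)) < 1e-9 * h[1]) sum(conc * radius) * h[1]
  else pracma::trapz(radius, conc * radius)
}
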