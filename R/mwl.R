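# ---- 2D sedimentation-coefficient x wavelength analysis ---------------

#' Consecutive per-wavelength c(s) fits assembled into a 2D distribution
#'
#' Runs the regularized c(s) inversion independently for every analysed
#' emission wavelength with one shared Lamm kernel (identical
#' hydrodynamic parameters across wavelengths, so the kernel is computed
#' once). The result is the sedimentation-coefficient versus
#' emission-wavelength distribution c(s, lambda).
#'
#' @param scanset An `mwe_scan_set`.
#' @param config An [fit_config()]; `vbar`/`ff0` are shared across all
#'   wavelengths.
#' @param lambda_step Analysis wavelength step in nm (default 1.5); the
#'   dataset's wavelength grid is subsampled to at least this step.
#' @param wavelengths Explicit wavelengths to analyse (overrides
#'   `lambda_step`).
#' @param solv A [solvent()].
#' @return An object of class `mwe_c2d`.
#' @export
fit_cs_lambda <- function(scanset, config = fit_config(),
                          lambda_step = 1.5, wavelengths = NULL,
                          solv = solvent()) {
  wl_all <- scanset$wavelength
  if (is.null(wavelengths)) {
    stride <- max(1L, round(lambda_step /
                              (if (length(wl_all) > 1) diff(wl_all[1:2]) else lambda_step)))
    wavelengths <- wl_all[seq(1, length(wl_all), by = stride)]
  } else {
    wavelengths <- wl_all[unique(vapply(wavelengths, function(w)
      which.min(abs(wl_all - w)), integer(1)))]
  }
  if (length(wavelengths) == 0) abort("empty wavelength selection")
  protocol <- scanset$protocol
  slice0 <- scan_slice(scanset, wavelengths[1])
  win <- default_window(protocol, config$window)
  keep <- slice0$radii >= win[1] & slice0$radii <= win[2]
  kernel <- build_lamm_kernel(config$s_grid, config$ff0, config$vbar,
                              solv, protocol, slice0$radii[keep],
                              slice0$times)
  fits <- purrr::map(wavelengths, function(w)
    fit_cs(scan_slice(scanset, w), kernel, config))
  A <- vapply(fits, function(f) f$distribution$c,
              numeric(length(config$s_grid)))
  structure(
    list(s_grid = config$s_grid, wavelength = wavelengths,
         amplitude = A,
         per_lambda = tibble(wavelength = wavelengths,
                             rmsd = purrr::map_dbl(fits, "rmsd"),
                             alpha = purrr::map_dbl(fits, "alpha")),
         fits = fits, config = config,
         kernel_meta = list(ff0 = config$ff0, vbar = config$vbar,
                            meniscus = protocol$meniscus)),
    class = "mwe_c2d")
}

#' @export
print.mwe_c2d <- function(x, ...) {
  cat(sprintf("<mwe_c2d> %d s-values x %d wavelengths (%g-%g nm), shared vbar %g\n",
              length(x$s_grid), length(x$wavelength), min(x$wavelength),
              max(x$wavelength), x$kernel_meta$vbar))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mwe_c2d <- function(x, ...) {
  tibble(s = rep(x$s_grid, times = length(x$wavelength)),
         wavelength = rep(x$wavelength, each = length(x$s_grid)),
         amplitude = as.numeric(x$amplitude))
}

#' @exportS3Method generics::glance
glance.mwe_c2d <- function(x, ...) {
  tibble(n_s = length(x$s_grid), n_wavelengths = length(x$wavelength),
         rmsd_mean = mean(x$per_lambda$rmsd),
         total_signal = sum(x$amplitude),
         vbar = x$kernel_meta$vbar, ff0 = x$kernel_meta$ff0)
}

# quadratic sub-grid interpolation of a discrete maximum
.quad_peak <- function(xg, y) {
  j <- which.max(y)
  if (j == 1 || j == length(y)) return(xg[j])
  denom <- y[j - 1] - 2 * y[j] + y[j + 1]
  if (denom >= 0) return(xg[j])
  xg[j] + 0.5 * (xg[j] - xg[j - 1]) * (y[j - 1] - y[j + 1]) / denom
}

#' Extract discrete species from a 2D distribution
#'
#' Peaks are found on the wavelength-integrated c(s); each contiguous
#' above-threshold region of the s-grid is one species, its emission
#' spectrum the amplitude slice summed over the region's s-support, and
#' its emission maximum located by quadratic interpolation around the
#' spectral maximum.
#'
#' @param c2d An `mwe_c2d`.
#' @param threshold Peak threshold as a fraction of the global maximum of
#'   the integrated c(s) (default 0.05).
#' @return Tibble with one row per species: `s` (weighted mean), `s_lo`,
#'   `s_hi`, `lambda_max` (nm), `abundance` (fraction of total signal)
#'   and a `spectrum` list-column of tibbles. Empty when nothing exceeds
#'   the threshold.
#' @export
extract_species <- function(c2d, threshold = 0.05) {
  cs <- rowSums(c2d$amplitude)
  pk <- peak_table(tibble(s = c2d$s_grid, c = cs), threshold)
  if (nrow(pk) == 0)
    return(tibble(s = numeric(), s_lo = numeric(), s_hi = numeric(),
                  lambda_max = numeric(), abundance = numeric(),
                  spectrum = list()))
  total <- sum(c2d$amplitude)
  purrr::pmap_dfr(pk, function(s_peak, amplitude, s_lo, s_hi) {
    i <- which(c2d$s_grid >= s_lo & c2d$s_grid <= s_hi)
    spec <- colSums(c2d$amplitude[i, , drop = FALSE])
    tibble(s = s_peak, s_lo = s_lo, s_hi = s_hi,
           lambda_max = .quad_peak(c2d$wavelength, spec),
           abundance = amplitude / total,
           spectrum = list(tibble(wavelength = c2d$wavelength,
                                  intensity = spec)))
  })
}

# ---- discrete-species global fit --------------------------------------

#' Global discrete-species fit across wavelengths
#'
#' Fits K discrete sedimentation coefficients shared across the selected
#' emission wavelengths; per-wavelength signal amplitudes are linear
#' parameters (nonnegative least squares with per-wavelength TI/RI noise
#' elimination), the shared s values nonlinear (Nelder-Mead on log s).
#' Initialised from [extract_species()] of a coarse 2D analysis unless
#' start values are given.
#'
#' @param scanset An `mwe_scan_set`.
#' @param k Number of discrete species (>= 1).
#' @param wavelengths Emission wavelengths (nm) included in the global
#'   fit.
#' @param s_init Optional start values (S), length `k`.
#' @param ff0,vbar Shared hydrodynamic parameters.
#' @param fit_ti,fit_ri Noise components eliminated per wavelength.
#' @param window Radial analysis window (cm).
#' @param solv A [solvent()].
#' @return List with `s` (fitted values, sorted), `amplitudes`
#'   (wavelength x species tibble), `rmsd`, `s_init` and `convergence`.
#'   Near-degenerate fitted s values (within 1%) are flagged with a
#'   warning.
#' @export
global_species_fit <- function(scanset, k, wavelengths, s_init = NULL,
                               ff0 = 1.2, vbar = 0.73, fit_ti = TRUE,
                               fit_ri = TRUE, window = NULL,
                               solv = solvent()) {
  if (k < 1) abort("k must be >= 1")
  protocol <- scanset$protocol
  slices <- purrr::map(wavelengths, function(w) scan_slice(scanset, w))
  win <- default_window(protocol, window)
  radii0 <- slices[[1]]$radii
  keep <- radii0 >= win[1] & radii0 <= win[2]
  radii <- radii0[keep]
  times <- slices[[1]]$times
  Ys <- purrr::map(slices, function(sl) sl$Y[keep, , drop = FALSE])
  nr <- length(radii); nt <- length(times)

  if (is.null(s_init)) {
    tot <- Reduce(`+`, Ys)
    cfg <- fit_config(s_min = 0.3, s_max = 30, n_s = 60, ff0 = ff0,
                      vbar = vbar, fit_ti = fit_ti, fit_ri = fit_ri)
    kern <- build_lamm_kernel(cfg$s_grid, ff0, vbar, solv, protocol,
                              radii, times)
    f0 <- fit_cs(list(radii = radii, times = times, Y = tot), kern, cfg)
    # start values at the mass quantiles of the integrated c(s): robust
    # when peaks are merged or partially resolved
    cc <- f0$distribution$c
    if (sum(cc) <= 0) abort("no signal: cannot initialise the global fit")
    cum <- cumsum(cc) / sum(cc)
    s_init <- vapply((seq_len(k) - 0.5) / k, function(p)
      f0$distribution$s[which(cum >= p)[1]], numeric(1))
  }
  if (length(s_init) != k) abort("s_init must have length k")

  rss_of <- function(svec) {
    kern <- build_lamm_kernel(svec, ff0, vbar, solv, protocol, radii,
                              times)
    Kp <- apply(kern$K, 2, function(col)
      as.numeric(project_noise(matrix(col, nr, nt), fit_ti, fit_ri)))
    Kp <- matrix(Kp, nr * nt, k)
    G <- crossprod(Kp)
    amps <- matrix(0, length(wavelengths), k)
    rss <- 0
    for (j in seq_along(wavelengths)) {
      yp <- as.numeric(project_noise(Ys[[j]], fit_ti, fit_ri))
      b <- as.numeric(crossprod(Kp, yp))
      sol <- nnls_compressed(G, b, sum(yp^2))
      amps[j, ] <- sol$c
      rss <- rss + sol$rss
    }
    list(rss = rss, amps = amps)
  }
  obj <- function(logs) rss_of(exp(logs))$rss
  if (k == 1) {
    opt <- optimize(function(x) obj(log(x)),
                    interval = s_init * c(0.5, 2))
    s_fit <- opt$minimum; conv <- 0
  } else {
    opt <- optim(log(s_init), obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-8))
    s_fit <- exp(opt$par); conv <- opt$convergence
  }
  ord <- order(s_fit)
  s_fit <- s_fit[ord]
  final <- rss_of(s_fit)
  if (k > 1 && any(diff(s_fit) / s_fit[-k] < 0.01))
    warn("near-degenerate fitted s values: k may exceed the number of identifiable species")
  amps <- as_tibble(final$amps[, ord, drop = FALSE],
                    .name_repair = ~ paste0("s", seq_len(k)))
  amps <- dplyr::mutate(amps, wavelength = wavelengths, .before = 1)
  list(s = s_fit, amplitudes = amps,
       rmsd = sqrt(final$rss / (nr * nt * length(wavelengths))),
       s_init = sort(s_init), convergence = conv)
}
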