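# ---- configuration ----------------------------------------------------

#' Configuration for c(s) inversion
#'
#' @param s_min,s_max Bounds of the sedimentation-coefficient grid (S).
#' @param n_s Number of grid values (default 150), log-spaced.
#' @param regularization `"second_derivative"` (Tikhonov on the second
#'   difference) or `"maximum_entropy"`.
#' @param confidence Confidence level of the one-sided F-statistic bound
#'   used to pick the regularization strength (default 0.683, one sigma).
#' @param fit_ti,fit_ri Eliminate time-invariant (fixed radial pattern)
#'   and radial-invariant (per-scan offset) noise algebraically.
#' @param ff0 Frictional ratio shared by all kernel columns.
#' @param vbar Partial specific volume shared by all kernel columns.
#' @param float One of `"none"`, `"meniscus"`, `"ff0"`, `"vbar"`: the
#'   nonlinear parameter optimised by [optimize_nonlinear()]. Only one of
#'   ff0/vbar may float.
#' @param float_start Start value for the floated parameter (e.g. 0.4 for
#'   vbar of dense nanoparticles).
#' @param window Radial analysis window `c(lo, hi)` in cm; by default the
#'   full column minus the last 0.1 mm at the bottom (the back-diffusion
#'   spike is physical but poorly described by c(s)).
#' @return An object of class `mwe_fit_config`.
#' @export
fit_config <- function(s_min = 0.5, s_max = 15, n_s = 150,
                       regularization = c("second_derivative",
                                          "maximum_entropy"),
                       confidence = 0.683, fit_ti = TRUE, fit_ri = TRUE,
                       ff0 = 1.2, vbar = 0.73,
                       float = c("none", "meniscus", "ff0", "vbar"),
                       float_start = NULL, window = NULL) {
  regularization <- match.arg(regularization)
  float <- match.arg(float)
  if (s_min <= 0 || s_max <= s_min) abort("need 0 < s_min < s_max")
  if (confidence <= 0 || confidence >= 1) abort("confidence must be in (0,1)")
  structure(
    list(s_grid = exp(seq(log(s_min), log(s_max), length.out = n_s)),
         regularization = regularization, confidence = confidence,
         fit_ti = fit_ti, fit_ri = fit_ri, ff0 = ff0, vbar = vbar,
         float = float, float_start = float_start, window = window),
    class = "mwe_fit_config")
}

default_window <- function(protocol, window = NULL) {
  window %||% c(protocol$meniscus, protocol$bottom - 0.01)
}

# ---- kernel -----------------------------------------------------------

#' Build the Lamm-solution design matrix for c(s) inversion
#'
#' One column per s-grid value: the unit-loading Lamm solution with the
#' diffusion coefficient implied by the shared frictional ratio and
#' partial specific volume, evaluated at the analysis radii and scan
#' times. The kernel is independent of emission wavelength and is cached
#' and shared across all per-wavelength fits.
#'
#' @param s_grid Sedimentation coefficients (S).
#' @param ff0,vbar Shared hydrodynamic parameters.
#' @param solv A [solvent()].
#' @param protocol A [rotor_protocol()]; its meniscus/bottom and radial
#'   step define the solver grid.
#' @param radii Analysis radii (cm) the columns are interpolated onto.
#' @param times Scan times (s).
#' @return An object of class `mwe_kernel` holding the design matrix `K`
#'   (stacked time blocks of radii) and its geometry.
#' @export
build_lamm_kernel <- function(s_grid, ff0, vbar, solv, protocol, radii,
                              times) {
  win <- range(radii)
  if (win[1] < protocol$meniscus - 1e-9 || win[2] > protocol$bottom + 1e-9)
    abort("analysis radii fall outside [meniscus, bottom]")
  nr <- length(radii); nt <- length(times)
  K <- matrix(0, nr * nt, length(s_grid))
  for (i in seq_along(s_grid)) {
    sp <- list(s = s_grid[i], ff0 = ff0, vbar = vbar, c0 = 1)
    sol <- solve_lamm(sp, solv, protocol, times = times)
    prof <- profiles_matrix(sol)
    grid_r <- protocol$radii
    col <- matrix(0, nr, nt)
    for (j in seq_len(nt))
      col[, j] <- approx(grid_r, prof[, j], xout = radii, rule = 2)$y
    K[, i] <- as.numeric(col)
  }
  structure(list(K = K, s_grid = s_grid, radii = radii, times = times,
                 ff0 = ff0, vbar = vbar, meniscus = protocol$meniscus,
                 protocol = protocol, solv = solv),
            class = "mwe_kernel")
}

# remove the TI/RI noise subspace from a radius x time matrix by centering
project_noise <- function(M, fit_ti, fit_ri) {
  if (fit_ti && fit_ri) {
    M - rowMeans(M) - rep(colMeans(M), each = nrow(M)) + mean(M)
  } else if (fit_ti) {
    M - rowMeans(M)
  } else if (fit_ri) {
    M - rep(colMeans(M), each = nrow(M))
  } else M
}

second_diff_matrix <- function(n) {
  if (n < 3) return(matrix(0, 0, n))
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}

# nonnegative least squares on compressed normal equations
# min ||y - K c||^2 + alpha ||L c||^2 given G = K'K, b = K'y
nnls_compressed <- function(G, b, yty, alpha = 0, LtL = NULL) {
  Ga <- G
  if (alpha > 0 && !is.null(LtL)) Ga <- Ga + alpha * LtL
  jit <- 1e-10 * mean(diag(Ga))
  R <- tryCatch(chol(Ga + diag(jit, nrow(Ga))),
                error = function(e)
                  abort("singular design: kernel columns are linearly dependent or all-zero; narrow the s-grid or analysis window"))
  d <- backsolve(R, b, transpose = TRUE)
  x <- pracma::lsqnonneg(R, d)$x
  x <- pmax(x, 0)
  # polish on the active set: one exact least-squares solve removes the
  # round-off incurred by the normal-equation compression
  act <- which(x > 0)
  if (length(act) > 0) {
    xa <- tryCatch(solve(Ga[act, act, drop = FALSE], b[act]),
                   error = function(e) NULL)
    if (!is.null(xa) && all(xa >= 0)) x[act] <- xa
  }
  rss <- max(yty - 2 * sum(b * x) + sum(x * (G %*% x)), 0)
  list(c = x, rss = rss)
}

# maximum-entropy solution: min rss/2 + alpha * sum(c log(c/m) - c + m)
maxent_solve <- function(G, b, yty, alpha, prior) {
  n <- length(b)
  obj <- function(c) {
    0.5 * (yty - 2 * sum(b * c) + sum(c * (G %*% c))) +
      alpha * sum(c * log(c / prior) - c + prior)
  }
  grad <- function(c) as.numeric(G %*% c - b) + alpha * log(c / prior)
  fit <- optim(rep(max(prior, 1e-8), n), obj, grad, method = "L-BFGS-B",
               lower = 1e-12, control = list(maxit = 500))
  x <- pmax(fit$par, 0)
  rss <- max(yty - 2 * sum(b * x) + sum(x * (G %*% x)), 0)
  list(c = x, rss = rss)
}

#' Choose the regularization strength by the F-ratio criterion
#'
#' Finds the largest penalty weight whose residual sum of squares stays
#' within the one-sided F-statistic bound relative to the unregularized
#' best fit: rss(alpha) <= rss0 * qf(confidence, df, df) with df the
#' number of fitted data points (one-sigma convention for confidence
#' 0.683). Bisection on log(alpha).
#'
#' @param rss_fun Function of alpha returning the data residual sum of
#'   squares of the regularized fit.
#' @param confidence Confidence level in (0, 1).
#' @param rss0 Unregularized residual sum of squares.
#' @param df Effective degrees of freedom (number of data points).
#' @param tol Relative tolerance on alpha.
#' @param max_iter Maximum bisection iterations.
#' @return The selected penalty weight (0 when the data are fit exactly).
#' @export
select_regularization <- function(rss_fun, confidence, rss0, df,
                                  tol = 1e-3, max_iter = 50) {
  if (rss0 <= 0 || !is.finite(rss0)) return(0)
  bound <- rss0 * qf(confidence, df, df)
  lo <- rss0 * 1e-9
  if (rss_fun(lo) > bound) return(0)
  hi <- lo
  for (k in 1:60) {
    hi <- hi * 10
    if (rss_fun(hi) > bound) break
    if (k == 60) return(hi)
  }
  for (k in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    if (rss_fun(mid) <= bound) lo <- mid else hi <- mid
    if (hi / lo < 1 + tol) break
  }
  lo
}

# ---- the fit ----------------------------------------------------------

#' Regularized c(s) fit of a single-wavelength slice
#'
#' Nonnegative least squares against Lamm-solution kernel columns with
#' algebraic elimination of time-invariant and radial-invariant noise
#' (solved exactly given the amplitudes) and regularization strength set
#' by the F-ratio criterion at the configured confidence level. Signal
#' amplitudes are rescaled to a maximum below 10 before fitting and
#' scaled back on output.
#'
#' @param data A slice as returned by [scan_slice()] (list with `radii`,
#'   `times`, `Y`), or an `mwe_scan_set` (then `wavelength` selects the
#'   slice).
#' @param kernel An [build_lamm_kernel()] result; built on the fly from
#'   `config` when `NULL`.
#' @param config An [fit_config()].
#' @param wavelength Wavelength (nm) when `data` is a scan set.
#' @param solv A [solvent()] (used only when the kernel must be built).
#' @return An object of class `mwe_cs_fit`: the distribution tibble
#'   (`s`, `c` loadings per grid value, `density` per S), TI/RI noise
#'   estimates, rmsd and the selected penalty.
#' @export
fit_cs <- function(data, kernel = NULL, config = fit_config(),
                   wavelength = NULL, solv = solvent()) {
  if (inherits(data, "mwe_scan_set")) {
    scanset <- data
    data <- scan_slice(scanset, wavelength)
    if (is.null(kernel)) {
      win <- default_window(scanset$protocol, config$window)
      keep <- data$radii >= win[1] & data$radii <= win[2]
      kernel <- build_lamm_kernel(config$s_grid, config$ff0, config$vbar,
                                  solv, scanset$protocol,
                                  data$radii[keep], data$times)
    }
  }
  if (is.null(kernel)) abort("a kernel is required when data is a raw slice")
  idx <- vapply(kernel$radii, function(r) which.min(abs(data$radii - r)),
                integer(1))
  if (max(abs(data$radii[idx] - kernel$radii)) > 1e-5)
    abort("kernel radii are not a subset of the data radii")
  Y <- data$Y[idx, , drop = FALSE]
  nr <- nrow(Y); nt <- ncol(Y)
  if (nt != length(kernel$times)) abort("kernel/data time grids differ")

  m <- max(abs(Y))
  f <- if (m > 0) 10 / m else 1
  Yw <- Y * f

  Yp <- project_noise(Yw, config$fit_ti, config$fit_ri)
  ns <- length(kernel$s_grid)
  Kp <- matrix(0, nr * nt, ns)
  for (i in seq_len(ns)) {
    Kc <- matrix(kernel$K[, i], nr, nt)
    Kp[, i] <- as.numeric(project_noise(Kc, config$fit_ti, config$fit_ri))
  }
  yp <- as.numeric(Yp)
  G <- crossprod(Kp); b <- as.numeric(crossprod(Kp, yp))
  yty <- sum(yp^2)
  df <- nr * nt

  solve_at <- if (config$regularization == "second_derivative") {
    LtL <- crossprod(second_diff_matrix(ns))
    function(alpha) nnls_compressed(G, b, yty, alpha, LtL)
  } else {
    prior <- 1e-4
    function(alpha) {
      if (alpha <= 0) nnls_compressed(G, b, yty)
      else maxent_solve(G, b, yty, alpha, prior)
    }
  }
  fit0 <- solve_at(0)
  alpha <- select_regularization(function(a) solve_at(a)$rss,
                                 config$confidence, fit0$rss, df)
  fit1 <- if (alpha > 0) solve_at(alpha) else fit0

  # noise components solved exactly given the amplitudes
  E <- matrix(as.numeric(Yw) - kernel$K %*% fit1$c, nr, nt)
  ti <- rep(0, nr); ri <- rep(0, nt)
  if (config$fit_ti && config$fit_ri) {
    ti <- rowMeans(E) - mean(E) # zero-mean TI convention
    ri <- colMeans(E)
  } else if (config$fit_ti) {
    ti <- rowMeans(E)
  } else if (config$fit_ri) {
    ri <- colMeans(E)
  }
  resid <- E - ti - rep(ri, each = nr)
  rmsd <- sqrt(mean(resid^2))

  s <- kernel$s_grid
  ds <- c(diff(s), s[length(s)] - s[length(s) - 1])
  structure(
    list(distribution = tibble(s = s, c = fit1$c / f,
                               density = fit1$c / f / ds),
         ti = tibble(radius = kernel$radii, ti = ti / f),
         ri = tibble(time = kernel$times, ri = ri / f),
         rmsd = rmsd / f, rmsd_unreg = sqrt(fit0$rss / df) / f,
         alpha = alpha, config = config, kernel_meta =
           list(meniscus = kernel$meniscus, ff0 = kernel$ff0,
                vbar = kernel$vbar),
         n_points = df, scale = f),
    class = "mwe_cs_fit")
}

#' @export
print.mwe_cs_fit <- function(x, ...) {
  pk <- peak_table(x)
  cat(sprintf("<mwe_cs_fit> %d s-values in [%g, %g] S, rmsd %.4g, alpha %.3g\n",
              nrow(x$distribution), min(x$distribution$s),
              max(x$distribution$s), x$rmsd, x$alpha))
  if (nrow(pk)) {
    cat("peaks:\n")
    print.data.frame(as.data.frame(pk), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mwe_cs_fit <- function(x, ...) x$distribution

#' @exportS3Method generics::glance
glance.mwe_cs_fit <- function(x, ...) {
  tibble(rmsd = x$rmsd, rmsd_unreg = x$rmsd_unreg, alpha = x$alpha,
         n_points = x$n_points, meniscus = x$kernel_meta$meniscus,
         ff0 = x$kernel_meta$ff0, vbar = x$kernel_meta$vbar,
         total_signal = sum(x$distribution$c))
}

#' Peaks of a c(s) distribution
#'
#' Contiguous regions of the s-grid above a threshold fraction of the
#' maximum define candidate peaks; a region holding several local maxima
#' is split at any interior valley that dips below `split_frac` of the
#' smaller neighbouring maximum (partially resolved peaks). Each peak is
#' reported with its signal-weighted mean s and integrated amplitude.
#'
#' @param x An `mwe_cs_fit` or a tibble with columns `s`, `c`.
#' @param threshold Fraction of the global maximum (default 0.05).
#' @param split_frac Valley depth (relative to the smaller adjacent
#'   maximum) below which a region is split into separate peaks.
#' @return Tibble with `s_peak` (weighted mean), `amplitude`, `s_lo`,
#'   `s_hi`.
#' @export
peak_table <- function(x, threshold = 0.05, split_frac = 0.5) {
  d <- if (inherits(x, "mwe_cs_fit")) x$distribution else as_tibble(x)
  cmax <- max(d$c)
  if (cmax <= 0) return(tibble(s_peak = numeric(), amplitude = numeric(),
                               s_lo = numeric(), s_hi = numeric()))
  above <- d$c >= threshold * cmax
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segments <- list()
  for (k in which(runs$values)) {
    i <- starts[k]:ends[k]
    y <- d$c[i]
    cut <- integer()
    if (length(y) >= 5) {
      lmax <- which(y >= dplyr::lag(y, default = -Inf) &
                      y >= dplyr::lead(y, default = -Inf))
      if (length(lmax) > 1) {
        for (m in seq_len(length(lmax) - 1)) {
          between <- (lmax[m] + 1):(lmax[m + 1] - 1)
          if (length(between) == 0) next
          v <- between[which.min(y[between])]
          if (y[v] < split_frac * min(y[lmax[m]], y[lmax[m + 1]]))
            cut <- c(cut, v)
        }
      }
    }
    bounds <- c(0, cut, length(y))
    for (m in seq_len(length(bounds) - 1))
      segments <- c(segments, list(i[(bounds[m] + 1):bounds[m + 1]]))
  }
  purrr::map_dfr(segments, function(i) {
    tibble(s_peak = weighted.mean(d$s[i], d$c[i]),
           amplitude = sum(d$c[i]),
           s_lo = d$s[i[1]], s_hi = d$s[i[length(i)]])
  })
}

# ---- nonlinear outer optimisation -------------------------------------

#' Optimise meniscus, frictional ratio or partial specific volume
#'
#' One-dimensional bounded minimisation (Brent) of the fit rmsd over the
#' floated nonlinear parameter; the linear c(s) problem is re-solved at
#' every trial (unregularized during the scan for speed, regularized in
#' the final refit).
#'
#' @param scanset An `mwe_scan_set`.
#' @param config An [fit_config()] with `float` set to `"meniscus"`,
#'   `"ff0"` or `"vbar"`.
#' @param interval Search interval for the floated parameter; defaults
#'   depend on the parameter.
#' @param wavelength Wavelength analysed (`NULL` = wavelength-integrated
#'   signal).
#' @param solv A [solvent()].
#' @return List with `par` (best value), `objective` (rmsd at optimum)
#'   and `fit` (the final regularized `mwe_cs_fit`).
#' @export
optimize_nonlinear <- function(scanset, config, interval = NULL,
                               wavelength = NULL, solv = solvent()) {
  if (config$float == "none") abort("config$float must name a parameter")
  protocol <- scanset$protocol
  start <- config$float_start
  interval <- interval %||% switch(config$float,
    meniscus = protocol$meniscus + c(-1, 1) * 0.05,
    ff0 = c(1.0, 4.0),
    vbar = c(0.2, 1.0))
  slice <- scan_slice(scanset, wavelength)
  win <- default_window(protocol, config$window)
  lo <- if (config$float == "meniscus") max(win[1], interval[2] + 0.002)
        else win[1]
  keep <- slice$radii >= lo & slice$radii <= win[2]
  radii <- slice$radii[keep]
  eval_par <- function(p, scan_only = TRUE) {
    prot <- protocol
    ff0 <- config$ff0; vbar <- config$vbar
    if (config$float == "meniscus") {
      prot$meniscus <- p
      prot$radii <- seq(p, protocol$bottom,
                        by = protocol$radial_step * 1e-4)
    } else if (config$float == "ff0") ff0 <- p else vbar <- p
    kern <- build_lamm_kernel(config$s_grid, ff0, vbar, solv, prot,
                              radii, slice$times)
    cfg <- config
    if (scan_only) cfg$confidence <- 1e-8 # effectively unregularized
    fit_cs(slice, kern, cfg)
  }
  obj <- function(p) eval_par(p)$rmsd_unreg
  if (!is.null(start))
    interval <- range(c(interval, start)) # start value always searchable
  opt <- optimize(obj, interval = interval, tol = 1e-4 * diff(interval))
  rel <- (opt$minimum - interval[1]) / diff(interval)
  if (rel < 0.01 || rel > 0.99)
    warn("optimum lies at the boundary of the search interval")
  final <- eval_par(opt$minimum, scan_only = FALSE)
  list(par = opt$minimum, objective = final$rmsd, fit = final)
}
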