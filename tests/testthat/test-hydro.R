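test_that("Svedberg relation gives the expected molar mass and fails at neutral buoyancy", {
  w20 <- solvent(density = 0.99823)
  # independent SI-unit evaluation: s R T / (D (1 - vbar rho))
  m_oracle <- 4.3e-13 * 8.314462618 * 293.15 /
    (6.0e-7 * 1e-4 * (1 - 0.733 * 0.99823))
  m <- svedberg_mass(4.3, 6.0e-7, 0.733, w20)
  expect_equal(m, m_oracle, tolerance = 1e-10)
  expect_within(m, 65, 1) # ~65 kg/mol for a BSA-like protein
  expect_error(svedberg_mass(4.3, 6e-7, 1 / 0.99823, w20), "neutral")
  # doubling D halves M
  expect_equal(svedberg_mass(4.3, 1.2e-6, 0.733, w20), m / 2)
})

test_that("diffusion_from_s matches a two-route Stokes-Svedberg oracle", {
  solv <- solvent()
  d <- diffusion_from_s(4, 1.2, 0.73, solv)
  # oracle: find D such that the Stokes radius of the sphere with molar
  # mass M(s, D) and friction f/f0 * 6 pi eta r0 reproduces D = kT / f
  kB <- 1.380649e-16
  eta <- solv$viscosity * 0.01
  resid <- function(D) {
    m_g <- svedberg_mass(4, D, 0.73, solv) * 1000 # g/mol
    r0 <- (3 * m_g * 0.73 / (4 * pi * 6.02214076e23))^(1 / 3)
    kB * solv$temperature / (6 * pi * eta * 1.2 * r0) - D
  }
  d_oracle <- uniroot(resid, c(1e-8, 1e-5), tol = 1e-15)$root
  expect_equal(d, d_oracle, tolerance = 1e-6)
  # monotone decreasing in f/f0; s^(-1/2) scaling
  expect_true(all(diff(diffusion_from_s(4, c(1, 1.2, 1.5, 2), 0.73, solv)) < 0))
  expect_equal(diffusion_from_s(16, 1.2, 0.73, solv), d / 2,
               tolerance = 1e-12)
  expect_error(diffusion_from_s(-1, 1.2, 0.73, solv))
  expect_error(diffusion_from_s(4, 1.2, 1.1, solvent(density = 1.0)))
})

test_that("ideal boundary position and plateau dilution follow the closed forms", {
  om <- rotor_protocol(speed = 40000)$omega
  expect_equal(om^2, 1.7545963e7, tolerance = 1e-6)
  expect_equal(faxen_boundary(4, om, 6.0, 0), 6.0)
  expect_equal(faxen_boundary(0, om, 6.0, c(0, 1e4, 1e5)), rep(6.0, 3))
  expect_equal(faxen_boundary(4, om, 6.0, 3600), 6.1535, tolerance = 1e-4)
  expect_true(all(diff(faxen_boundary(4, om, 6.0, seq(0, 7200, 600))) > 0))
  expect_equal(radial_dilution(4, om, 0), 1.0)
  expect_equal(radial_dilution(4, om, 3600), 0.9507, tolerance = 1e-4)
  expect_equal(radial_dilution(4, om, 7200), radial_dilution(4, om, 3600)^2,
               tolerance = 1e-12)
})

test_that("Lamm solver conserves sector mass and recovers the pure-diffusion limit", {
  sp <- species("x", s = 4, ff0 = 1.2, vbar = 0.73, c0 = 1)
  prot <- rotor_protocol(n_scans = 10, scan_interval = 900)
  sol <- solve_lamm(sp, protocol = prot)
  M <- profiles_matrix(sol)
  expect_true(all(M >= 0))
  m0 <- sector_mass(prot$radii, rep(1, length(prot$radii)))
  drift <- apply(M, 2, function(cc)
    abs(sector_mass(prot$radii, cc) - m0) / m0)
  expect_lt(max(drift), 1e-6)
  # omega ~ 0: diffusion drives the profile back to uniform
  still <- rotor_protocol(speed = 1, n_scans = 2, scan_interval = 5e6)
  M2 <- profiles_matrix(solve_lamm(species("d", s = 0, c0 = 1),
                                   protocol = still, D = 5e-6))
  expect_lt(max(abs(M2[, 2] - 1)), 1e-6)
})

test_that("diffusion-free boundary midpoint tracks the ideal boundary within one radial step", {
  sp <- species("i", s = 4, ff0 = 1.2, vbar = 0.73, c0 = 1)
  prot <- rotor_protocol(n_scans = 12, scan_interval = 600)
  sol <- solve_lamm(sp, protocol = prot, D = 0)
  mids <- mweauc:::boundary_midpoints(sol, prot)
  fx <- faxen_boundary(4, prot$omega, prot$meniscus, mids$time)
  expect_lt(max(abs(mids$midpoint - fx)), prot$radial_step * 1e-4)
})

test_that("solver plateau matches the square-dilution rule to 0.1%", {
  sp <- species("x", s = 4, ff0 = 1.2, vbar = 0.73, c0 = 1)
  prot <- rotor_protocol(n_scans = 6, scan_interval = 600)
  sol <- solve_lamm(sp, protocol = prot)
  M <- profiles_matrix(sol)
  for (j in seq_along(prot$times)) {
    r_b <- faxen_boundary(4, prot$omega, prot$meniscus, prot$times[j])
    sel <- prot$radii > r_b + 0.1 & prot$radii < prot$bottom - 0.3
    plat <- stats::median(M[sel, j])
    expect_within(plat, radial_dilution(4, prot$omega, prot$times[j]),
                  1e-3)
  }
})

test_that("solver refuses a grid too coarse to resolve the transport", {
  sp <- species("x", s = 4, ff0 = 1.2, vbar = 0.73, c0 = 1)
  prot <- rotor_protocol(radial_step = 1000, n_scans = 2)
  expect_error(solve_lamm(sp, protocol = prot), "coarse")
})

test_that("halving the radial step changes windowed profiles below the fit tolerance", {
  sp <- species("x", s = 4, ff0 = 1.2, vbar = 0.73, c0 = 1)
  p1 <- rotor_protocol(n_scans = 6, scan_interval = 900, radial_step = 50)
  p2 <- rotor_protocol(n_scans = 6, scan_interval = 900, radial_step = 25)
  M1 <- profiles_matrix(solve_lamm(sp, protocol = p1))
  M2 <- profiles_matrix(solve_lamm(sp, protocol = p2))
  M2 <- M2[seq(1, nrow(M2), by = 2), ]
  win <- p1$radii <= 6.9
  expect_lt(max(abs(M1[win, ] - M2[win, ])), 0.03)
})

test_that("species and protocol constructors enforce their invariants", {
  expect_error(species("bad", s = 4, ff0 = 0.9), "frictional")
  expect_error(species("bad", s = 4, vbar = 1.5), "vbar")
  expect_error(species("bad", s = -1), ">= 0")
  expect_error(rotor_protocol(meniscus = 7.3, bottom = 7.2), "meniscus")
  sp <- species("ok", s = 3, emission = gaussian_emission(700, 40))
  expect_equal(sum(sp$emission$intensity), 1)
  # flotation is flagged through the buoyancy term, not at construction
  expect_error(diffusion_from_s(3, 1.2, 1.1, solvent()), "float")
})
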