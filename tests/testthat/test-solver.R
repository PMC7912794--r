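test_that("interfacial partition: no-exclusion identity and ideal-Donnan quadratic", {
  salt <- ideal_salt(10)
  m0 <- membrane(0.5e-9, 1e-5, 78.4, charge_profile(0, 0))
  pt <- partition_interface(salt$conc, 0, m0, salt)
  expect_equal(pt$dpsi, 0, tolerance = 1e-12)
  expect_equal(unname(pt$c_pore), c(10, 10), tolerance = 1e-8)

  # fixed charge -20 mol/m^3 against 10 mol/m^3 1:1 salt: quadratic closed form
  mq <- membrane(0.5e-9, 1e-5, 78.4, charge_profile(-20, -20))
  ptq <- partition_interface(salt$conc, -20, mq, salt)
  oracle <- donnan_quadratic(10, -20)
  expect_equal(unname(ptq$c_pore[1]) / oracle[["cation"]], 1, tolerance = 1e-8)
  expect_equal(unname(ptq$c_pore[2]) / oracle[["anion"]], 1, tolerance = 1e-8)
  expect_lt(ptq$dpsi, 0)  # negative charge pulls the pore potential down

  # with no fixed charge, partition is homogeneous of degree one
  salt2 <- ideal_salt(20)
  pt2 <- partition_interface(salt2$conc, 0, m0, salt2)
  expect_equal(unname(pt2$c_pore), 2 * unname(pt$c_pore), tolerance = 1e-8)
})

test_that("ENP right-hand side reduces correctly in limiting cases", {
  feed <- neutral_feed(5)
  m <- uncharged_membrane()
  tr <- feed$species[[1]]
  lam <- tr$r_stokes / m$rp
  h <- bungay_brenner(lam)
  Jv <- 1e-5
  P <- Jv * m$dx_eff / (h$Kd * tr$D_inf)
  out <- enp_rhs(0.5, conc = 3, permeate = 1, Jv = Jv, membrane = m,
                 solution = feed)
  expect_equal(out$dconc, P * (h$Kc * 3 - 1), tolerance = 1e-12)
  expect_equal(out$dpsi_dx, 0)
  # flat steady state: gradient vanishes when Kc*c equals the permeate
  out0 <- enp_rhs(0.5, conc = 3, permeate = h$Kc * 3, Jv = Jv, membrane = m,
                  solution = feed)
  expect_equal(out0$dconc, 0, tolerance = 1e-14)

  # inhomogeneous-charge term: rising fixed charge with zero convective
  # imbalance gives dpsi/dx > 0, i.e. a negative axial field
  salt <- ideal_salt(10)
  mb <- membrane(0.5e-9, 1e-5, 78.4, charge_profile(-20, 20, x0 = 0.5, w = 0.1))
  hh <- bungay_brenner(1e-18 / 0.5e-9)
  outc <- enp_rhs(0.5, conc = c(10, 10), permeate = hh$Kc * c(10, 10),
                  Jv = 1e-6, membrane = mb, solution = salt)
  expect_gt(outc$dpsi_dx, 0)
})

test_that("solver reproduces the closed-form neutral rejection law", {
  feed <- neutral_feed(5)
  m <- uncharged_membrane()
  tr <- feed$species[[1]]
  lam <- tr$r_stokes / m$rp
  h <- bungay_brenner(lam)
  for (pe in c(0.01, 0.5, 5, 50)) {
    Jv <- pe * h$Kd * tr$D_inf / (h$Kc * m$dx_eff)
    sol <- solve_transport(m, operating_point(feed, Jv = Jv))
    expect_true(sol$converged)
    expect_equal(sol$rejection[[1]], neutral_rejection_curve(lam, pe),
                 tolerance = 1e-6)
  }
})

test_that("zero and vanishing flux give zero rejection", {
  feed <- neutral_feed(5)
  m <- uncharged_membrane()
  s0 <- solve_transport(m, operating_point(feed, Jv = 0))
  expect_true(s0$converged)
  expect_equal(s0$rejection[[1]], 0)
  stiny <- solve_transport(m, operating_point(feed, Jv = 1e-9))
  expect_lt(stiny$rejection[[1]], 1e-3)
})

test_that("high-Peclet rejection approaches the ideal-Donnan limiting value", {
  salt <- ideal_salt(10)
  m <- membrane(0.5e-9, 1e-5, 78.4, charge_profile(-20, -20))
  Jv <- 30 * 1.3e-9 / 1e-5   # Pe = 30 for both (equal-D, unhindered) ions
  sol <- solve_transport(m, operating_point(salt, Jv = Jv))
  expect_true(sol$converged)
  expect_equal(sol$rejection[[1]], donnan_limiting_rejection(10, -20),
               tolerance = 1e-3)
  expect_equal(sol$rejection[[1]], sol$rejection[[2]], tolerance = 1e-8)
})

test_that("electroneutrality closure holds at every grid point", {
  feed <- sdz_feed()
  m <- suppressWarnings(nf_membranes())[["NF90"]]
  sol <- solve_transport(m, operating_point(feed, Jv = 1e-5),
                         control = quiet_ctl())
  expect_true(sol$converged)
  expect_lt(sol$residual_electroneutrality, 1e-8)
  Cl <- eval_profile(m$profile, sol$x_grid)
  z <- sol$pars$z
  expect_lt(max(abs(sol$conc %*% z + Cl)) / max(sol$conc), 1e-8)
})

test_that("species fluxes reconstructed from the profiles are conserved", {
  salt <- ideal_salt(10)
  m <- membrane(0.5e-9, 1e-5, 78.4, charge_profile(-20, -20))
  Jv <- 5 * 1.3e-9 / 1e-5
  sol <- solve_transport(m, operating_point(salt, Jv = Jv))
  cst <- physical_constants()
  RTF <- cst$R * 298.15 / cst$F
  psi_s <- stats::splinefun(sol$x_grid, sol$psi)
  xs <- seq(0.02, 0.98, length.out = 40)
  for (i in seq_along(sol$pars$z)) {
    c_s <- stats::splinefun(sol$x_grid, sol$conc[, i])
    hKdD <- sol$pars$Kd[i] * sol$pars$D[i] / m$dx_eff
    j <- sol$pars$Kc[i] * c_s(xs) * Jv -
      hKdD * (c_s(xs, deriv = 1) + sol$pars$z[i] * c_s(xs) *
                psi_s(xs, deriv = 1) / RTF)
    expect_equal(j / Jv, rep(sol$permeate[[i]], length(xs)), tolerance = 1e-6)
  }
})

test_that("rejection is stable under a tenfold tighter integration tolerance", {
  feed <- sdz_feed()
  m <- suppressWarnings(nf_membranes())[["NF270"]]
  s1 <- solve_transport(m, operating_point(feed, Jv = 1e-5),
                        control = quiet_ctl(rtol = 1e-10))
  s2 <- solve_transport(m, operating_point(feed, Jv = 1e-5),
                        control = quiet_ctl(rtol = 1e-11))
  expect_lt(abs(s1$rejection[["SDZ"]] - s2$rejection[["SDZ"]]), 1e-6)
})

test_that("potential profile integrates the axial field", {
  salt <- ideal_salt(10)
  mb <- membrane(0.5e-9, 1e-5, 78.4, charge_profile(-20, 20, x0 = 0.6, w = 0.1))
  sol <- solve_transport(mb, operating_point(salt, Jv = 2e-6))
  # -integral(E) dx * dx_eff recovers psi(1) - psi(0)
  x <- sol$x_grid
  intE <- sum((sol$E[-1] + sol$E[-length(x)]) / 2 * diff(x))
  expect_equal(-intE * mb$dx_eff, sol$psi[length(x)] - sol$psi[1],
               tolerance = 1e-4)
})

test_that("pressure-to-flux conversion follows Hagen-Poiseuille", {
  m <- membrane(0.34e-9, 1e-6, 33.4, charge_profile(0, 0))
  expect_identical(flux_from_pressure(0, m), 0)
  expect_equal(flux_from_pressure(1e6, m),
               (0.34e-9)^2 * 1e6 / (8 * 0.89e-3 * 1e-6), tolerance = 1e-12)
  expect_equal(flux_from_pressure(1e6, m) * 1e5, 1.6, tolerance = 0.02)
  expect_equal(flux_from_pressure(2e6, m), 2 * flux_from_pressure(1e6, m))
  expect_identical(flux_from_pressure(1e3, m, delta_pi = 1e6), 0)  # clipped
})

test_that("solver inputs are validated", {
  feed <- neutral_feed()
  expect_error(operating_point(feed), "exactly one")
  expect_error(operating_point(feed, Jv = 1e-5, dP = 1e6), "exactly one")
  expect_error(operating_point(feed, Jv = -1), ">= 0")
  m <- uncharged_membrane()
  sol <- solve_transport(m, operating_point(feed, Jv = 1e-6))
  expect_error(rejection(sol, "nope"), "not in the feed")
  expect_equal(rejection(sol, "tracer"), sol$rejection[["tracer"]])
})
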