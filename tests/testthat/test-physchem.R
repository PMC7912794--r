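test_that("Stokes-Einstein radius reproduces the tabulated solute sizes", {
  # sulfadiazine: D = 6.14e-10 m^2/s at 25 C gives 0.40 nm at 2 s.f.
  rs <- stokes_einstein_radius(6.14e-10, T = 298.15, mu = 0.89e-3)
  expect_equal(signif(rs * 1e9, 2), 0.40)
  # direct evaluation for a faster diffuser
  expect_equal(stokes_einstein_radius(9.1e-10) * 1e9, 0.2696408, tolerance = 1e-6)
  # inverse proportionality in D
  expect_equal(stokes_einstein_radius(2 * 6.14e-10),
               stokes_einstein_radius(6.14e-10) / 2)
  # exact round trip radius -> D -> radius
  r0 <- 0.31e-9
  expect_equal(stokes_einstein_radius(diffusivity_from_radius(r0)), r0,
               tolerance = 1e-12)
  expect_error(stokes_einstein_radius(-1e-10), "positive")
})

test_that("amphoteric speciation fractions behave like a diprotic acid-base", {
  f <- charge_fractions(6.50, 2.00, 6.50)
  expect_equal(unname(f[1, "anionic"]), 0.5, tolerance = 1e-4) # half-dissociation at pKa2
  f7 <- charge_fractions(7, 2.00, 6.50)
  expect_equal(unname(f7[1, "anionic"]), 0.7597451, tolerance = 1e-6)
  expect_equal(unname(charge_fractions(-6, 2, 6.5)[1, "cationic"]), 1,
               tolerance = 1e-6)  # fully protonated at very low pH
  # fractions sum to one across the pH scale
  fr <- charge_fractions(seq(0, 14, by = 0.25), 2.00, 6.50)
  expect_true(all(abs(rowSums(fr) - 1) < 1e-12))
  expect_error(charge_fractions(7, 6.5, 2), "smaller")
})

test_that("Gouy-Chapman charge conversion matches closed form and limits", {
  kcl <- zeta_electrolyte()
  expect_identical(gouy_chapman_sigma(0, kcl), 0)
  # direct evaluation at zeta = -RT/F (exp(+-1) terms), 1 mM KCl, 25 C
  cst <- physical_constants()
  zeta <- -cst$R * 298.15 / cst$F
  s_direct <- -sqrt(2 * cst$eps0 * 78.4 * cst$R * 298.15 *
                      (exp(1) + exp(-1) - 2))
  expect_equal(gouy_chapman_sigma(zeta, kcl), s_direct, tolerance = 1e-12)
  expect_equal(s_direct * 1e3, -1.933433, tolerance = 1e-6)
  # odd in zeta, monotone in |zeta|
  zs <- seq(1e-3, 60e-3, length.out = 25)
  sg <- gouy_chapman_sigma(zs, kcl)
  expect_equal(gouy_chapman_sigma(-zs, kcl), -sg)
  expect_true(all(diff(sg) > 0))
  # Debye-Huckel linearization within 2% for |zeta| <= 5 mV
  kappa <- sqrt(2 * cst$F^2 * 1 / (cst$eps0 * 78.4 * cst$R * 298.15))
  zlin <- seq(0.5e-3, 5e-3, length.out = 10)
  expect_equal(gouy_chapman_sigma(zlin, kcl),
               cst$eps0 * 78.4 * kappa * zlin, tolerance = 0.02)
})

test_that("surface-to-volume charge conversion is 2 sigma / (F rp)", {
  expect_identical(sigma_to_cloc(0, 0.4e-9), 0)
  expect_equal(sigma_to_cloc(-1.93e-3, 0.35e-9), -114.3031, tolerance = 1e-5)
  expect_equal(sigma_to_cloc(-1.93e-3, 0.70e-9),
               sigma_to_cloc(-1.93e-3, 0.35e-9) / 2)
  expect_error(sigma_to_cloc(1e-3, 0), "positive")
})

test_that("Born solvation penalty has the right magnitude and scalings", {
  sdz <- species("SDZ", -1, 6.14e-10, r_stokes = 0.40e-9)
  expect_equal(born_energy(sdz, eps_p = 33.4, eps_b = 78.4, T = 298.15),
               1.203938, tolerance = 1e-5)
  expect_identical(born_energy(species("n", 0, 6e-10), 33.4), 0)
  expect_equal(born_energy(sdz, eps_p = 78.4, eps_b = 78.4), 0)
  # z^2 scaling
  dv <- species("D2-", -2, 6.14e-10, r_stokes = 0.40e-9)
  expect_equal(born_energy(dv, 33.4), 4 * born_energy(sdz, 33.4))
  # strictly decreasing in eps_p up to the bulk value
  eps <- seq(20, 78.4, length.out = 20)
  w <- vapply(eps, function(e) born_energy(sdz, e), numeric(1))
  expect_true(all(diff(w) < 0))
  expect_true(all(w >= 0))
})

test_that("steric partition and the lambda cap", {
  expect_identical(steric_partition(0), 1)
  expect_identical(steric_partition(0.5), 0.25)
  expect_error(steric_partition(1), "cap")
  expect_error(steric_partition(-0.1), "non-negative")
  expect_warning(l <- cap_lambda(1.18), "capped")
  expect_identical(l, 0.95)
  expect_identical(cap_lambda(0.6), 0.6)
})

test_that("species and solution constructors validate their inputs", {
  expect_error(species("x", 0.5, 1e-9), "integer")
  expect_error(species("x", 1, -1e-9), "positive")
  sdz <- default_species()$sdz
  expect_equal(sdz$r_cav, sdz$r_stokes)  # cavity radius defaults to Stokes
  expect_error(
    solution_state(list(species("Na+", 1, 1.33e-9)), conc = 2),
    "electroneutral")
  feed <- sdz_feed()
  expect_s3_class(feed, "sede_solution")
  z <- vapply(feed$species, `[[`, numeric(1), "z")
  expect_lt(abs(sum(z * feed$conc)), 1e-12)
  expect_equal(unname(feed$conc["SDZ"]), 1 / 250.28, tolerance = 1e-12)
})
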