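test_that("profile endpoints, monotonicity and degenerate cases", {
  pr <- charge_profile(-50, 50, x0 = 0.5, w = 0.1)
  expect_equal(eval_profile(pr, 0), -50)
  expect_equal(eval_profile(pr, 1), 50)
  expect_equal(eval_profile(pr, 0.5), 0, tolerance = 1e-12)  # antisymmetric
  expect_true(all(diff(eval_profile(pr, seq(0, 1, by = 0.01))) > 0))
  # homogeneous membrane: constant profile, zero derivative
  ph <- charge_profile(-30, -30)
  expect_equal(eval_profile(ph, c(0, 0.37, 1)), rep(-30, 3))
  expect_equal(profile_derivative(ph, c(0.2, 0.8)), c(0, 0))
  expect_error(eval_profile(pr, 1.2), "0, 1")
  expect_error(charge_profile(10, -10), "non-decreasing")
})

test_that("analytic derivative agrees with finite differences and integrates back", {
  pr <- charge_profile(-60, 20, x0 = 0.7, w = 0.05)
  xs <- seq(0.05, 0.95, length.out = 20)
  h <- 1e-6
  fd <- (eval_profile(pr, xs + h) - eval_profile(pr, xs - h)) / (2 * h)
  expect_equal(profile_derivative(pr, xs), fd, tolerance = 1e-8)
  expect_true(all(profile_derivative(pr, seq(0, 1, by = 0.02)) >= 0))
  intd <- stats::integrate(function(x) profile_derivative(pr, x), 0, 1,
                           rel.tol = 1e-12)$value
  expect_equal(intd, pr$c_exit - pr$c_entrance, tolerance = 1e-8)
})

test_that("average charge: constant, antisymmetric and sharp-step limits", {
  expect_equal(average_charge(charge_profile(-7, -7)), -7, tolerance = 1e-10)
  expect_equal(average_charge(charge_profile(-40, 40, x0 = 0.5, w = 0.06)), 0,
               tolerance = 1e-8)
  # w -> 0: area tends to c_ent*x0 + c_exit*(1-x0)
  sharp <- charge_profile(-60, 20, x0 = 0.7, w = 1e-3)
  expect_equal(average_charge(sharp), -60 * 0.7 + 20 * 0.3, tolerance = 0.05)
})

test_that("zeta calibration produces bipolar profiles hitting average targets", {
  kcl <- zeta_electrolyte()
  # symmetric zetas give an antisymmetric profile with zero average
  ps <- calibrate_profile(20e-3, -20e-3, 0.4e-9, kcl, x0 = 0.5)
  expect_equal(ps$c_exit, -ps$c_entrance, tolerance = 1e-12)
  expect_equal(average_charge(ps), 0, tolerance = 1e-8)
  # fitted transition midpoint reproduces a requested average
  pt <- calibrate_profile(12e-3, -25e-3, 0.4e-9, kcl, target_average = -25.8)
  expect_equal(average_charge(pt), -25.8, tolerance = 1e-6)
  expect_error(
    calibrate_profile(12e-3, -25e-3, 0.4e-9, kcl, target_average = -500),
    "infeasible")
  expect_error(calibrate_profile(-10e-3, -20e-3, 0.4e-9, kcl), "amphoteric")
})

test_that("bundled fixtures encode the measured charge orderings", {
  fx <- suppressWarnings(nf_membranes())
  ent <- vapply(fx, function(m) m$profile$c_entrance, numeric(1))
  ext <- vapply(fx, function(m) m$profile$c_exit, numeric(1))
  # bipolar: negative entrance, positive exit, for every membrane
  expect_true(all(ent < 0 & ext > 0))
  # entrance magnitude: NF270 > TMN20H-400 > NF90 > VNF2-8040
  expect_true(abs(ent["NF270"]) > abs(ent["TMN20H-400"]) &&
                abs(ent["TMN20H-400"]) > abs(ent["NF90"]) &&
                abs(ent["NF90"]) > abs(ent["VNF2-8040"]))
  # exit magnitude: NF90 > TMN20H-400 > VNF2-8040 > NF270
  expect_true(ext["NF90"] > ext["TMN20H-400"] &&
                ext["TMN20H-400"] > ext["VNF2-8040"] &&
                ext["VNF2-8040"] > ext["NF270"])
  # calibrated averages reproduce their targets well within 5%
  zt <- membrane_zeta_table()
  avg <- vapply(fx, function(m) average_charge(m$profile), numeric(1))
  expect_equal(unname(avg[zt$membrane]), zt$avg_target, tolerance = 1e-6)
  # underlying zeta fixtures keep the measured pH-2 and pH-9 orderings
  za <- stats::setNames(zt$zeta_acid, zt$membrane)
  zb <- stats::setNames(zt$zeta_base, zt$membrane)
  expect_true(za["NF90"] > za["TMN20H-400"] && za["TMN20H-400"] > za["NF270"] &&
                za["NF270"] > za["VNF2-8040"])
  expect_true(abs(zb["NF270"]) > abs(zb["TMN20H-400"]) &&
                abs(zb["TMN20H-400"]) > abs(zb["NF90"]))
})
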