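p <- fibrin_params()

test_that("force laws reproduce hand-evaluated values", {
  # monomer: linear up to the onset d2, cubic beyond
  expect_identical(fibrinogen_force(0, p), 0)
  expect_equal(fibrinogen_force(46, p), 69)             # 1.5 * 46, cubic zero
  expect_equal(fibrinogen_force(56, p), 84.3)           # 84 + 0.0003 * 10^3
  expect_equal(fibrinogen_force(20, p), 1.5 * 20)       # pure linear regime

  # erf bond laws at one extension scale: k * erf(1)
  expect_identical(knob_hole_force(0, p), 0)
  expect_equal(knob_hole_force(10, p), 130 * ERF1, tolerance = 1e-12)
  expect_equal(gamma_gamma_force(20, p), 13 * ERF1, tolerance = 1e-12)

  # saturation far beyond the extension scale
  expect_equal(knob_hole_force(1000 * p$d3, p), 130)
  expect_equal(gamma_gamma_force(1000 * p$d4, p), 13)

  # binding: cubic inactive exactly at its onset
  expect_identical(binding_force(0, p), 0)
  expect_equal(binding_force(11.5, p), 1.15)
})

test_that("binding force vanishes identically when switched off", {
  off <- fibrin_params(k5 = 0, k6 = 0)
  x <- seq(-50, 200, by = 7)
  expect_identical(binding_force(x, off), rep(0, length(x)))
})

test_that("force laws are odd, monotone and bounded as stated", {
  x <- seq(0.1, 150, length.out = 40)
  # odd symmetry (erf laws exactly; cubic laws linear-branch mirrored)
  expect_equal(knob_hole_force(-x, p), -knob_hole_force(x, p))
  expect_equal(gamma_gamma_force(-x, p), -gamma_gamma_force(x, p))
  xs <- x[x <= p$d2]    # below cubic onset the monomer law is odd too
  expect_equal(fibrinogen_force(-xs, p), -fibrinogen_force(xs, p))

  # monotone non-decreasing
  grid <- seq(-200, 200, length.out = 401)
  for (f in list(fibrinogen_force, knob_hole_force, gamma_gamma_force,
                 binding_force)) {
    expect_true(all(diff(f(grid, p)) >= 0))
  }

  # saturation bounds: never above the plateau, strictly below it wherever
  # erf has not yet saturated to 1 in double precision
  expect_true(all(abs(knob_hole_force(grid, p)) <= p$k3))
  expect_true(all(abs(gamma_gamma_force(grid, p)) <= p$k4))
  near <- seq(-5 * p$d3, 5 * p$d3, length.out = 101)
  expect_true(all(abs(knob_hole_force(near, p)) < p$k3))
  expect_true(all(abs(gamma_gamma_force(near * 2, p)) < p$k4))
  expect_gte(knob_hole_force(3 * p$d3, p), 0.999 * p$k3)
  expect_gte(gamma_gamma_force(3 * p$d4, p), 0.999 * p$k4)
})

test_that("spring kinds dispatch to their laws; halves compose the monomer", {
  expect_equal(spring_force("knob_hole", 10, p), knob_hole_force(10, p))
  expect_equal(spring_force("gamma_gamma", 20, p), gamma_gamma_force(20, p))
  expect_equal(spring_force("binding", 11.5, p), binding_force(11.5, p))
  # two identical half springs in series at equal tension reproduce the
  # whole-molecule law: F_half(x/2) == F_molecule(x)
  x <- c(5, 23, 46, 60, 100)
  expect_equal(spring_force("monomer_half", x / 2, p), fibrinogen_force(x, p))
  expect_error(spring_force("wobbly", 1, p), "unknown spring kind")
  expect_error(spring_energy("wobbly", 1, p), "unknown spring kind")
})

test_that("spring energies are the antiderivatives of the force laws", {
  kinds <- c("monomer_half", "knob_hole", "gamma_gamma", "binding")
  for (kind in kinds) {
    expect_identical(spring_energy(kind, 0, p), 0)
  }
  # linear regime closed form: E = 1/2 k x^2 (half springs have k = 2 k1)
  expect_equal(spring_energy("monomer_half", 10, p), 0.5 * (2 * p$k1) * 10^2)

  # quadrature oracle: E(x) = integral of the force law from 0 to x
  for (kind in kinds) {
    for (x in c(5, 12, 30, 80, -15)) {
      quad <- integrate(function(t) spring_force(kind, t, p), 0, x,
                        rel.tol = 1e-11, abs.tol = 1e-13)$value
      expect_equal(spring_energy(kind, x, p), quad, tolerance = 1e-8)
    }
  }

  # central-difference derivative of the energy matches the force pointwise
  h <- 1e-5
  grid <- seq(-3 * p$d2, 3 * p$d2, length.out = 61)
  for (kind in kinds) {
    dE <- (spring_energy(kind, grid + h, p) -
             spring_energy(kind, grid - h, p)) / (2 * h)
    f <- spring_force(kind, grid, p)
    expect_equal(dE, f, tolerance = 1e-6)
  }
})

test_that("molecule-scale curve samples the monomer law", {
  crv <- fibrinogen_curve(p, x_max = 100, n = 51)
  expect_s3_class(crv, "force_extension_curve")
  expect_identical(curve_scale(crv), "molecule")
  expect_equal(crv$force_pN, fibrinogen_force(crv$extension_nm, p))
  g <- glance(crv)
  expect_identical(g$n_samples, 51L)
})
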