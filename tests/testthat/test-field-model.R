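test_that("disc solid angle matches the on-axis closed form and its limits", {
  a <- 12.5
  # point at distance d = a on the axis: 2*pi*(1 - 1/sqrt(2))
  expect_equal(disc_solid_angle(0, a, a), 2 * pi * (1 - 1 / sqrt(2)),
               tolerance = 1e-12)
  # almost touching the face: approaches the half-space 2*pi
  expect_equal(disc_solid_angle(0, 1e-6, a), 2 * pi, tolerance = 1e-6)
  # vanishing far field, on and off axis
  expect_lt(disc_solid_angle(0, 1e4, a), 1e-5)
  expect_lt(disc_solid_angle(1e4, 5, a), 1e-5)
  # always inside (0, 2*pi)
  for (x in c(0, 3, 12.5, 20)) {
    om <- disc_solid_angle(x, 3.5, a)
    expect_gt(om, 0)
    expect_lt(om, 2 * pi)
  }
})

test_that("elliptic evaluation agrees with direct 2-D quadrature to 1e-8", {
  for (x in c(0.5, 6, 12.4, 12.6, 25)) {
    om_e <- disc_solid_angle(x, 3.5, 12.5, method = "elliptic")
    om_q <- disc_solid_angle(x, 3.5, 12.5, method = "quadrature")
    expect_equal(om_e, om_q, tolerance = 1e-8)
  }
})

test_that("degenerate geometries are rejected as domain errors", {
  expect_error(disc_solid_angle(0, 0, 12.5), class = "paddleire_domain_error")
  expect_error(disc_solid_angle(0, -1, 12.5), class = "paddleire_domain_error")
  expect_error(disc_solid_angle(0, 5, 0), class = "paddleire_domain_error")
  expect_error(disc_solid_angle(-1, 5, 12.5), class = "paddleire_domain_error")
  expect_error(paddle_geometry(radius = 0, separation = 7),
               class = "paddleire_domain_error")
  expect_error(paddle_geometry(separation = -2), class = "paddleire_domain_error")
})

test_that("mid-plane density approaches the parallel-plate value as the gap closes", {
  a <- 12.5
  plate <- 100 / (pi * a^2)  # 0.2037 A/cm^2 at 1 A
  j0 <- nominal_midplane_density(paddle_geometry(a, 0.25), 0)
  expect_equal(j0, plate, tolerance = 0.01)
  # and from well below a/50 even tighter
  expect_equal(nominal_midplane_density(paddle_geometry(a, 0.05), 0), plate,
               tolerance = 2e-3)
})

test_that("nominal profile is non-increasing in radius across gap ratios", {
  a <- 12.5
  for (h_over_a in c(0.3, 0.56, 1.0)) {
    prof <- nominal_profile(paddle_geometry(a, h_over_a * a),
                            seq(0, 3 * a, by = 0.5))
    expect_true(all(diff(prof$j_a_per_cm2) <= 1e-9))
    expect_true(all(is.finite(prof$j_a_per_cm2)) && all(prof$j_a_per_cm2 >= 0))
  }
})

test_that("profile tabulation handles degenerate grids and lookup rounding", {
  geo <- paddle_geometry(separation = 7)
  single <- nominal_profile(geo, 0)
  expect_equal(nrow(single), 1)
  expect_equal(single$j_a_per_cm2, nominal_midplane_density(geo, 0))

  # lookup mode rounds 7.3 mm to the 7 mm table
  look <- nominal_profile(paddle_geometry(separation = 7.3), seq(0, 10, 1),
                          thickness_mode = "lookup")
  cont <- nominal_profile(paddle_geometry(separation = 7), seq(0, 10, 1))
  expect_equal(look$j_a_per_cm2, cont$j_a_per_cm2, tolerance = 1e-12)
  # ties round to even: 7.5 -> 8, 8.5 -> 8
  look75 <- nominal_profile(paddle_geometry(separation = 7.5), 0, "lookup")
  look85 <- nominal_profile(paddle_geometry(separation = 8.5), 0, "lookup")
  cont8 <- nominal_profile(paddle_geometry(separation = 8), 0)
  expect_equal(look75$j_a_per_cm2, cont8$j_a_per_cm2)
  expect_equal(look85$j_a_per_cm2, cont8$j_a_per_cm2)

  expect_error(nominal_profile(geo, numeric(0)), class = "paddleire_input_error")
  expect_error(nominal_profile(geo, c(1, 2)), class = "paddleire_input_error")
  expect_error(nominal_profile(geo, c(0, 2, 2)), class = "paddleire_input_error")
})

test_that("profile scaling is elementwise, linear and composable", {
  geo <- paddle_geometry(separation = 7)
  prof <- nominal_profile(geo, seq(0, 20, by = 1))

  expect_equal(scale_profile(prof, 0)$j_a_per_cm2, rep(0, 21))
  expect_equal(scale_profile(prof, 1)$j_a_per_cm2, prof$j_a_per_cm2)

  s <- scale_profile(prof, 25.3)
  expect_equal(s$j_a_per_cm2[1], 25.3 * prof$j_a_per_cm2[1], tolerance = 1e-15)
  expect_equal(attr(s, "peak_current"), 25.3)

  # scale(p, c1*c2) == scale(scale(p, c1), c2); powers of two compose with
  # no rounding at all, arbitrary factors to machine precision
  expect_identical(scale_profile(prof, 2 * 4)$j_a_per_cm2,
                   scale_profile(scale_profile(prof, 2), 4)$j_a_per_cm2)
  expect_equal(scale_profile(prof, 2.5 * 1.7)$j_a_per_cm2,
               scale_profile(scale_profile(prof, 2.5), 1.7)$j_a_per_cm2,
               tolerance = 1e-15)

  expect_error(scale_profile(prof, -1), class = "paddleire_input_error")
})

test_that("mid-plane flux recovers the delivered current", {
  grid <- seq(0, 100, by = 0.5)
  for (h in c(4, 7, 12)) {
    prof <- nominal_profile(paddle_geometry(separation = h), grid)
    expect_equal(as.numeric(midplane_flux(prof)), 1, tolerance = 0.01)
  }
  prof7 <- nominal_profile(paddle_geometry(separation = 7), grid)
  expect_equal(as.numeric(midplane_flux(scale_profile(prof7, 0))), 0)
  # linearity: scaled by the serial-group mean current
  expect_equal(as.numeric(midplane_flux(scale_profile(prof7, 22.4))), 22.4,
               tolerance = 0.3 / 22.4)
  # a grid that stops too early cannot support the tail extrapolation
  short <- nominal_profile(paddle_geometry(separation = 12), seq(0, 18, 0.5))
  expect_error(midplane_flux(short), class = "paddleire_precision_error")
})
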