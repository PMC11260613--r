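test_that("dose grids validate their invariants at construction", {
  expect_error(dose_grid(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(dose_grid(array(NaN, c(2, 2, 2))), "finite")
  expect_error(dose_grid(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  g <- dose_grid(array(1.5, c(3, 4, 5)), spacing = c(1, 2, 3),
                 origin = c(-1, 0, 2), frame_id = "ebrt")
  expect_identical(g$geometry$shape, c(3L, 4L, 5L))
  expect_equal(g$frame_id, "ebrt")
})

test_that("EQD2 conversion matches the linear-quadratic closed form", {
  # 45 Gy in 25 fx, a/b = 10: 45 * (1.8 + 10) / 12 = 44.25
  out <- eqd2_convert(uniform_dose_grid(45), fractionation_scheme(45, 25, 10))
  expect_equal(out$values, array(44.25, c(8, 8, 8)))
  # single 6 Gy fraction: 6 * 16 / 12 = 8 (a/b 10), 6 * 9 / 5 = 10.8 (a/b 3)
  expect_equal(eqd2_convert(uniform_dose_grid(6),
                            fractionation_scheme(6, 1, 10))$values[1], 8)
  expect_equal(eqd2_convert(uniform_dose_grid(6),
                            fractionation_scheme(6, 1, 3))$values[1], 10.8)
})

test_that("delivery at exactly 2 Gy per fraction is an EQD2 fixed point", {
  vals <- array(50, c(4, 4, 4))
  g <- dose_grid(vals, spacing = c(2, 2, 2))
  for (ab in c(3, 10)) {
    out <- eqd2_convert(g, fractionation_scheme(50, 25, ab))
    expect_identical(out$values, vals)
  }
})

test_that("EQD2 conversion is voxel-wise monotone and preserves zeros", {
  set.seed(11)
  a <- dose_grid(array(runif(64, 0, 60), c(4, 4, 4)))
  b <- dose_grid(array(pmax(as.vector(a$values) - runif(64, 0, 10), 0),
                       c(4, 4, 4)))
  sch <- fractionation_scheme(50, 25, 3)
  ea <- eqd2_convert(a, sch); eb <- eqd2_convert(b, sch)
  expect_true(all(ea$values >= eb$values))
  z <- eqd2_convert(dose_grid(array(0, c(3, 3, 3))), sch)
  expect_identical(z$values, array(0, c(3, 3, 3)))
})

test_that("scheme validation rejects non-positive parameters", {
  expect_error(fractionation_scheme(45, 0, 10), "positive integer")
  expect_error(fractionation_scheme(45, 25, 0), "alpha_beta")
  expect_error(scale_bt_course(uniform_dose_grid(8), 0), ">= 1")
})

test_that("BT course scaling is additive over sub-courses", {
  set.seed(7)
  fx <- dose_grid(array(runif(60, 0, 9), c(5, 4, 3)))
  whole <- scale_bt_course(fx, 7)
  parts <- accumulate_dose(scale_bt_course(fx, 3), scale_bt_course(fx, 4))
  expect_identical(whole$values, parts$values)
  expect_identical(scale_bt_course(fx, 1)$values, fx$values)
})

test_that("accumulation sums the printed summed prescriptions", {
  ebrt45 <- eqd2_convert(uniform_dose_grid(45), fractionation_scheme(45, 25, 10))
  ebrt50 <- eqd2_convert(uniform_dose_grid(50), fractionation_scheme(50, 25, 10))
  bt <- scale_bt_course(
    eqd2_convert(uniform_dose_grid(6), fractionation_scheme(6, 1, 10)), 4)
  expect_equal(accumulate_dose(ebrt45, bt)$values[1], 76.25)
  expect_equal(accumulate_dose(ebrt50, bt)$values[1], 82)
  # additive identity and commutativity
  zero <- uniform_dose_grid(0)
  x <- uniform_dose_grid(13)
  expect_identical(accumulate_dose(x, zero)$values, x$values)
  expect_identical(accumulate_dose(x, bt)$values, accumulate_dose(bt, x)$values)
})

test_that("accumulation requires one geometry and frame", {
  a <- uniform_dose_grid(1, shape = c(4, 4, 4))
  b <- uniform_dose_grid(1, shape = c(4, 4, 5))
  expect_error(accumulate_dose(a, b), "geometry")
  c2 <- uniform_dose_grid(1, shape = c(4, 4, 4), frame_id = "other")
  expect_error(accumulate_dose(a, c2), "geometry|frame")
})

test_that("resampling to the identical geometry is the identity", {
  set.seed(3)
  g <- dose_grid(array(runif(120, 0, 80), c(6, 5, 4)), spacing = c(2, 3, 4))
  out <- resample_to_grid(g, g$geometry)
  expect_equal(out$values, g$values, tolerance = 1e-12)
})

test_that("a uniform field survives resampling to a finer interior grid", {
  g <- uniform_dose_grid(42, shape = c(6, 6, 6), spacing = c(4, 4, 4))
  fine <- grid_geometry(c(8, 8, 8), c(2, 2, 2), origin = c(2, 2, 2))
  out <- resample_to_grid(g, fine)
  expect_equal(out$values, array(42, c(8, 8, 8)), tolerance = 1e-12)
})

test_that("trilinear resampling reproduces a linear ramp analytically", {
  # values linear in x: v(x) = 3 + 2.5 * x_mm
  geom <- grid_geometry(c(9, 4, 4), c(4, 2, 2))
  xs <- (0:8) * 4
  vals <- array(rep(3 + 2.5 * xs, times = 16), c(9, 4, 4))
  g <- dose_grid(vals, geom)
  fine <- grid_geometry(c(15, 4, 4), c(2, 2, 2), origin = c(1, 0, 0))
  out <- resample_to_grid(g, fine)
  expected <- 3 + 2.5 * (1 + (0:14) * 2)
  expect_equal(out$values[, 2, 2], expected, tolerance = 1e-10)
})

test_that("disjoint extents raise a geometry error", {
  g <- uniform_dose_grid(1, shape = c(4, 4, 4), spacing = c(1, 1, 1))
  far <- grid_geometry(c(4, 4, 4), c(1, 1, 1), origin = c(100, 0, 0))
  expect_error(resample_to_grid(g, far), "disjoint")
})

test_that("warping with the identity field is bit-for-bit", {
  set.seed(5)
  g <- dose_grid(array(runif(210, 0, 90), c(7, 6, 5)), spacing = c(2, 3, 4))
  id <- deformation_field(array(0, c(7, 6, 5, 3)), g$geometry)
  expect_identical(warp_dose(g, id)$values, g$values)
})

test_that("a one-voxel constant displacement shifts the grid by one plane", {
  set.seed(6)
  g <- dose_grid(array(runif(125, 0, 50), c(5, 5, 5)), spacing = c(2, 2, 2))
  disp <- array(0, c(5, 5, 5, 3)); disp[, , , 1] <- 2  # +x one spacing
  out <- warp_dose(g, deformation_field(disp, g$geometry))
  expect_equal(out$values[1:4, , ], g$values[2:5, , ], tolerance = 1e-12)
  expect_equal(out$values[5, , ], matrix(0, 5, 5))
})

test_that("displacements leaving the extent give a zero field", {
  g <- uniform_dose_grid(30, shape = c(4, 4, 4), spacing = c(2, 2, 2))
  disp <- array(500, c(4, 4, 4, 3))
  out <- warp_dose(g, deformation_field(disp, g$geometry))
  expect_identical(out$values, array(0, c(4, 4, 4)))
})

test_that("deformation fields validate their shape and finiteness", {
  geom <- grid_geometry(c(4, 4, 4), c(1, 1, 1))
  expect_error(deformation_field(array(0, c(4, 4, 3, 3)), geom), "dim")
  expect_error(deformation_field(array(Inf, c(4, 4, 4, 3)), geom), "finite")
})
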