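test_that("eca_cdl matches a numeric ellipse-perimeter quadrature oracle", {
  cases <- list(c(8.7, 6.5), c(9.5, 7.0), c(7.9, 5.9), c(10.2, 8.1))
  for (ab in cases) {
    oracle <- 1.417 * ellipse_perimeter_quadrature(ab[1] / 2, ab[2] / 2)
    expect_equal(eca_cdl(ab[1], ab[2]), oracle, tolerance = 5e-4)
  }
})

test_that("eca_cdl reduces to the circle circumference in the circle limit", {
  cfg <- geometry_config(eca_scale = 1)
  a <- 4
  # A = B is rejected as degenerate, so approach the limit
  expect_equal(eca_cdl(2 * a, 2 * a - 1e-9, cfg), 2 * pi * a, tolerance = 1e-8)
})

test_that("eca_cdl is strictly increasing in A and in B and validates input", {
  base <- eca_cdl(8.7, 6.5)
  expect_gt(eca_cdl(8.8, 6.5), base)
  expect_gt(eca_cdl(8.7, 6.6), base)
  expect_error(eca_cdl(6.5, 8.7), "exceed")
  expect_error(eca_cdl(-1, -2), "positive")
  expect_warning(eca_cdl(13, 6.5), "sanity band")
})

test_that("angle/length maps are exact inverses and hit both endpoints", {
  sp <- spiral_model(34.0)
  expect_identical(angle_to_length(0, sp), 0)
  expect_equal(angle_to_length(900, sp), 34.0)
  expect_equal(length_to_angle(34.0, sp), 900)
  set.seed(42)
  theta <- runif(1000, 0, 900)
  round_trip <- length_to_angle(angle_to_length(theta, sp), sp)
  expect_lt(max(abs(round_trip - theta)), 1e-9)
  expect_error(angle_to_length(901, sp), "degrees")
  expect_error(length_to_angle(35, sp), "mm")
})

test_that("cumulative arc length is strictly increasing and concave in angle", {
  sp <- spiral_model(34.0)
  grid <- seq(0, 900, by = 1)
  len <- angle_to_length(grid, sp)
  expect_true(all(diff(len) > 0))
  expect_true(all(diff(diff(len)) < 0))
})

test_that("the default map inverts the cohort-mean coverage near 511 degrees", {
  sp <- spiral_model(34.0)
  aid <- length_to_angle(0.748 * 34.0, sp)
  expect_true(aid > 505 && aid < 515)
})

test_that("electrode coverage is a plain percentage with validation", {
  expect_equal(electrode_coverage(25.43, 34.0), 100 * 25.43 / 34.0)
  expect_equal(electrode_coverage(17, 34), 50)
  expect_equal(electrode_coverage(20, 20), 100)
  expect_error(electrode_coverage(35, 34), "review")
  expect_error(electrode_coverage(0, 34), "positive")
})

test_that("with a fixed inserted length, AID falls as CDL grows", {
  cdl <- seq(31, 37, by = 0.25)
  aid <- vapply(cdl, function(ci) length_to_angle(25.4, spiral_model(ci)), 1.0)
  expect_true(all(diff(aid) < 0))
  expect_lt(cor(aid, cdl), 0)
})
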