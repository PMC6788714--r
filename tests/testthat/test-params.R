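test_that("the two parameter conventions agree and derive consistent rates", {
  p1 <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
  p2 <- branching_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.14 - 1.7 * 0.01,
                         u = 1e-5, M = 1e8)
  expect_equal(p1$d, p2$d)
  expect_equal(p1$d1, p2$d1)
  expect_equal(p1$c, 1.7)
  expect_equal(p1$g, 0.7)
  expect_equal(p1$r1, p1$c * p1$r)
})

test_that("invalid rate combinations are rejected", {
  # subcritical wild type (as listed for the fourth published CDF panel)
  expect_error(branching_params(b = 0.14, d = 0.17, b1 = 0.14, d1 = 0.02,
                                u = 1e-5, M = 1e8), "supercritical")
  # implied negative driver death rate
  expect_error(branching_params(b1 = 0.1, b = 0.1, r = 0.1, c = 3,
                                u = 1e-5, M = 1e8), "negative")
  # disadvantageous driver
  expect_error(branching_params(b = 0.2, d = 0.1, b1 = 0.2, d1 = 0.15,
                                u = 1e-5, M = 1e8), "decrease")
  # inconsistent d and r
  expect_error(branching_params(b = 0.14, d = 0.13, r = 0.02, g = 0.3,
                                u = 1e-5, M = 1e8), "inconsistent")
})

test_that("detection windows validate their bounds", {
  w <- detection_window()
  expect_equal(unclass(w), c(lo = 0.2, hi = 0.8))
  expect_error(detection_window(0.9, 0.2))
  expect_error(detection_window(-0.1, 0.5))
  expect_error(detection_window(0.5, 1.2))
  expect_equal(subdriver:::as_detection_window(c(0.24, 0.48))[["hi"]], 0.48)
})

test_that("rate-bound inputs must be nonnegative", {
  expect_error(rate_bound_inputs(-1, 90, 1e-8))
  expect_s3_class(rate_bound_inputs(0, 90, 1e-8), "rate_bound_inputs")
})

test_that("lattice parameters derive the driver death rate from g", {
  lp <- lattice_params(b = 1, d = 0.7, g = 0.7, u = 1e-5)
  expect_equal(lp$d1, 1 - 1.7 * 0.3)
  expect_equal(lp$c, 1.7)
  expect_equal(lp$u_site, 1e-3)
  expect_error(lattice_params(b = 1, d = 0.7, g = 3, u = 1e-5), "negative")
  expect_error(lattice_params(b = 1, d = 1.1, g = 0.3, u = 1e-5))
})
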