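test_that("second-driver detection is zero when it cannot arise", {
  p0 <- branching_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.123,
                         u = 0, M = 1e8)
  expect_equal(two_driver_detection(p0, delta_r = 0.007), 0)
  p <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
  expect_equal(two_driver_detection(p, delta_r = 0.007, window = c(0.3, 0.3)), 0)
  # second driver stronger than the division rate allows
  expect_error(two_driver_detection(p, delta_r = 0.5), "death rate")
})

test_that("the fixed outer rule agrees with adaptive quadrature", {
  cases <- list(
    list(b = 0.14, r = 0.01, g = 0.7, M = 1e8),
    list(b = 0.25, r = 0.07, g = 1.0, M = 1e9),
    list(b = 0.33, r = 0.0013, g = 0.3, M = 1e10)
  )
  for (cs in cases) {
    p <- branching_params(b = cs$b, r = cs$r, g = cs$g, u = 1e-5, M = cs$M)
    fixed <- two_driver_detection(p, delta_r = cs$g * cs$r)
    adaptive <- two_driver_detection(p, delta_r = cs$g * cs$r,
                                     outer_nodes = NULL)
    expect_equal(fixed, adaptive, tolerance = 2e-3)
    expect_gte(fixed, 0)
    expect_lte(fixed, 1)
  }
})

test_that("the two-driver formula matches a three-type Gillespie estimate", {
  # feasible point in the fast regime where the one-surviving-clone
  # approximation holds (1 << b1/(c u) << M)
  p <- branching_params(b = 0.25, r = 0.07, g = 0.7, u = 3e-4, M = 1e5)
  tt <- run_three_type(p, delta_r = 0.7 * 0.07, n_runs = 1500, seed = 11)
  P1_hat <- mean(tt$f_first >= 0.2 & tt$f_first <= 0.8)
  P2_hat <- mean(tt$f_first > 0.8 &
                   tt$f_second >= 0.2 & tt$f_second <= 0.8)
  P1 <- detection_probability(p)
  P2 <- two_driver_detection(p, delta_r = 0.7 * 0.07)
  sem1 <- sqrt(P1_hat * (1 - P1_hat) / nrow(tt))
  sem2 <- sqrt(P2_hat * (1 - P2_hat) / nrow(tt))
  expect_lt(abs(P1_hat - P1), 3 * sem1)
  expect_lt(abs(P2_hat - P2), 3 * sem2)
})
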