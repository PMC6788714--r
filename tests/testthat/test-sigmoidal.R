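test_that("degenerate initial conditions behave exactly", {
  sp <- sigmoidal_params(r = 0.01, g = 0.7, K = 1e11)
  expect_equal(final_driver_fraction(sp, x0 = 1e6, y0 = 0), 0)
  tr <- solve_sigmoidal(sp, x0 = 1e6, y0 = 0, n_out = 50)
  expect_true(all(tr$y == 0))
  expect_equal(tail(tr$driver_fraction, 1), 0)
  expect_error(final_driver_fraction(sp, x0 = 0, y0 = 10), "x0")
  expect_error(solve_sigmoidal(sp, x0 = -1, y0 = 10), "x0")
  expect_error(final_driver_fraction(sp, x0 = 1e11, y0 = 1e10),
               "carrying capacity")
})

test_that("a neutral pair freezes at its initial fractions", {
  sp <- sigmoidal_params(r = 0.05, c = 1 + 1e-12, K = 1e9)
  expect_equal(final_driver_fraction(sp, x0 = 9e5, y0 = 1e5), 0.1,
               tolerance = 1e-6)
})

test_that("the first integral y = y0 (x/x0)^c holds along every trajectory", {
  withr::with_seed(14, {
    for (i in 1:5) {
      cc <- runif(1, 1.1, 2.8)
      K <- 10^runif(1, 8, 11)
      x0 <- 10^runif(1, 4, 6)
      y0 <- 10^runif(1, 2, 5)
      sp <- sigmoidal_params(r = runif(1, 0.005, 0.1), c = cc, K = K)
      tr <- solve_sigmoidal(sp, x0 = x0, y0 = y0)
      rel <- abs(tr$y / (y0 * (tr$x / x0)^cc) - 1)
      expect_lt(max(rel), 1e-6)
      # total size nondecreasing and bounded by K
      expect_true(all(diff(tr$total) >= -1e-6 * K))
      expect_true(all(tr$total <= K * (1 + 1e-9)))
      # closed-form terminal fraction matches the integrated trajectory
      expect_equal(final_driver_fraction(sp, x0, y0),
                   tail(tr$driver_fraction, 1), tolerance = 1e-6)
    }
  })
})

test_that("the final driver fraction is monotone in the initial driver load", {
  sp <- sigmoidal_params(r = 0.01, g = 0.7, K = 1e11)
  total <- 1e6
  y0 <- seq(0, total, length.out = 21)[-21]
  f <- final_driver_fraction(sp, x0 = total - y0, y0 = y0)
  expect_true(all(diff(f) >= -1e-12))
})

test_that("the combined spatial-logistic pipeline scores the detection window", {
  lp <- lattice_params(b = 1, d = 0.5, g = 0.7, u = 1e-5)
  sp <- sigmoidal_params(r = 0.07, g = 0.7, K = 1e11, handoff_size = 2e5)
  det <- sigmoidal_detection(lp, sp, n_runs = 40, seed = 2)
  expect_gte(det$summary$p_det, 0)
  expect_lte(det$summary$p_det, 1)
  expect_equal(det$summary$n, 40)
  expect_equal(nrow(tidy(det)), 40)
  # the trivial window catches every accepted run
  det_all <- sigmoidal_detection(lp, sp, window = c(0, 1), n_runs = 40,
                                 seed = 2)
  expect_equal(det_all$summary$p_det, 1)
})
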