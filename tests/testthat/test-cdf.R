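fig_moderate <- function(g = 0.7, M = 1e8, u = 1e-5) {
  branching_params(b = 0.14, r = 0.01, g = g, u = u, M = M)
}

test_that("the frequency CDF is a proper, monotone distribution function", {
  p <- fig_moderate()
  expect_equal(cdf_subclonal_frequency(p, 0), 0)
  withr::with_seed(42, {
    for (pars in list(fig_moderate(0.3, 1e6), fig_moderate(1.0, 1e10),
                      branching_params(b = 0.5, r = 0.05, g = 0.2,
                                       u = 1e-6, M = 1e9))) {
      alphas <- sort(runif(12, 0, 1 - 1e-6))
      Fv <- cdf_subclonal_frequency(pars, alphas)
      expect_true(all(Fv >= 0 & Fv <= 1))
      expect_true(all(diff(Fv) >= -1e-12))
    }
  })
})

test_that("the CDF approaches its closed-form upper limit", {
  for (pars in list(fig_moderate(), fig_moderate(0.3, 1e6, 1e-6),
                    branching_params(b = 0.25, r = 0.07, g = 1, u = 1e-7, M = 1e9))) {
    expect_equal(cdf_subclonal_frequency(pars, 1 - 1e-9),
                 cdf_upper_limit(pars), tolerance = 1e-8)
  }
  # direct arithmetic: (c u / b1) M large makes the limit 1
  p <- branching_params(b = 0.14, r = 0.01, c = 1.3, u = 1e-5, M = 1e9)
  expect_equal(cdf_upper_limit(p), 1 - exp(-1.3e-5 / 0.14 * 1e9))
  expect_equal(cdf_upper_limit(p), 1)
  # no mutation, no driver mass
  p0 <- branching_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.123,
                         u = 0, M = 1e8)
  expect_equal(cdf_upper_limit(p0), 0)
  expect_equal(cdf_subclonal_frequency(p0, 0.5), 0)
})

test_that("vanishing mutation rate drives all frequency mass to zero", {
  # F[alpha] <= F[1-] = 1 - exp(-(cu/b1) M) -> 0 as u -> 0
  for (u in 10^c(-9, -11, -13)) {
    p <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = u, M = 1e6)
    expect_lte(cdf_subclonal_frequency(p, 0.9), cdf_upper_limit(p) + 1e-12)
    expect_lt(cdf_subclonal_frequency(p, 0.9), 2e-2)
  }
  expect_error(cdf_subclonal_frequency(fig_moderate(), 1), "alpha")
  expect_error(pdf_subclonal_frequency(fig_moderate(), 0), "alpha")
})

test_that("the density is the derivative of the CDF and integrates to it", {
  p <- fig_moderate()
  # central finite difference at alpha = 0.5
  h <- 1e-5
  fd <- (cdf_subclonal_frequency(p, 0.5 + h) -
           cdf_subclonal_frequency(p, 0.5 - h)) / (2 * h)
  expect_equal(pdf_subclonal_frequency(p, 0.5), fd, tolerance = 1e-4)

  # integral over the window equals the CDF difference
  pa <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
  ii <- stats::integrate(function(a) pdf_subclonal_frequency(pa, a),
                         0.2, 0.8, rel.tol = 1e-9)$value
  expect_equal(ii, diff(cdf_subclonal_frequency(pa, c(0.2, 0.8))),
               tolerance = 1e-6)

  # normalization of the continuous part (tail integrated in log(1 - alpha)
  # where the near-fixation mass concentrates)
  body <- stats::integrate(function(a) pdf_subclonal_frequency(pa, a),
                           0, 0.9, rel.tol = 1e-9)$value
  tail <- stats::integrate(function(w) {
    exp(w) * pdf_subclonal_frequency(pa, 1 - exp(w))
  }, log(1e-9), log(0.1), rel.tol = 1e-9)$value
  expect_equal(body + tail, cdf_upper_limit(pa), tolerance = 1e-6)

  # finite deep into the upper tail
  expect_true(is.finite(pdf_subclonal_frequency(pa, 1 - 1e-12)))
})

test_that("detection probability is the window mass of the CDF", {
  p <- fig_moderate(0.3, 1e9)
  expect_equal(detection_probability(p),
               diff(cdf_subclonal_frequency(p, c(0.2, 0.8))))
  expect_equal(detection_probability(p, c(0.5, 0.5)), 0)
  # published headline for moderate selection in a moderately growing tumor
  expect_lt(detection_probability(p), 0.15)
  # narrower window always captures less mass
  expect_lt(detection_probability(p, c(0.24, 0.48)), detection_probability(p))
})

test_that("driver mutation-rate bounds reproduce the published arithmetic", {
  bounds <- driver_mutation_rate_bounds()
  expect_equal(bounds$rate[bounds$bound == "upper"], 600 * 90 * 6e-8)
  expect_equal(bounds$rate[bounds$bound == "upper"], 3.24e-3)
  expect_equal(bounds$rate[bounds$bound == "lower"], 20 * 90 * 4e-11)
  expect_equal(bounds$rate[bounds$bound == "lower"], 7.2e-8)
  zero <- driver_mutation_rate_bounds(
    upper = rate_bound_inputs(0, 90, 6e-8),
    lower = rate_bound_inputs(0, 90, 4e-11))
  expect_equal(zero$rate, c(0, 0))
})

test_that("the frequency density is convex across the standard grid ranges", {
  withr::with_seed(21, {
    for (i in 1:6) {
      cc <- runif(1, 1.01, 3)
      b1 <- runif(1, 0.1, 1)
      r <- 10^runif(1, -3, -1)
      if (cc * r > b1) r <- b1 / cc * 0.9   # keep the tuple physical
      u <- 10^runif(1, -7, -3)
      M <- 10^runif(1, 7, 11)
      p <- branching_params(b = b1, d = b1 - r, b1 = b1, d1 = b1 - cc * r,
                            u = u, M = M)
      a <- seq(0.02, 0.98, by = 0.01)
      f <- pdf_subclonal_frequency(p, a)
      d2 <- diff(f, differences = 2)
      scale <- pmax(abs(f[-c(1, length(f))]), max(f) * 1e-6)
      expect_true(all(d2 >= -1e-5 * scale),
                  label = sprintf("convexity at c=%.2f b1=%.2f r=%.3g u=%.1g M=%.1g",
                                  cc, b1, r, u, M))
    }
  })
})
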