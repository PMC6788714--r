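test_that("runs without mutation are rejected under the standard policy", {
  lp <- lattice_params(b = 1, d = 0, d1 = 0, u = 0, cells_per_site = 1)
  expect_error(run_spatial(lp, sizes_cells = 50, n_runs = 2, seed = 1,
                           max_attempts = 25), "max_attempts")
  # with the null-experiment escape hatch the same runs are accepted
  s <- run_spatial(lp, sizes_cells = 50, n_runs = 5, seed = 1,
                   require_driver = FALSE)
  expect_true(all(s$runs$f_sub == 0))
  expect_false(any(s$meta$mutated))
})

test_that("identical seed reproduces the spatial sample exactly", {
  lp <- lattice_params(b = 1, d = 0.5, g = 1, u = 1e-3, cells_per_site = 1,
                       neighborhood = 6)
  s1 <- run_spatial(lp, sizes_cells = c(100, 400), n_runs = 10, seed = 42)
  s2 <- run_spatial(lp, sizes_cells = c(100, 400), n_runs = 10, seed = 42)
  expect_identical(s1$runs, s2$runs)
})

test_that("pure growth matches a naive single-site-updating reference", {
  # d = d1 = 0, u = 0: compare the distribution of the time to grow from
  # one cell to 8 cells against an unoptimized reference implementation
  lp <- lattice_params(b = 1, d = 0, d1 = 0, u = 0, cells_per_site = 1,
                       neighborhood = 6)
  s <- run_spatial(lp, sizes_cells = 8, n_runs = 400, seed = 6,
                   require_driver = FALSE)
  t_fast <- s$runs$t
  withr::with_seed(8, {
    t_ref <- replicate(400, naive_lattice_growth_time(8))
  })
  se <- sqrt(stats::var(t_fast) / 400 + stats::var(t_ref) / 400)
  expect_lt(abs(mean(t_fast) - mean(t_ref)), 3 * se)
  ks <- suppressWarnings(stats::ks.test(t_fast, t_ref))
  expect_gt(ks$p.value, 0.001)
})

test_that("at most one driver clone exists and fractions are recorded per size", {
  lp <- lattice_params(b = 1, d = 0.5, g = 1, u = 5e-3, cells_per_site = 1,
                       neighborhood = 26)
  s <- run_spatial(lp, sizes_cells = c(200, 800), n_runs = 30, seed = 9)
  expect_true(all(s$meta$mutated))
  expect_equal(nrow(s$runs), 60)
  expect_true(all(s$runs$f_sub >= 0 & s$runs$f_sub <= 1))
  # recording times are ordered with size within each run
  wide <- tidyr::pivot_wider(s$runs, id_cols = "run",
                             names_from = "size_cells", values_from = "t")
  expect_true(all(wide[[2]] < wide[[3]]))
})

test_that("detection_from_sample counts window membership with binomial error", {
  expect_equal(detection_from_sample(c(0.5, 0.5, 0.5))$p_det, 1)
  expect_equal(detection_from_sample(c(0.1, 0.9))$p_det, 0)
  expect_error(detection_from_sample(numeric(0)), "empty")
  withr::with_seed(4, u <- runif(500))
  d <- detection_from_sample(u, detection_window(0.2, 0.8))
  expect_lt(abs(d$p_det - 0.6), 3 * d$sem + 3 * sqrt(0.6 * 0.4 / 500))
})

test_that("driver-extinct runs follow the configured acceptance policy", {
  lp <- lattice_params(b = 1, d = 0.5, g = 0.3, u = 2e-3, cells_per_site = 1,
                       neighborhood = 26)
  acc <- run_spatial(lp, sizes_cells = 300, n_runs = 40, seed = 10)
  # default: driver-produced-but-extinct runs are accepted with f_sub = 0
  expect_true(any(acc$runs$f_sub == 0))
  strict <- run_spatial(lp, sizes_cells = 300, n_runs = 40, seed = 10,
                        reject_driver_extinct = TRUE)
  expect_true(all(strict$runs$f_sub > 0))
  expect_gt(strict$n_rejected_driverless, 0)
})
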