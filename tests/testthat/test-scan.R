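test_that("grid construction has the right cardinality, order and exclusions", {
  # full published resolution: 100 points per axis, 1e10 combinations
  expect_equal(grid_size(grid_spec(n_points = 100)), 1e10)
  expect_error(build_grid(grid_spec(n_points = 100)), "max_tuples")

  # single tuple, not excluded
  g1 <- build_grid(grid_spec(c_range = c(1.3, 1.3), u_range = c(1e-5, 1e-5),
                             M_range = c(1e9, 1e9), b1_range = c(0.14, 0.14),
                             r_range = c(0.01, 0.01), n_points = 1))
  expect_equal(nrow(g1), 1)
  expect_false(g1$excluded)

  # corner with implied negative driver death rate is excluded, not clamped
  g2 <- build_grid(grid_spec(c_range = c(3, 3), u_range = c(1e-5, 1e-5),
                             M_range = c(1e9, 1e9), b1_range = c(0.1, 0.1),
                             r_range = c(0.1, 0.1), n_points = 1))
  expect_true(g2$excluded)

  g3 <- build_grid(grid_spec(n_points = 3))
  expect_equal(nrow(g3), 3^5)
  expect_equal(sum(g3$excluded) + sum(!g3$excluded), 3^5)
  # log-spaced axes hit the endpoints (up to floating point)
  expect_equal(sort(unique(g3$u)), c(1e-7, 1e-5, 1e-3), tolerance = 1e-12)
  expect_equal(sort(unique(g3$c)), c(1.01, 2.005, 3), tolerance = 1e-12)
})

test_that("a one-tuple scan equals the direct detection probability", {
  sc <- scan_detection(grid_spec(c_range = c(1.7, 1.7), u_range = c(1e-5, 1e-5),
                                 M_range = c(1e8, 1e8), b1_range = c(0.14, 0.14),
                                 r_range = c(0.01, 0.01), n_points = 1))
  p <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
  expect_equal(sc$p_det, detection_probability(p), tolerance = 1e-7)
})

test_that("scan results are a pure function of the tuple, not of row order", {
  grid <- build_grid(grid_spec(n_points = 3))
  sc <- scan_detection(grid)
  withr::with_seed(7, perm <- sample.int(nrow(grid)))
  sc_perm <- scan_detection(grid[perm, ])
  expect_equal(sc_perm$p_det, sc$p_det[perm])
  gl <- glance(sc)
  expect_equal(gl$n_evaluated + gl$n_excluded, 3^5)
  expect_true(all(sc$p_det[!sc$excluded] >= 0 & sc$p_det[!sc$excluded] <= 1))
})

test_that("the narrow window is dominated by the wide one at every tuple", {
  grid <- build_grid(grid_spec(n_points = 3))
  grid <- grid[!grid$excluded, ]
  withr::with_seed(3, grid <- grid[sample.int(nrow(grid), 40), ])
  wide <- scan_detection(grid, detection_window(0.2, 0.8))
  narrow <- scan_detection(grid, detection_window(0.24, 0.48))
  expect_true(all(narrow$p_det <= wide$p_det + 1e-10))
})

test_that("detection-vs-size curves match the published shape constraints", {
  M_grid <- 10^seq(5, 11, length.out = 25)
  cur <- detection_vs_size(b = 0.14, r = 0.01, u = 1e-5,
                           g_list = c(0.3, 0.7, 1.0), M_grid = M_grid)
  # moderate selection stays below one third up to 1e11 cells
  expect_lt(max(cur$p_det[cur$g == 0.3]), 1 / 3)
  # very strong selection peaks at smaller tumors than strong selection
  peak_M <- function(g) {
    d <- cur[cur$g == g, ]
    d$M[which.max(d$p_det)]
  }
  expect_lt(peak_M(1.0), peak_M(0.7))
  # empty size grid gives an empty table
  empty <- detection_vs_size(b = 0.14, r = 0.01, u = 1e-5,
                             g_list = 0.7, M_grid = numeric(0))
  expect_equal(nrow(empty), 0)
})

test_that("detection probability vanishes for very large well-mixed tumors", {
  p_small <- detection_probability(
    branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8))
  p_seq <- vapply(c(1e10, 1e12, 1e14), function(M) {
    detection_probability(
      branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = M))
  }, numeric(1))
  expect_true(all(diff(p_seq) < 0))
  expect_lt(p_seq[3], 0.01)
  expect_lt(p_seq[3], p_small)
})

test_that("add_detection_probability augments a parameter tibble", {
  df <- tibble::tibble(b1 = 0.14, r = 0.01, g = c(0.3, 0.7), u = 1e-5, M = 1e8)
  out <- add_detection_probability(df)
  expect_named(out, c(names(df), "c", "p_det"), ignore.order = TRUE)
  expect_equal(out$p_det[2],
               detection_probability(
                 branching_params(b = 0.14, r = 0.01, g = 0.7,
                                  u = 1e-5, M = 1e8)),
               tolerance = 1e-7)
})
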