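test_that("survival fraction without mutation matches the birth-death closed form", {
  # a supercritical birth-death clone survives with probability r/b
  p0 <- branching_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.13,
                         u = 0, M = 1000)
  s <- run_branching(p0, n_runs = 300, seed = 7)
  g <- glance(s)
  p_hat <- g$survival_fraction
  p_exp <- 0.01 / 0.14
  se <- sqrt(p_exp * (1 - p_exp) / s$attempts)
  expect_lt(abs(p_hat - p_exp), 3 * se)
  # no mutation, no driver cells
  expect_true(all(s$runs$f_sub == 0))
})

test_that("identical configuration and seed reproduce the sample exactly", {
  p <- branching_params(b = 1, d = 0.5, g = 0.5, u = 1e-3, M = 5e3)
  s1 <- run_branching(p, n_runs = 40, seed = 123)
  s2 <- run_branching(p, n_runs = 40, seed = 123)
  expect_identical(s1$runs, s2$runs)
  s3 <- run_branching(p, n_runs = 40, seed = 124)
  expect_false(identical(s1$runs$f_sub, s3$runs$f_sub))
})

test_that("neutral driver clones stay rare in large populations", {
  # with c = 1 and M >> b1/u, late-arising neutral clones cannot take over:
  # mass near 0 exceeds mass near 1
  p <- branching_params(b = 1, d = 0.5, b1 = 1, d1 = 0.5, u = 1e-3, M = 2e4)
  s <- run_branching(p, n_runs = 400, seed = 5)
  expect_gt(mean(s$runs$f_sub < 0.2), mean(s$runs$f_sub > 0.8))
})

test_that("the empirical CDF and its bootstrap errors behave correctly", {
  expect_error(empirical_cdf(numeric(0), 0.5), "empty")
  const <- rep(0.5, 200)
  e <- empirical_cdf(const, c(0.4, 0.6), seed = 1)
  expect_equal(e$F_hat, c(0, 1))
  expect_equal(e$sem, c(0, 0))
  # uniform sample: F(0.5) ~ 0.5 with sem ~ sqrt(0.25/n)
  withr::with_seed(2, u <- runif(400))
  e2 <- empirical_cdf(u, 0.5, seed = 3)
  expect_equal(e2$F_hat, mean(u <= 0.5))
  expect_equal(e2$sem, sqrt(0.25 / 400), tolerance = 0.15)
  # deterministic given the bootstrap seed
  e3 <- empirical_cdf(u, 0.5, seed = 3)
  expect_identical(e2, e3)
})

test_that("analytic CDF matches simulation in a small, fast regime", {
  # desk-scale cross-check; the publication-scale panels are exercised in
  # the acceptance suite
  p <- branching_params(b = 0.25, r = 0.07, g = 0.7, u = 1e-4, M = 1e5)
  s <- run_branching(p, n_runs = 400, seed = 9)
  alphas <- seq(0.1, 0.9, by = 0.2)
  emp <- empirical_cdf(s, alphas, seed = 9)
  ana <- cdf_subclonal_frequency(p, alphas)
  expect_true(all(abs(emp$F_hat - ana) <= 3 * pmax(emp$sem, 1e-3)))
})

test_that("designation shortcut matches the ordered full simulation", {
  # same observable, two independent code paths: production path with the
  # first-surviving-lineage designation and two-phase loop, versus a plain
  # ordered multi-clone simulation with no shortcut at all
  p <- branching_params(b = 0.25, r = 0.07, g = 0.7, u = 1e-4, M = 3e4)
  s_prod <- run_branching(p, n_runs = 400, seed = 31)$runs$f_sub
  s_ref <- subdriver:::branching_sim_eq1_cpp(p$b, p$d, p$b1, p$d1, p$u, p$M,
                                             400L, 32)$f_sub
  ks <- suppressWarnings(stats::ks.test(s_prod, s_ref))
  expect_gt(ks$p.value, 0.001)
  se <- sqrt(stats::var(s_prod) / 400 + stats::var(s_ref) / 400)
  expect_lt(abs(mean(s_prod) - mean(s_ref)), 3 * se)
})
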