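# internal: run code with a private RNG state, restoring the caller's
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Exact Gillespie simulation of the two-type branching process
#'
#' Stochastic simulation of tumor growth with a single driver type: type-0
#' cells divide (`b`), die (`d`) and mutate to type-1 (`u`); type-1 cells
#' divide (`b1`) and die (`d1`). Counts are aggregated, making the exact
#' algorithm feasible up to `M` of order `1e8`. Nascent driver clones are
#' tracked in founding order until the oldest surviving clone becomes
#' certain to survive drift (its extinction probability `(d1/b1)^n` falls
#' below `survivor_threshold_prob`); from then on only that first surviving
#' lineage is followed -- the observable the analytic frequency
#' distribution describes. Runs in which the whole population dies out are
#' rejected and restarted, and their count reported; if no clone ever
#' reaches the survivor threshold, the final driver fraction sums all
#' living driver clones.
#'
#' Each run uses an independent counter-based RNG stream derived from
#' `(seed, run index)`, so results are reproducible and independent of
#' execution order.
#'
#' @param params A [branching_params()]; `u = 0` gives a null model useful
#'   for survival-probability checks.
#' @param n_runs Number of surviving runs to collect.
#' @param seed Integer master seed.
#' @param survivor_threshold_prob Extinction-probability threshold below
#'   which a driver clone is designated as surviving.
#' @param track_time If `TRUE`, accumulate exact event times (slower).
#' @param max_attempts Safety cap on total attempted runs.
#' @return An object of class `driver_freq_sample`: a list with `runs` (a
#'   tibble: `run`, `f_sub`, `rejected_before`, `survivor_designated` and,
#'   if tracked, `t_final`), the total `n_rejected`, `seed` and `params`.
#'   `tidy()` returns the run table, `glance()` a one-row summary,
#'   `autoplot()` the empirical CDF.
#' @examples
#' p <- branching_params(b = 1, d = 0.5, g = 0.5, u = 1e-3, M = 1e4)
#' s <- run_branching(p, n_runs = 50, seed = 1)
#' glance(s)
#' @export
run_branching <- function(params, n_runs, seed,
                          survivor_threshold_prob = 1e-6,
                          track_time = FALSE,
                          max_attempts = 1e9) {
  stopifnot(inherits(params, "branching_params"), n_runs >= 1)
  res <- branching_sim_cpp(params$b, params$d, params$b1, params$d1,
                           params$u, params$M, as.integer(n_runs),
                           as.double(seed), survivor_threshold_prob,
                           track_time, max_attempts)
  runs <- tibble::tibble(
    run = seq_len(n_runs),
    f_sub = res$f_sub,
    rejected_before = res$rejected_before,
    survivor_designated = res$survivor_designated
  )
  if (track_time) runs$t_final <- res$t_final
  structure(
    list(runs = runs,
         n_rejected = sum(res$rejected_before),
         attempts = res$attempts,
         seed = seed,
         params = params),
    class = "driver_freq_sample"
  )
}

#' @export
print.driver_freq_sample <- function(x, ...) {
  cat(sprintf(
    "Driver frequency sample: %d surviving runs (%d rejected), seed %s\n",
    nrow(x$runs), x$n_rejected, format(x$seed)))
  print(x$params)
  invisible(x)
}

#' @rdname run_branching
#' @param x,object A `driver_freq_sample`.
#' @param ... Unused.
#' @method tidy driver_freq_sample
#' @export
tidy.driver_freq_sample <- function(x, ...) x$runs

#' @rdname run_branching
#' @method glance driver_freq_sample
#' @export
glance.driver_freq_sample <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x$runs),
    n_rejected = x$n_rejected,
    survival_fraction = nrow(x$runs) / x$attempts,
    mean_f_sub = mean(x$runs$f_sub),
    median_f_sub = stats::median(x$runs$f_sub),
    prop_survivor_designated = mean(x$runs$survivor_designated)
  )
}

#' @rdname run_branching
#' @method autoplot driver_freq_sample
#' @export
autoplot.driver_freq_sample <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = .data$f_sub)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "driver frequency f_sub", y = "empirical CDF") +
    ggplot2::theme_minimal()
}

#' Empirical CDF of driver frequency with bootstrap errors
#'
#' Evaluates the empirical cumulative distribution of simulated driver
#' fractions at the requested frequencies and attaches a bootstrap standard
#' error of the mean at each point (joint resampling of runs, so errors are
#' consistent across frequencies).
#'
#' @param sample A `driver_freq_sample` from [run_branching()] or a numeric
#'   vector of frequencies.
#' @param alphas Frequencies at which to evaluate the CDF.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Seed for the bootstrap resampling.
#' @return A tibble with columns `alpha`, `F_hat`, `sem`.
#' @examples
#' empirical_cdf(c(0.1, 0.4, 0.9, 0.95), alphas = c(0.2, 0.5, 0.8), seed = 1)
#' @export
empirical_cdf <- function(sample, alphas, n_boot = 1000, seed = 1) {
  f <- if (inherits(sample, "driver_freq_sample")) sample$runs$f_sub
       else as.numeric(sample)
  if (length(f) == 0) stop("empty sample", call. = FALSE)
  stopifnot(n_boot >= 100)
  n <- length(f)
  F_hat <- vapply(alphas, function(a) mean(f <= a), numeric(1))
  sem <- with_local_seed(seed, {
    boot <- matrix(0, nrow = n_boot, ncol = length(alphas))
    for (b in seq_len(n_boot)) {
      fs <- f[sample.int(n, n, replace = TRUE)]
      boot[b, ] <- vapply(alphas, function(a) mean(fs <= a), numeric(1))
    }
    apply(boot, 2, stats::sd)
  })
  tibble::tibble(alpha = alphas, F_hat = F_hat, sem = sem)
}

#' Three-type (two sequential drivers) Gillespie simulation
#'
#' Brute-force aggregated-count simulation with wild-type cells, first-driver
#' cells and second-driver cells; both mutation steps occur at per-cell rate
#' `u`. The clone bookkeeping mirrors [run_branching()] and the analytic
#' convention: each driver stage is tracked as nascent clones until one is
#' certain to survive drift, after which only that clone is followed and the
#' next mutation stage opens inside it. Used as the independent Monte-Carlo
#' check of the two-driver detection formula.
#'
#' @param params A [branching_params()] for the wild type and first driver.
#' @param delta_r Net growth-rate increment of the second driver (per day).
#' @param n_runs Surviving runs to collect.
#' @param seed Integer master seed.
#' @param survivor_threshold_prob Extinction-probability threshold for clone
#'   designation, as in [run_branching()].
#' @param max_attempts Safety cap on attempted runs.
#' @return A tibble with one row per surviving run: `f_first` (frequency of
#'   the first-driver lineage, second-driver cells included) and `f_second`.
#' @export
run_three_type <- function(params, delta_r, n_runs, seed,
                           survivor_threshold_prob = 1e-6,
                           max_attempts = 1e9) {
  stopifnot(inherits(params, "branching_params"), delta_r > 0)
  b2 <- params$b1
  d2 <- params$b1 - (params$r1 + delta_r)
  if (d2 < 0) stop("delta_r implies a negative second-driver death rate",
                   call. = FALSE)
  res <- three_type_sim_cpp(params$b, params$d, params$b1, params$d1,
                            b2, d2, params$u, params$M,
                            as.integer(n_runs), as.double(seed),
                            survivor_threshold_prob, max_attempts)
  tibble::tibble(run = seq_len(n_runs),
                 f_first = res$f_first,
                 f_second = res$f_second)
}
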