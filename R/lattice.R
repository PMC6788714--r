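#' Parameters of the 3d lattice tumor-growth model
#'
#' Cells occupy sites of a simple cubic lattice. Every cell replicates at
#' rate `b` times its fraction of empty neighbor sites (a fully surrounded
#' cell cannot replicate) and dies at rate `d` (wild type) or `d1` (driver).
#' A replication of a wild-type cell produces a driver daughter with
#' probability `u_site / b`, after which further mutations are forbidden, so
#' at most one driver clone exists per tumor.
#'
#' To reach realistic tumor sizes, one lattice site represents
#' `cells_per_site` cells (default 100) and the mutation rate is scaled up
#' by the same factor (`u_site = u * cells_per_site`); reported sizes are in
#' cells.
#'
#' @param b Birth rate (per day), shared by both types.
#' @param d Wild-type death rate (per day, `d < b`).
#' @param d1 Driver death rate; omit if `g` is given, in which case
#'   `d1 = b - (1 + g) * (b - d)`.
#' @param g Relative growth advantage of the driver.
#' @param u Driver mutation rate per cell per day.
#' @param cells_per_site Site-to-cell scaling factor.
#' @param neighborhood 26 (Moore, default) or 6 (von Neumann). The 26-site
#'   neighborhood keeps all standard regimes above the contact-process
#'   growth threshold; with 6 neighbors a high death rate (d/b > ~0.76)
#'   is subcritical and the tumor cannot grow.
#' @return An object of class `lattice_params`.
#' @examples
#' lattice_params(b = 1, d = 0.7, g = 0.7, u = 1e-5)
#' @export
lattice_params <- function(b = 1, d, d1 = NULL, g = NULL, u = 1e-5,
                           cells_per_site = 100, neighborhood = 26) {
  stopifnot(b > 0, d >= 0, d < b, u >= 0, cells_per_site >= 1)
  if (!neighborhood %in% c(6, 26))
    stop("neighborhood must be 6 or 26", call. = FALSE)
  if (is.null(d1)) {
    if (is.null(g)) stop("supply `d1` or `g`", call. = FALSE)
    d1 <- b - (1 + g) * (b - d)
    if (d1 < -1e-12)
      stop(sprintf("implied driver death rate d1 = %.4g is negative", d1),
           call. = FALSE)
    d1 <- max(d1, 0)
  }
  if (d1 >= b) stop("driver must be viable: d1 < b", call. = FALSE)
  c <- (b - d1) / (b - d)
  u_site <- u * cells_per_site
  if (u_site / b > 1)
    stop("scaled mutation probability u*cells_per_site/b exceeds 1", call. = FALSE)
  structure(
    list(b = b, d = d, d1 = d1, u = u, cells_per_site = cells_per_site,
         u_site = u_site, c = c, g = c - 1,
         neighborhood = as.integer(neighborhood)),
    class = "lattice_params"
  )
}

#' @export
print.lattice_params <- function(x, ...) {
  cat("3d lattice tumor model (rates per day)\n")
  cat(sprintf("  b = %g, d = %g, d1 = %g (c = %g, g = %g%%)\n",
              x$b, x$d, x$d1, x$c, 100 * x$g))
  cat(sprintf("  u = %g per cell (1 site = %g cells, u_site = %g)\n",
              x$u, x$cells_per_site, x$u_site))
  cat(sprintf("  %d-neighbor cubic lattice\n", x$neighborhood))
  invisible(x)
}

#' Simulate 3d lattice tumor growth with a single driver
#'
#' Event-driven stochastic simulation on the cubic lattice (see
#' [lattice_params()]). The driver fraction is recorded at the first moment
#' the tumor reaches each requested size, so one run yields the entire size
#' sweep. Runs are rejected and restarted if the population goes extinct or
#' if no driver mutation was ever produced; by default a run whose driver
#' clone was produced but died out is accepted with driver fraction 0
#' (`reject_driver_extinct = TRUE` applies the stricter reading).
#'
#' @param lparams A [lattice_params()].
#' @param sizes_cells Tumor sizes (in cells) at which to record the driver
#'   fraction; converted to sites internally and must be multiples of
#'   `cells_per_site`.
#' @param n_runs Accepted runs to collect.
#' @param seed Integer master seed.
#' @param reject_driver_extinct Reject runs whose driver clone died out.
#' @param require_driver Reject runs that never produced a driver mutation
#'   (the standard policy); set `FALSE` for null experiments with `u = 0`.
#' @param track_time Accumulate exact event times (adds an exponential draw
#'   per event; disable for large screens where times are unused).
#' @param max_attempts Safety cap on attempted runs.
#' @return An object of class `spatial_freq_sample`: list with `runs` (a
#'   long tibble: `run`, `size_cells`, `f_sub`, `t`), per-run `meta`
#'   (mutation produced / driver alive at final size, rejection counts),
#'   counts of rejected runs, `seed` and `lparams`.
#' @examples
#' lp <- lattice_params(b = 1, d = 0.5, g = 1, u = 1e-3, cells_per_site = 1)
#' s <- run_spatial(lp, sizes_cells = c(100, 500), n_runs = 5, seed = 1)
#' tidy(s)
#' @export
run_spatial <- function(lparams, sizes_cells, n_runs, seed,
                        reject_driver_extinct = FALSE,
                        require_driver = TRUE,
                        track_time = TRUE,
                        max_attempts = 1e7) {
  stopifnot(inherits(lparams, "lattice_params"), n_runs >= 1)
  sizes_cells <- sort(unique(sizes_cells))
  sites <- sizes_cells / lparams$cells_per_site
  if (any(abs(sites - round(sites)) > 1e-8))
    stop("sizes_cells must be multiples of cells_per_site", call. = FALSE)
  sites <- as.integer(round(sites))
  if (any(sites < 2)) stop("sizes must be at least 2 sites", call. = FALSE)

  res <- lattice_sim_cpp(lparams$b, lparams$d, lparams$d1,
                         lparams$u_site / lparams$b, sites,
                         as.integer(n_runs), as.double(seed),
                         lparams$neighborhood, reject_driver_extinct,
                         require_driver, track_time, max_attempts)
  runs <- tibble::tibble(
    run = rep(seq_len(n_runs), times = length(sites)),
    size_cells = rep(sizes_cells, each = n_runs),
    f_sub = as.vector(res$f_at_size),
    t = as.vector(res$t_at_size)
  )
  meta <- tibble::tibble(
    run = seq_len(n_runs),
    mutated = res$mutated,
    driver_alive = res$driver_alive,
    rejected_extinct_before = res$rejected_extinct,
    rejected_driverless_before = res$rejected_driverless
  )
  structure(
    list(runs = runs, meta = meta,
         n_rejected_extinct = sum(res$rejected_extinct),
         n_rejected_driverless = sum(res$rejected_driverless),
         attempts = res$attempts,
         seed = seed, lparams = lparams),
    class = "spatial_freq_sample"
  )
}

#' @export
print.spatial_freq_sample <- function(x, ...) {
  cat(sprintf(
    "Spatial driver frequency sample: %d accepted runs (%d extinct, %d driverless rejected)\n",
    max(x$runs$run), x$n_rejected_extinct, x$n_rejected_driverless))
  print(x$lparams)
  invisible(x)
}

#' @rdname run_spatial
#' @param x,object A `spatial_freq_sample`.
#' @param ... Unused.
#' @method tidy spatial_freq_sample
#' @export
tidy.spatial_freq_sample <- function(x, ...) x$runs

#' @rdname run_spatial
#' @method glance spatial_freq_sample
#' @export
glance.spatial_freq_sample <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$runs, .data$size_cells),
    n = dplyr::n(),
    mean_f_sub = mean(.data$f_sub),
    prop_driver_present = mean(.data$f_sub > 0),
    .groups = "drop"
  )
}

#' @rdname run_spatial
#' @method autoplot spatial_freq_sample
#' @export
autoplot.spatial_freq_sample <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = .data$f_sub,
                               color = factor(.data$size_cells))) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "driver frequency f_sub", y = "empirical CDF",
                  color = "tumor size (cells)") +
    ggplot2::theme_minimal()
}

#' Detection probability from an empirical frequency sample
#'
#' Fraction of runs whose driver frequency lies inside the window, with a
#' binomial standard error. Accepts a bare numeric vector of frequencies, a
#' `driver_freq_sample`, or a `spatial_freq_sample` (in which case the
#' fraction is computed per recorded tumor size).
#'
#' @param sample Frequencies, or a simulation result object.
#' @param window A [detection_window()] or numeric `c(lo, hi)`.
#' @return A tibble with columns `p_det`, `sem`, `n` (and `size_cells` for
#'   spatial samples).
#' @examples
#' detection_from_sample(c(0.1, 0.5, 0.9), detection_window())
#' @export
detection_from_sample <- function(sample, window = detection_window()) {
  window <- as_detection_window(window)
  in_win <- function(f) f >= window[["lo"]] & f <= window[["hi"]]
  binom <- function(f) {
    n <- length(f)
    if (n == 0) stop("empty sample", call. = FALSE)
    p <- mean(in_win(f))
    tibble::tibble(p_det = p, sem = sqrt(p * (1 - p) / n), n = n)
  }
  if (inherits(sample, "spatial_freq_sample")) {
    dplyr::reframe(dplyr::group_by(sample$runs, .data$size_cells),
                   binom(.data$f_sub))
  } else if (inherits(sample, "driver_freq_sample")) {
    binom(sample$runs$f_sub)
  } else {
    binom(as.numeric(sample))
  }
}
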