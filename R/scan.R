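#' Specification of a 5-dimensional parameter grid
#'
#' Axes of the detection-probability grid over the growth-ratio `c`, the
#' driver mutation rate `u`, the tumor size `M`, the driver division rate
#' `b1` and the wild-type net growth rate `r`. The default ranges cover all
#' biologically plausible values: `c` in `[1.01, 3]` (driver advantage 1% to
#' 200%), `u` in `[1e-7, 1e-3]` per day, `M` in `[1e7, 1e11]` cells, `b1` in
#' `[0.1, 1]` per day and `r` in `[0.001, 0.1]` per day. `u`, `M` and `r`
#' are spaced equally in log space, `c` and `b1` linearly.
#'
#' @param c_range,u_range,M_range,b1_range,r_range Length-2 numeric ranges.
#' @param n_points Points per axis: a single count or a named vector/list
#'   with entries for `c`, `u`, `M`, `b1`, `r`.
#' @return An object of class `grid_spec`: a tibble with one row per axis
#'   (`name`, `low`, `high`, `n_points`, `spacing`).
#' @examples
#' grid_spec(n_points = 12)
#' grid_size(grid_spec(n_points = 100))  # 1e10 combinations
#' @export
grid_spec <- function(c_range = c(1.01, 3),
                      u_range = c(1e-7, 1e-3),
                      M_range = c(1e7, 1e11),
                      b1_range = c(0.1, 1),
                      r_range = c(0.001, 0.1),
                      n_points = 100) {
  ranges <- list(c = c_range, u = u_range, M = M_range,
                 b1 = b1_range, r = r_range)
  spacing <- c(c = "linear", u = "log", M = "log", b1 = "linear", r = "log")
  if (length(n_points) == 1) n_points <- stats::setNames(rep(n_points, 5), names(ranges))
  np <- unlist(n_points)[names(ranges)]
  if (anyNA(np)) stop("n_points must name all of c, u, M, b1, r", call. = FALSE)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || !(rg[1] < rg[2] || (np[[nm]] == 1 && rg[1] <= rg[2])))
      stop(sprintf("invalid range for axis %s", nm), call. = FALSE)
    if (np[[nm]] < 1) stop("n_points must be >= 1", call. = FALSE)
  }
  out <- tibble::tibble(
    name = names(ranges),
    low = vapply(ranges, `[`, numeric(1), 1),
    high = vapply(ranges, `[`, numeric(1), 2),
    n_points = as.integer(np),
    spacing = unname(spacing[names(ranges)])
  )
  class(out) <- c("grid_spec", class(out))
  out
}

axis_values <- function(low, high, n, spacing) {
  if (n == 1) return(low)
  if (spacing == "log") exp(seq(log(low), log(high), length.out = n))
  else seq(low, high, length.out = n)
}

#' Cardinality of a grid without materializing it
#'
#' @param spec A [grid_spec()].
#' @return The number of parameter tuples (a double, since full-resolution
#'   grids exceed integer range).
#' @export
grid_size <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  prod(as.numeric(spec$n_points))
}

#' Materialize a parameter grid
#'
#' Builds the cartesian product of the axis values in a deterministic order
#' (the first axis varies slowest). Tuples whose implied type-1 death rate
#' `d1 = b1 - c*r` would be negative are flagged `excluded` rather than
#' clamped: negative death rates are unphysical, and exclusion keeps the
#' scan's accounting transparent (`excluded + evaluated = grid size`).
#'
#' @param spec A [grid_spec()].
#' @param max_tuples Safety cap on the materialized size.
#' @return A tibble with columns `c`, `u`, `M`, `b1`, `r`, `excluded`.
#' @examples
#' build_grid(grid_spec(n_points = 3))
#' @export
build_grid <- function(spec, max_tuples = 5e6) {
  stopifnot(inherits(spec, "grid_spec"))
  n <- grid_size(spec)
  if (n > max_tuples)
    stop(sprintf("grid has %.3g tuples, above max_tuples = %.3g; use grid_size() for cardinality checks",
                 n, max_tuples), call. = FALSE)
  vals <- purrr::pmap(spec, function(name, low, high, n_points, spacing) {
    axis_values(low, high, n_points, spacing)
  })
  names(vals) <- spec$name
  grid <- rev(expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE))
  grid <- tibble::as_tibble(grid)
  grid$excluded <- grid$b1 - grid$c * grid$r < 0
  grid
}

#' Detection probability over a parameter grid
#'
#' Evaluates `P_det = F[hi] - F[lo]` at every non-excluded tuple of the
#' grid. The result is a pure function of the tuple, so values are
#' independent of row order or parallel chunking.
#'
#' @param grid A [grid_spec()] (materialized internally) or a tibble from
#'   [build_grid()] (or any tibble with columns `c`, `u`, `M`, `b1`, `r`).
#' @param window A [detection_window()] or numeric `c(lo, hi)`.
#' @param quad A [quad_spec()]; the scan default trades a little tolerance
#'   for speed, ample for bound checks.
#' @return A tibble of class `driver_scan`: the grid columns plus `p_det`
#'   (`NA` for excluded tuples). Use [glance()] for the scan summary
#'   (maximum, argmax, exclusion counts).
#' @examples
#' sc <- scan_detection(grid_spec(n_points = 3))
#' glance(sc)
#' @export
scan_detection <- function(grid, window = detection_window(),
                           quad = quad_spec(rel_tol = 1e-8)) {
  if (inherits(grid, "grid_spec")) grid <- build_grid(grid)
  stopifnot(all(c("c", "u", "M", "b1", "r") %in% names(grid)))
  if (!"excluded" %in% names(grid))
    grid$excluded <- grid$b1 - grid$c * grid$r < 0
  window <- as_detection_window(window)

  p <- rep(NA_real_, nrow(grid))
  idx <- which(!grid$excluded)
  cs <- grid$c; us <- grid$u; Ms <- grid$M; b1s <- grid$b1; rs <- grid$r
  p[idx] <- vapply(idx, function(i) {
    pr <- branching_params(b = b1s[i], d = b1s[i] - rs[i], b1 = b1s[i],
                           d1 = b1s[i] - cs[i] * rs[i], u = us[i], M = Ms[i])
    tryCatch(
      detection_probability(pr, window, quad),
      error = function(e) stop(sprintf(
        "quadrature failure at tuple (c=%g, u=%g, M=%g, b1=%g, r=%g): %s",
        cs[i], us[i], Ms[i], b1s[i], rs[i], conditionMessage(e)),
        call. = FALSE)
    )
  }, numeric(1))
  out <- dplyr::mutate(grid, p_det = p)
  class(out) <- c("driver_scan", class(out))
  attr(out, "window") <- unclass(window)
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Summary of a detection-probability scan
#'
#' @param x A `driver_scan` tibble from [scan_detection()].
#' @param ... Unused.
#' @return A one-row tibble: evaluated/excluded counts, the maximum `p_det`
#'   and its coordinates.
#' @method glance driver_scan
#' @export
glance.driver_scan <- function(x, ...) {
  ev <- dplyr::filter(x, !.data$excluded)
  i <- which.max(ev$p_det)
  tibble::tibble(
    n_tuples = nrow(x),
    n_evaluated = nrow(ev),
    n_excluded = sum(x$excluded),
    max_p_det = ev$p_det[i],
    at_c = ev$c[i], at_u = ev$u[i], at_M = ev$M[i],
    at_b1 = ev$b1[i], at_r = ev$r[i]
  )
}

#' Detection probability as a function of tumor size
#'
#' One detection-probability curve per selection strength: for each `g` in
#' `g_list` and each size in `M_grid`, evaluates the probability that the
#' driver sits in the detection window.
#'
#' @param b,r Wild-type birth and net growth rate (per day).
#' @param u Driver mutation rate (per day).
#' @param g_list Relative growth advantages of the driver.
#' @param M_grid Tumor sizes (cells); typically log-spaced.
#' @param b1 Driver division rate; defaults to `b`.
#' @param window,quad See [detection_probability()].
#' @return A tibble of class `driver_curve` with columns `b`, `r`, `u`,
#'   `g`, `M`, `p_det`. Plot with [ggplot2::autoplot()].
#' @examples
#' detection_vs_size(b = 0.14, r = 0.01, u = 1e-5, g_list = 0.7,
#'                   M_grid = 10^seq(5, 10, by = 1))
#' @export
detection_vs_size <- function(b, r, u, g_list, M_grid, b1 = b,
                              window = detection_window(),
                              quad = quad_spec(rel_tol = 1e-8)) {
  window <- as_detection_window(window)
  out <- tidyr::expand_grid(g = g_list, M = M_grid)
  out$p_det <- purrr::map2_dbl(out$g, out$M, function(g, M) {
    pr <- branching_params(b = b, r = r, g = g, b1 = b1, u = u, M = M)
    detection_probability(pr, window, quad)
  })
  out <- dplyr::mutate(out, b = b, r = r, u = u, .before = 1)
  class(out) <- c("driver_curve", class(out))
  attr(out, "window") <- unclass(window)
  out
}

#' @rdname detection_vs_size
#' @param object A `driver_curve` tibble.
#' @param ... Unused.
#' @method autoplot driver_curve
#' @export
autoplot.driver_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$M, y = .data$p_det,
                               color = factor(100 * .data$g))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "tumor size M (cells)",
                  y = "P(driver in detection window)",
                  color = "driver advantage g (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram view of a grid scan
#'
#' @param object A `driver_scan` tibble.
#' @param ... Unused.
#' @method autoplot driver_scan
#' @export
autoplot.driver_scan <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !.data$excluded),
                  ggplot2::aes(x = .data$p_det)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey30") +
    ggplot2::labs(x = "P(driver in detection window)", y = "tuples") +
    ggplot2::theme_minimal()
}

#' Add detection probabilities to a parameter table
#'
#' Data-frame-first wrapper: takes any tibble with columns `b1`, `r`, `c`
#' (or `g`), `u`, `M` and appends a `p_det` column.
#'
#' @param data A data frame of parameter tuples.
#' @param window,quad See [detection_probability()].
#' @return `data` with an added `p_det` column.
#' @export
add_detection_probability <- function(data, window = detection_window(),
                                      quad = quad_spec(rel_tol = 1e-8)) {
  stopifnot(is.data.frame(data))
  if (!"c" %in% names(data) && "g" %in% names(data)) data$c <- 1 + data$g
  stopifnot(all(c("b1", "r", "c", "u", "M") %in% names(data)))
  window <- as_detection_window(window)
  data$p_det <- vapply(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    pr <- branching_params(b = row$b1, d = row$b1 - row$r, b1 = row$b1,
                           d1 = row$b1 - row$c * row$r, u = row$u, M = row$M)
    detection_probability(pr, window, quad)
  }, numeric(1))
  tibble::as_tibble(data)
}
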