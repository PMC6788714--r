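#' Lattice analogues of the growth regimes
#'
#' Death rates of the wild type in the 3d lattice model for the moderate,
#' fast and slow growth regimes (`d = 0.7`, `0.5`, `0.9`), with birth rate
#' `b = 1` for all cells.
#'
#' @return A tibble with columns `regime`, `b`, `d`.
#' @examples
#' lattice_regimes()
#' @export
lattice_regimes <- function() {
  tibble::tibble(
    regime = c("moderate", "fast", "slow"),
    b = 1,
    d = c(0.7, 0.5, 0.9)
  )
}

#' Sweep of one- and two-driver detection probabilities
#'
#' For each growth regime, selection strength and tumor size, computes the
#' probability `P1` that the first driver lies in the detection window and
#' the probability `P2` that the second driver does while the first is
#' above it (see [two_driver_detection()]); the second driver adds the same
#' absolute growth increment `g * r` as the first.
#'
#' @param regimes Tibble with columns `regime`, `b`, `r`
#'   (default [growth_regimes()]); `b1 = b`.
#' @param g_list Relative growth advantages of the first driver.
#' @param M_grid Tumor sizes (cells); default 25 log-spaced sizes from
#'   `1e6` to `1e11`.
#' @param u Driver mutation rate (per day).
#' @param window A [detection_window()] or numeric `c(lo, hi)`.
#' @param quad A [quad_spec()].
#' @return A tibble with columns `regime`, `b`, `r`, `g`, `M`, `P1`, `P2`,
#'   `total` (`P1 + P2`).
#' @examples
#' \donttest{
#' two_driver_sweep(M_grid = 10^seq(6, 11, length.out = 6))
#' }
#' @export
two_driver_sweep <- function(regimes = growth_regimes(),
                             g_list = c(0.3, 0.7, 1.0),
                             M_grid = 10^seq(6, 11, length.out = 25),
                             u = 1e-5,
                             window = detection_window(),
                             quad = quad_spec(rel_tol = 1e-7)) {
  stopifnot(all(c("regime", "b", "r") %in% names(regimes)))
  window <- as_detection_window(window)
  out <- tidyr::expand_grid(regimes, g = g_list, M = M_grid)
  res <- purrr::pmap(out[, c("b", "r", "g", "M")], function(b, r, g, M) {
    pr <- branching_params(b = b, r = r, g = g, u = u, M = M)
    P1 <- detection_probability(pr, window, quad)
    P2 <- two_driver_detection(pr, delta_r = g * r, window, quad)
    c(P1 = P1, P2 = P2)
  })
  out$P1 <- vapply(res, `[[`, numeric(1), "P1")
  out$P2 <- vapply(res, `[[`, numeric(1), "P2")
  out$total <- out$P1 + out$P2
  out
}

#' Average driver-detection probability over the standard sweep
#'
#' Mean of the total (first-or-second driver) detection probability over
#' the grid of 3 growth regimes x 3 selection strengths x log-spaced tumor
#' sizes, for each requested frequency window. The density of the size grid
#' is a modeling choice; `n_M` exposes it so its influence on the averages
#' can be reported.
#'
#' @param windows List of detection windows (each a [detection_window()] or
#'   numeric `c(lo, hi)`).
#' @param n_M Number of log-spaced tumor sizes between `M_range[1]` and
#'   `M_range[2]`.
#' @param M_range Size range (cells).
#' @inheritParams two_driver_sweep
#' @return A list of class `average_detection`: `summary` (one row per
#'   window: `lo`, `hi`, `mean_total`, `mean_P1`, `mean_P2`) and `detail`
#'   (the underlying per-point sweep).
#' @examples
#' \donttest{
#' average_detection(n_M = 5)
#' }
#' @export
average_detection <- function(windows = list(detection_window(0.2, 0.8),
                                             detection_window(0.24, 0.48)),
                              regimes = growth_regimes(),
                              g_list = c(0.3, 0.7, 1.0),
                              n_M = 25, M_range = c(1e6, 1e11),
                              u = 1e-5,
                              quad = quad_spec(rel_tol = 1e-7)) {
  M_grid <- 10^seq(log10(M_range[1]), log10(M_range[2]), length.out = n_M)
  detail <- purrr::map_dfr(windows, function(w) {
    w <- as_detection_window(w)
    sw <- two_driver_sweep(regimes, g_list, M_grid, u, w, quad)
    dplyr::mutate(sw, lo = w[["lo"]], hi = w[["hi"]], .before = 1)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(detail, .data$lo, .data$hi),
    mean_P1 = mean(.data$P1),
    mean_P2 = mean(.data$P2),
    mean_total = mean(.data$total),
    .groups = "drop"
  )
  structure(list(summary = summary, detail = detail),
            class = "average_detection")
}

#' @export
print.average_detection <- function(x, ...) {
  cat("Average driver-detection probability (first or second driver)\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  window [%.2f, %.2f]: %.3f\n",
                x$summary$lo[i], x$summary$hi[i], x$summary$mean_total[i]))
  invisible(x)
}

#' @rdname average_detection
#' @param x An `average_detection` object.
#' @param ... Unused.
#' @method tidy average_detection
#' @export
tidy.average_detection <- function(x, ...) x$detail

#' @rdname average_detection
#' @method glance average_detection
#' @export
glance.average_detection <- function(x, ...) x$summary

#' Write a run manifest
#'
#' Records, next to a command's outputs, everything needed to reproduce
#' them: command name, fully resolved parameters, seed, package version and
#' output paths.
#'
#' @param path File to write (JSON).
#' @param command Command or function name.
#' @param params Named list of resolved parameters.
#' @param seed Seed(s) used, or `NULL` for deterministic commands.
#' @param outputs Character vector of output paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, params, seed = NULL,
                               outputs = character()) {
  manifest <- list(
    command = command,
    params = params,
    seed = seed,
    package = "subdriver",
    version = as.character(utils::packageVersion("subdriver")),
    outputs = outputs,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

write_figure_csvs <- function(data, figure, out_dir, command, seed = NULL,
                              params = list()) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(data)) {
    p <- file.path(out_dir, sprintf("%s_%s.csv", figure, nm))
    utils::write.csv(data[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  write_run_manifest(file.path(out_dir, sprintf("%s_manifest.json", figure)),
                     command, params, seed, paths)
  invisible(paths)
}

#' Regenerate the package's standard figures
#'
#' Recomputes the data behind the standard result figures: detection-vs-size
#' curves for the three growth regimes (`"fig2"`), detection contours over
#' mutation rate and selection strength (`"fig3"`), analytic-vs-simulated
#' frequency CDFs (`"fig4"`), the 3d lattice screen (`"s1"`), the combined
#' 3d + sigmoidal screen (`"s2"`) and the two-driver curves (`"s3"`). The
#' `"reduced"` budget uses desk-scale grid resolutions and replicate
#' counts; `"full"` uses publication-scale ones (slow for the stochastic
#' figures).
#'
#' @param figure One of `"fig2"`, `"fig3"`, `"fig4"`, `"s1"`, `"s2"`, `"s3"`.
#' @param budget `"reduced"` (default) or `"full"`.
#' @param out_dir If non-`NULL`, CSV tables and a run manifest are written
#'   there.
#' @param seed Seed for the stochastic figures.
#' @param quad A [quad_spec()].
#' @return A list with elements `data` (named tibbles) and `plots` (named
#'   ggplot objects).
#' @examples
#' \donttest{
#' fig <- reproduce_figure("fig2")
#' fig$plots$curves
#' }
#' @export
reproduce_figure <- function(figure = c("fig2", "fig3", "fig4", "s1", "s2", "s3"),
                             budget = c("reduced", "full"),
                             out_dir = NULL, seed = 1,
                             quad = quad_spec(rel_tol = 1e-7)) {
  figure <- match.arg(figure)
  budget <- match.arg(budget)
  reduced <- budget == "reduced"
  switch(figure,
    fig2 = figure_detection_curves(reduced, out_dir, quad),
    fig3 = figure_detection_contours(reduced, out_dir, quad),
    fig4 = figure_cdf_validation(reduced, out_dir, seed, quad),
    s1 = figure_spatial_screen(reduced, out_dir, seed),
    s2 = figure_sigmoidal_screen(reduced, out_dir, seed),
    s3 = figure_two_driver_curves(reduced, out_dir, quad)
  )
}

figure_detection_curves <- function(reduced, out_dir, quad) {
  M_grid <- 10^seq(5, 12, length.out = if (reduced) 36 else 120)
  curves <- purrr::pmap_dfr(growth_regimes(), function(regime, b, r) {
    dplyr::mutate(
      detection_vs_size(b = b, r = r, u = 1e-5, g_list = c(0.3, 0.7, 1.0),
                        M_grid = M_grid, quad = quad),
      regime = regime, .before = 1)
  })
  dens_M <- c(small = 1e6, intermediate = 4e7, large = 1e9)
  alphas <- seq(0.01, 0.99, by = 0.01)
  density <- purrr::imap_dfr(dens_M, function(M, label) {
    pr <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = M)
    tibble::tibble(size = label, M = M, alpha = alphas,
                   density = pdf_subclonal_frequency(pr, alphas, quad))
  })
  data <- list(curves = curves, density = density)
  plots <- list(
    curves = autoplot(curves) + ggplot2::facet_wrap(~regime),
    density = ggplot2::ggplot(density,
                ggplot2::aes(x = .data$alpha, y = .data$density)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~size, scales = "free_y") +
      ggplot2::labs(x = "driver frequency", y = "probability density") +
      ggplot2::theme_minimal()
  )
  write_figure_csvs(data, "fig2", out_dir, "reproduce_figure",
                    params = list(figure = "fig2"))
  list(data = data, plots = plots)
}

figure_detection_contours <- function(reduced, out_dir, quad) {
  n <- if (reduced) 15 else 60
  grid <- tidyr::expand_grid(
    M = c(small = 1e7, intermediate = 1e9, large = 1e11),
    u = 10^seq(-7, -3, length.out = n),
    g = seq(0.01, 2, length.out = n)
  )
  grid <- dplyr::mutate(grid, b1 = 0.14, r = 0.01, c = 1 + .data$g)
  grid <- add_detection_probability(grid, quad = quad)
  data <- list(contours = grid)
  plots <- list(
    contours = ggplot2::ggplot(grid,
                 ggplot2::aes(x = .data$u, y = 100 * .data$g,
                              z = .data$p_det)) +
      ggplot2::geom_contour_filled() +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(~M, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "driver mutation rate u (per day)",
                    y = "driver advantage g (%)") +
      ggplot2::theme_minimal()
  )
  write_figure_csvs(data, "fig3", out_dir, "reproduce_figure",
                    params = list(figure = "fig3"))
  list(data = data, plots = plots)
}

fig4_panels <- function() {
  # panels a-c of the CDF-validation figure; the published panel d lists a
  # subcritical wild type (d > b), which the model rejects, so it is omitted
  # with a note
  tibble::tibble(
    panel = c("a", "b", "c"),
    b = 0.14, d = 0.13, c = c(1.7, 1.5, 1.5),
    u = c(1e-5, 1e-4, 1e-5), M = 1e8
  )
}

figure_cdf_validation <- function(reduced, out_dir, seed, quad) {
  panels <- fig4_panels()
  if (reduced) panels$M <- 1e6
  n_runs <- if (reduced) 300 else 1000
  alphas <- seq(0.1, 0.9, by = 0.1)
  deciles <- purrr::pmap_dfr(panels, function(panel, b, d, c, u, M) {
    pr <- branching_params(b = b, d = d, b1 = b, d1 = b - c * (b - d),
                           u = u, M = M)
    sim <- run_branching(pr, n_runs = n_runs,
                         seed = seed + match(panel, c("a", "b", "c")))
    emp <- empirical_cdf(sim, alphas, seed = seed)
    dplyr::mutate(emp, panel = panel, M = M,
                  F_analytic = cdf_subclonal_frequency(pr, alphas, quad),
                  .before = 1)
  })
  message("panel d omitted: its published parameters imply a subcritical wild type")
  data <- list(deciles = deciles)
  plots <- list(
    deciles = ggplot2::ggplot(deciles, ggplot2::aes(x = .data$alpha)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$F_analytic)) +
      ggplot2::geom_pointrange(ggplot2::aes(
        y = .data$F_hat,
        ymin = .data$F_hat - .data$sem,
        ymax = .data$F_hat + .data$sem), size = 0.2) +
      ggplot2::facet_wrap(~panel) +
      ggplot2::labs(x = "driver frequency", y = "P(f_sub <= alpha)") +
      ggplot2::theme_minimal()
  )
  write_figure_csvs(data, "fig4", out_dir, "reproduce_figure", seed,
                    params = list(figure = "fig4", n_runs = n_runs))
  list(data = data, plots = plots)
}

#' Default tumor-size grids for the 3d lattice screen
#'
#' Log-spaced size grids in lattice sites (1 site = 100 cells under default
#' scaling), one per growth regime. The slow regime (d = 0.9) sits close to
#' the contact-process threshold and grows as a sparse, slowly advancing
#' cloud, so its grid uses smaller sizes; the driver there typically sweeps
#' before the tumor is large anyway.
#'
#' @return A named list of integer vectors (sites) keyed by regime.
#' @export
spatial_screen_sizes <- function() {
  list(moderate = c(500L, 2000L, 8000L, 32000L),
       fast = c(500L, 2000L, 8000L, 32000L),
       slow = c(250L, 500L, 1000L, 2000L))
}

figure_spatial_screen <- function(reduced, out_dir, seed) {
  n_runs <- if (reduced) 100 else 1000
  screen <- spatial_screen(g_list = c(0.3, 0.7, 1.0), n_runs = n_runs,
                           seed = seed)
  data <- list(screen = screen)
  plots <- list(
    screen = ggplot2::ggplot(screen,
               ggplot2::aes(x = .data$size_cells, y = .data$p_det,
                            color = factor(100 * .data$g))) +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$p_det - .data$sem, ymax = .data$p_det + .data$sem)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(~regime) +
      ggplot2::labs(x = "tumor size (cells)",
                    y = "P(driver in detection window)",
                    color = "driver advantage g (%)") +
      ggplot2::theme_minimal()
  )
  write_figure_csvs(data, "s1", out_dir, "reproduce_figure", seed,
                    params = list(figure = "s1", n_runs = n_runs))
  list(data = data, plots = plots)
}

#' 3d lattice detection screen
#'
#' Runs the spatial model across the three lattice growth regimes and the
#' given selection strengths, recording the detection probability at each
#' tumor size (sizes are recorded along single runs, so each replicate
#' serves every size).
#'
#' @param g_list Driver growth advantages.
#' @param sizes_sites Tumor sizes in lattice sites (1 site = 100 cells by
#'   default scaling): either one integer vector for all regimes or a named
#'   list keyed by regime (see [spatial_screen_sizes()]).
#' @param n_runs Accepted runs per regime/selection combination.
#' @param seed Integer master seed.
#' @param u Driver mutation rate per cell per day.
#' @param cells_per_site Site scaling factor.
#' @param window A [detection_window()] or numeric `c(lo, hi)`.
#' @return A tibble: `regime`, `b`, `d`, `g`, `size_cells`, `p_det`, `sem`,
#'   `n`.
#' @export
spatial_screen <- function(g_list = c(0.3, 0.7, 1.0),
                           sizes_sites = spatial_screen_sizes(),
                           n_runs = 200, seed = 1, u = 1e-5,
                           cells_per_site = 100,
                           window = detection_window()) {
  window <- as_detection_window(window)
  combos <- tidyr::expand_grid(lattice_regimes(), g = g_list)
  purrr::pmap_dfr(combos, function(regime, b, d, g) {
    sizes <- if (is.list(sizes_sites)) sizes_sites[[regime]] else sizes_sites
    lp <- lattice_params(b = b, d = d, g = g, u = u,
                         cells_per_site = cells_per_site)
    sim <- run_spatial(lp, sizes_cells = sizes * cells_per_site,
                       n_runs = n_runs, track_time = FALSE,
                       seed = seed + 1000 * match(regime, lattice_regimes()$regime) +
                         round(1e5 * g))
    det <- detection_from_sample(sim, window)
    dplyr::mutate(det, regime = regime, b = b, d = d, g = g, .before = 1)
  })
}

figure_sigmoidal_screen <- function(reduced, out_dir, seed) {
  n_runs <- if (reduced) 100 else 1000
  screen <- sigmoidal_screen(n_runs = n_runs, seed = seed)
  data <- list(screen = screen)
  plots <- list(
    screen = ggplot2::ggplot(screen,
               ggplot2::aes(x = factor(100 * .data$g), y = .data$p_det)) +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$p_det - .data$sem, ymax = .data$p_det + .data$sem)) +
      ggplot2::facet_wrap(~regime) +
      ggplot2::labs(x = "driver advantage g (%)",
                    y = "P(final driver fraction in window)") +
      ggplot2::theme_minimal()
  )
  write_figure_csvs(data, "s2", out_dir, "reproduce_figure", seed,
                    params = list(figure = "s2", n_runs = n_runs))
  list(data = data, plots = plots)
}

#' Combined 3d + sigmoidal detection screen
#'
#' For each growth regime (paired lattice death rate and logistic growth
#' rate) and selection strength, runs the spatial phase to the handoff size
#' and scores the final stable driver fraction of the logistic phase
#' against the detection window.
#'
#' @param g_list Driver growth advantages.
#' @param K Carrying capacity (cells).
#' @param handoff_size Cells at the spatial-to-logistic handoff.
#' @param n_runs Accepted runs per combination.
#' @param seed Integer master seed.
#' @param u Driver mutation rate per cell per day.
#' @param window A [detection_window()] or numeric `c(lo, hi)`.
#' @return A tibble: `regime`, `g`, `p_det`, `sem`, `n`.
#' @export
sigmoidal_screen <- function(g_list = c(0.3, 0.7, 1.0), K = 1e11,
                             handoff_size = 1e6, n_runs = 200, seed = 1,
                             u = 1e-5, window = detection_window()) {
  window <- as_detection_window(window)
  regimes <- dplyr::left_join(lattice_regimes(),
                              growth_regimes()[, c("regime", "r")],
                              by = "regime")
  combos <- tidyr::expand_grid(regimes, g = g_list)
  purrr::pmap_dfr(combos, function(regime, b, d, r, g) {
    lp <- lattice_params(b = b, d = d, g = g, u = u)
    sp <- sigmoidal_params(r = r, g = g, K = K, handoff_size = handoff_size)
    det <- sigmoidal_detection(lp, sp, window, n_runs = n_runs,
                               seed = seed + 1000 * match(regime, regimes$regime) +
                                 round(1e5 * g))
    dplyr::mutate(det$summary, regime = regime, g = g, .before = 1)
  })
}

figure_two_driver_curves <- function(reduced, out_dir, quad) {
  M_grid <- 10^seq(6, 11, length.out = if (reduced) 12 else 40)
  sweep <- two_driver_sweep(M_grid = M_grid, quad = quad)
  long <- tidyr::pivot_longer(sweep, c("P1", "P2", "total"),
                              names_to = "which", values_to = "prob")
  data <- list(curves = sweep)
  plots <- list(
    curves = ggplot2::ggplot(long,
               ggplot2::aes(x = .data$M, y = .data$prob,
                            color = .data$which)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_color_manual(
        values = c(P1 = "#EE7733", P2 = "#0077BB", total = "#CC3311"),
        labels = c(P1 = "first driver", P2 = "second driver",
                   total = "either")) +
      ggplot2::facet_grid(regime ~ g, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "tumor size M (cells)", y = "detection probability",
                    color = NULL) +
      ggplot2::theme_minimal()
  )
  write_figure_csvs(data, "s3", out_dir, "reproduce_figure",
                    params = list(figure = "s3"))
  list(data = data, plots = plots)
}
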