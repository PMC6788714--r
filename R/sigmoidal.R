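#' Parameters of the two-clone logistic (sigmoidal) growth phase
#'
#' Late-stage tumor growth is modeled deterministically by two competing
#' clones sharing one carrying capacity:
#' \deqn{dx/dt = r\,x\,(1 - (x+y)/K), \qquad dy/dt = c\,r\,y\,(1 - (x+y)/K),}
#' where `x` is the wild-type and `y` the driver population, `c = 1 + g > 1`
#' the ratio of their initial growth rates and `K` the carrying capacity.
#' Dividing the equations gives the exact first integral
#' `y = y0 * (x/x0)^c`, which pins the final composition without
#' integration. The phase is seeded at `handoff_size` cells (default
#' `1e6`), typically from the end of a 3d lattice simulation.
#'
#' @param r Wild-type initial growth rate (per day, > 0).
#' @param c Growth-rate ratio (> 1); alternative to `g`.
#' @param g Relative driver advantage, `c = 1 + g`.
#' @param K Carrying capacity (cells, > `handoff_size`).
#' @param handoff_size Total size (cells) at which the stochastic spatial
#'   phase hands over to this deterministic phase.
#' @return An object of class `sigmoidal_params`.
#' @examples
#' sigmoidal_params(r = 0.01, g = 0.7, K = 1e11)
#' @export
sigmoidal_params <- function(r, c = NULL, g = NULL, K, handoff_size = 1e6) {
  stopifnot(r > 0, K > 0, handoff_size > 0)
  if (is.null(c)) {
    if (is.null(g)) stop("supply `c` or `g`", call. = FALSE)
    c <- 1 + g
  }
  if (c <= 1) stop("growth-rate ratio must satisfy c > 1", call. = FALSE)
  if (K <= handoff_size)
    stop("carrying capacity K must exceed handoff_size", call. = FALSE)
  structure(list(r = r, c = c, g = c - 1, K = K,
                 handoff_size = handoff_size),
            class = "sigmoidal_params")
}

#' @export
print.sigmoidal_params <- function(x, ...) {
  cat("Two-clone logistic growth phase\n")
  cat(sprintf("  r = %g /day, c = %g (g = %g%%), K = %g cells, handoff %g cells\n",
              x$r, x$c, 100 * x$g, x$K, x$handoff_size))
  invisible(x)
}

#' Integrate the two-clone logistic system
#'
#' Solves the sigmoidal-growth ODEs from initial populations `(x0, y0)`
#' until the total size reaches `(1 - 1e-6) K`, using an adaptive solver
#' with a root-stopping condition (relative tolerance 1e-11, absolute
#' tolerance scaled to the initial population).
#' Output rows report both populations and the driver fraction along the
#' trajectory; the first integral `y = y0 (x/x0)^c` holds at every output
#' time up to solver tolerance.
#'
#' @param params A [sigmoidal_params()].
#' @param x0 Initial wild-type population (> 0).
#' @param y0 Initial driver population (>= 0).
#' @param n_out Number of output time points.
#' @return A tibble of class `sigmoidal_trajectory` with columns `t`, `x`,
#'   `y`, `total`, `driver_fraction`.
#' @examples
#' sp <- sigmoidal_params(r = 0.1, g = 0.7, K = 1e9)
#' solve_sigmoidal(sp, x0 = 9e5, y0 = 1e5)
#' @export
solve_sigmoidal <- function(params, x0, y0, n_out = 200) {
  stopifnot(inherits(params, "sigmoidal_params"))
  if (x0 <= 0) stop("x0 must be positive (first integral undefined at 0)",
                    call. = FALSE)
  if (y0 < 0) stop("y0 must be nonnegative", call. = FALSE)
  if (x0 + y0 > params$K)
    stop("initial total exceeds carrying capacity", call. = FALSE)

  K <- params$K; r <- params$r; cc <- params$c
  target <- (1 - 1e-6) * K
  # time horizon: logistic growth from the initial total at the slow rate,
  # padded; the root function stops integration early
  t_end <- (log(target / min(x0 + max(y0, 1), K)) + log(1e6)) / r + 1
  deriv <- function(t, state, parms) {
    dens <- 1 - (state[1] + state[2]) / K
    list(c(r * state[1] * dens, cc * r * state[2] * dens))
  }
  root <- function(t, state, parms) (state[1] + state[2]) - target
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::lsodar(y = c(x = x0, y = y0), times = times,
                         func = deriv, parms = NULL,
                         rtol = 1e-11, atol = 1e-11 * (x0 + y0), rootfunc = root)
  out <- tibble::tibble(
    t = sol[, "time"], x = sol[, "x"], y = sol[, "y"],
    total = sol[, "x"] + sol[, "y"]
  )
  out$driver_fraction <- out$y / out$total
  class(out) <- c("sigmoidal_trajectory", class(out))
  attr(out, "params") <- params
  out
}

#' @rdname solve_sigmoidal
#' @param object A `sigmoidal_trajectory`.
#' @param ... Unused.
#' @method autoplot sigmoidal_trajectory
#' @export
autoplot.sigmoidal_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("t", "x", "y")],
                              c("x", "y"),
                              names_to = "clone", values_to = "size")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$size,
                                     color = .data$clone)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_color_manual(
      values = c(x = "#4477AA", y = "#CC3311"),
      labels = c(x = "wild type", y = "driver")) +
    ggplot2::labs(x = "time (days)", y = "population size (cells)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Final stable driver fraction under logistic competition
#'
#' As growth stops at carrying capacity, clone frequencies freeze. The
#' limiting wild-type size `x*` solves `x* + y0 (x*/x0)^c = K` (the first
#' integral evaluated at total size `K`), and the final driver fraction is
#' `1 - x*/K`. The root is found in log space; no ODE integration is
#' involved. Vectorized over `x0`, `y0`.
#'
#' @inheritParams solve_sigmoidal
#' @return Final driver fractions in `[0, 1]`.
#' @examples
#' sp <- sigmoidal_params(r = 0.01, g = 0.7, K = 1e11)
#' final_driver_fraction(sp, x0 = 9e5, y0 = 1e5)
#' final_driver_fraction(sp, x0 = 1e6, y0 = 0)  # no driver: 0
#' @export
final_driver_fraction <- function(params, x0, y0) {
  stopifnot(inherits(params, "sigmoidal_params"))
  n <- max(length(x0), length(y0))
  x0 <- rep_len(x0, n); y0 <- rep_len(y0, n)
  if (any(x0 <= 0)) stop("x0 must be positive (first integral undefined at 0)",
                         call. = FALSE)
  if (any(y0 < 0)) stop("y0 must be nonnegative", call. = FALSE)
  if (any(x0 + y0 > params$K))
    stop("initial total exceeds carrying capacity", call. = FALSE)
  K <- params$K; cc <- params$c
  vapply(seq_len(n), function(i) {
    if (y0[i] == 0) return(0)
    # phi(t) = x0 e^t + y0 e^(c t) - K on t = log(x*/x0) in [0, log(K/x0)];
    # phi is increasing, phi(0) <= 0, phi(log(K/x0)) >= 0
    phi <- function(t) x0[i] * exp(t) + y0[i] * exp(cc * t) - K
    tmax <- log(K / x0[i])
    if (phi(0) >= 0) return(y0[i] / (x0[i] + y0[i]))  # already at capacity
    t_star <- stats::uniroot(phi, c(0, tmax), tol = 1e-14)$root
    xs <- x0[i] * exp(t_star)
    ys <- y0[i] * exp(cc * t_star)
    ys / (xs + ys)
  }, numeric(1))
}

#' Detection probability in the combined 3d + sigmoidal model
#'
#' Per-run pipeline for late-stage tumors: grow a 3d lattice tumor to the
#' handoff size, convert the recorded wild-type and driver populations to
#' cells, and propagate them through the deterministic logistic phase to
#' carrying capacity via the first-integral root. Reports the fraction of
#' accepted runs whose final stable driver fraction lies in the detection
#' window. Runs with no driver produced in the spatial phase are rejected
#' (the same policy as [run_spatial()]).
#'
#' @param lparams A [lattice_params()] for the avascular spatial phase.
#' @param sig A [sigmoidal_params()]; its `handoff_size` (cells) sets the
#'   lattice final size and its `c` should normally equal `1 + lparams$g`.
#' @param window A [detection_window()] or numeric `c(lo, hi)`.
#' @param n_runs Accepted spatial runs.
#' @param seed Integer master seed.
#' @param reject_driver_extinct Passed to [run_spatial()].
#' @return A list of class `sigmoidal_detection`: `summary` (tibble with
#'   `p_det`, `sem`, `n`), `fractions` (per-run final fractions), and the
#'   rejection counts of the spatial phase.
#' @examples
#' \donttest{
#' lp <- lattice_params(b = 1, d = 0.5, g = 0.7, u = 1e-5)
#' sp <- sigmoidal_params(r = 0.07, g = 0.7, K = 1e11, handoff_size = 1e5)
#' sigmoidal_detection(lp, sp, n_runs = 20, seed = 1)
#' }
#' @export
sigmoidal_detection <- function(lparams, sig, window = detection_window(),
                                n_runs = 200, seed = 1,
                                reject_driver_extinct = FALSE) {
  stopifnot(inherits(lparams, "lattice_params"),
            inherits(sig, "sigmoidal_params"))
  window <- as_detection_window(window)
  spat <- run_spatial(lparams, sizes_cells = sig$handoff_size,
                      n_runs = n_runs, seed = seed,
                      reject_driver_extinct = reject_driver_extinct,
                      track_time = FALSE)
  f_handoff <- spat$runs$f_sub
  total <- sig$handoff_size
  y0 <- f_handoff * total
  x0 <- total - y0
  # driver fixation on the lattice leaves x0 = 0; frequencies then stay 1
  fixed <- x0 <= 0
  final <- numeric(length(y0))
  final[fixed] <- 1
  if (any(!fixed))
    final[!fixed] <- final_driver_fraction(sig, x0[!fixed], y0[!fixed])
  summ <- detection_from_sample(final, window)
  structure(
    list(summary = summ,
         fractions = tibble::tibble(run = seq_along(final),
                                    f_handoff = f_handoff,
                                    f_final = final),
         n_rejected_extinct = spat$n_rejected_extinct,
         n_rejected_driverless = spat$n_rejected_driverless,
         window = unclass(window), seed = seed),
    class = "sigmoidal_detection"
  )
}

#' @export
print.sigmoidal_detection <- function(x, ...) {
  cat(sprintf(
    "Sigmoidal-model detection: P_det = %.3f (sem %.3f, n = %d) in [%.2f, %.2f]\n",
    x$summary$p_det, x$summary$sem, x$summary$n,
    x$window[["lo"]], x$window[["hi"]]))
  invisible(x)
}

#' @rdname sigmoidal_detection
#' @param x A `sigmoidal_detection` object.
#' @param ... Unused.
#' @method tidy sigmoidal_detection
#' @export
tidy.sigmoidal_detection <- function(x, ...) x$fractions

#' @rdname sigmoidal_detection
#' @method glance sigmoidal_detection
#' @export
glance.sigmoidal_detection <- function(x, ...) {
  dplyr::mutate(x$summary,
                n_rejected_extinct = x$n_rejected_extinct,
                n_rejected_driverless = x$n_rejected_driverless)
}
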