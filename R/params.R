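#' Parameters of the two-type branching process
#'
#' Bundles the rates and final size of the well-mixed two-type model of tumor
#' growth: wild-type (type-0) cells divide at rate `b` and die at rate `d`;
#' driver-carrying (type-1) cells divide at rate `b1` and die at rate `d1`;
#' type-0 cells acquire the driver at rate `u` per cell; growth is followed
#' until the tumor holds `M` cells. All rates are per day.
#'
#' Two conventions are supported. Either give the four rates directly
#' (`b`, `d`, `b1`, `d1`), or give the wild-type net growth rate r `= b - d`
#' together with the driver's relative growth advantage `g` (or the ratio
#' `c = 1 + g` of net growth rates), in which case `d = b - r` and
#' `d1 = b1 - (1 + g) * r`. The implied death rates must be nonnegative and
#' both types supercritical (`b > d`, `b1 > d1`).
#'
#' @param b Type-0 birth rate (per day).
#' @param d Type-0 death rate (per day); omit if `r` is given.
#' @param b1 Type-1 birth rate (per day); defaults to `b`.
#' @param d1 Type-1 death rate (per day); omit if `g` or `c` is given.
#' @param u Driver mutation rate per cell per day (`u = 0` is only meaningful
#'   for simulator null experiments).
#' @param M Final total cell count (may be non-integer for analytic work).
#' @param r Type-0 net growth rate `b - d` (per day), alternative to `d`.
#' @param g Relative growth-rate advantage of the driver, `r1/r - 1`.
#' @param c Ratio of net growth rates `r1/r`; alternative to `g`.
#'
#' @return An object of class `branching_params`: a list with fields
#'   `b`, `d`, `b1`, `d1`, `u`, `M` and derived `r`, `r1`, `c`, `g`.
#' @examples
#' branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
#' branching_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.123, u = 1e-5, M = 1e8)
#' @export
branching_params <- function(b, d = NULL, b1 = b, d1 = NULL, u, M,
                             r = NULL, g = NULL, c = NULL) {
  stopifnot(is.numeric(b), length(b) == 1, b > 0)
  if (is.null(d)) {
    if (is.null(r)) stop("supply either `d` or `r`", call. = FALSE)
    d <- b - r
  }
  if (!is.null(r) && abs((b - d) - r) > 1e-12 * max(1, abs(r)))
    stop("`d` and `r` are inconsistent: r must equal b - d", call. = FALSE)
  r <- b - d
  if (is.null(d1)) {
    if (is.null(c)) {
      if (is.null(g)) stop("supply `d1`, `g` or `c`", call. = FALSE)
      c <- 1 + g
    }
    d1 <- b1 - c * r
    if (d1 < -1e-12)
      stop(sprintf(
        "implied type-1 death rate d1 = b1 - c*r = %.4g is negative", d1),
        call. = FALSE)
    d1 <- max(d1, 0)
  }
  r1 <- b1 - d1
  if (d < 0 || d1 < 0) stop("death rates must be nonnegative", call. = FALSE)
  if (b <= d) stop("type-0 must be supercritical: b > d", call. = FALSE)
  if (b1 <= d1) stop("type-1 must be supercritical: b1 > d1", call. = FALSE)
  cc <- r1 / r
  if (cc < 1 - 1e-12)
    stop("the driver must not decrease the net growth rate (c = r1/r >= 1)",
         call. = FALSE)
  if (!is.null(c) && abs(c - cc) > 1e-9 * cc)
    stop("`c` inconsistent with the supplied rates", call. = FALSE)
  stopifnot(is.numeric(u), length(u) == 1, u >= 0)
  stopifnot(is.numeric(M), length(M) == 1, M >= 1)

  structure(
    list(b = b, d = d, b1 = b1, d1 = d1, u = u, M = M,
         r = r, r1 = r1, c = cc, g = cc - 1),
    class = "branching_params"
  )
}

#' @export
print.branching_params <- function(x, ...) {
  cat("Two-type branching process parameters (rates per day)\n")
  cat(sprintf("  type-0: b = %g, d = %g (r = %g)\n", x$b, x$d, x$r))
  cat(sprintf("  type-1: b1 = %g, d1 = %g (r1 = %g, c = %g, g = %g%%)\n",
              x$b1, x$d1, x$r1, x$c, 100 * x$g))
  cat(sprintf("  driver mutation rate u = %g, final size M = %g cells\n",
              x$u, x$M))
  invisible(x)
}

#' Detectable frequency window
#'
#' The cancer-cell-frequency interval within which a subclonal driver is
#' considered detectable, i.e. able to distort the neutral 1/f
#' mutation-frequency spectrum. The default `[0.2, 0.8]` is deliberately wide;
#' `[0.24, 0.48]` corresponds to the narrower CCF range used by the original
#' 1/f neutrality test.
#'
#' @param lo,hi Window bounds, frequencies in `[0, 1]` with `lo <= hi`.
#' @return A length-2 numeric vector of class `detection_window`.
#' @examples
#' detection_window()             # [0.2, 0.8]
#' detection_window(0.24, 0.48)   # 1/f-test CCF range
#' @export
detection_window <- function(lo = 0.2, hi = 0.8) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1, length(hi) == 1)
  if (!(lo >= 0 && hi <= 1 && lo <= hi))
    stop("window must satisfy 0 <= lo <= hi <= 1", call. = FALSE)
  structure(c(lo = lo, hi = hi), class = "detection_window")
}

as_detection_window <- function(window) {
  if (inherits(window, "detection_window")) return(window)
  if (is.numeric(window) && length(window) == 2)
    return(detection_window(window[[1]], window[[2]]))
  stop("`window` must be a detection_window or a numeric length-2 vector",
       call. = FALSE)
}

#' Numerical quadrature settings
#'
#' Tolerances and subdivision budget for the adaptive quadratures behind the
#' frequency distribution. The defaults are tight enough that quadrature
#' error is negligible against the model's own approximations.
#'
#' @param rel_tol Relative tolerance (> 0).
#' @param abs_tol Absolute tolerance (>= 0); the floor for integrals whose
#'   value underflows any relative target.
#' @param max_subdivisions Subdivision budget of the adaptive rule.
#' @return An object of class `quad_spec`.
#' @export
quad_spec <- function(rel_tol = 1e-9, abs_tol = 1e-14, max_subdivisions = 200L) {
  stopifnot(rel_tol > 0, abs_tol >= 0, max_subdivisions >= 10)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_subdivisions = as.integer(max_subdivisions)),
            class = "quad_spec")
}

#' Inputs for a driver mutation-rate bound
#'
#' A bound on the driver mutation rate is the product of a driver-gene count,
#' the average number of positions per gene whose mutation yields a functional
#' driver, and a per-base-pair mutation rate.
#'
#' @param n_driver_genes Number of driver genes (>= 0).
#' @param positions_per_gene Average driver positions per gene (>= 0).
#' @param per_bp_rate Point mutation rate per base pair per day (>= 0).
#' @return An object of class `rate_bound_inputs`.
#' @seealso [driver_mutation_rate_bounds()]
#' @export
rate_bound_inputs <- function(n_driver_genes, positions_per_gene, per_bp_rate) {
  stopifnot(n_driver_genes >= 0, positions_per_gene >= 0, per_bp_rate >= 0)
  structure(list(n_driver_genes = n_driver_genes,
                 positions_per_gene = positions_per_gene,
                 per_bp_rate = per_bp_rate),
            class = "rate_bound_inputs")
}

#' Representative tumor growth regimes
#'
#' Literature-derived parameter sets for a moderately growing tumor
#' (b = 0.14, r = 0.01), a fast growing tumor (b = 0.25, r = 0.07)
#' and a slow-growing tumor (b = 0.33, r = 0.0013), all rates per day
#' with `b1 = b`. These are the standard regimes used throughout the
#' package's sweeps and figures.
#'
#' @return A tibble with columns `regime`, `b`, `r`.
#' @examples
#' growth_regimes()
#' @export
growth_regimes <- function() {
  tibble::tibble(
    regime = c("moderate", "fast", "slow"),
    b = c(0.14, 0.25, 0.33),
    r = c(0.01, 0.07, 0.0013)
  )
}
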