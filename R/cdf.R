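#' @useDynLib subdriver, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# Clip tiny quadrature excursions outside [0,1]; anything larger is a bug
# and raises rather than being silently hidden.
clip_probability <- function(p, tol = 1e-10, what = "probability") {
  bad <- p < -tol | p > 1 + tol
  if (any(bad, na.rm = TRUE))
    stop(sprintf("%s outside [0,1] beyond numerical noise: %.6g",
                 what, p[which(bad)[1]]), call. = FALSE)
  pmin(pmax(p, 0), 1)
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# construction; cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  gl <- list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
  .gl_cache[[key]] <- gl
  gl
}

# log of the inner-exponent coefficient B(alpha) after the substitution
# s = (c*u/b1) * X0, so that the frequency CDF becomes
#   F[alpha] = int_0^{lam*M} exp(-s) * (1 - exp(-B * s^c)) ds,
# with lam = c*u/b1 and
#   B = (c*r/b1) * alpha * (1-alpha)^(-c) * lam^(-c) * M^(1-c).
# Everything is assembled in log space so that M^(1-c) cannot underflow.
log_B_alpha <- function(params, alpha) {
  with(params,
       log(c * r / b1) + log(alpha) - c * log1p(-alpha) -
         c * log(c * u / b1) + (1 - c) * log(M))
}

integrate_checked <- function(f, lower, upper, quad) {
  res <- stats::integrate(f, lower, upper,
                          rel.tol = quad$rel_tol,
                          abs.tol = quad$abs_tol,
                          subdivisions = quad$max_subdivisions,
                          stop.on.error = FALSE)
  if (!res$message %in% "OK") {
    # accept a failed *relative* target when the integral is simply tiny
    if (is.finite(res$value) && abs(res$value) < 1e3 * quad$abs_tol)
      return(res$value)
    stop(sprintf("quadrature failed (%s), estimated residual %.3g",
                 res$message, res$abs.error), call. = FALSE)
  }
  res$value
}

#' Cumulative distribution of subclonal driver frequency
#'
#' Probability `F[alpha]` that the cancer-cell frequency of the driver
#' subclone is at most `alpha` when the tumor reaches `M` cells:
#' \deqn{F[\alpha] = \int_0^M \frac{cu}{b_1} e^{-\frac{cu}{b_1} X_0}
#'   \left[1 - \exp\left(-\frac{cr}{b_1}\,\frac{\alpha}{(1-\alpha)^c}\,
#'   X_0^c M^{1-c}\right)\right] dX_0,}
#' where the integration variable \eqn{X_0} is the (exponentially
#' distributed) wild-type population size when the first surviving driver
#' lineage appears. The inner exponent is evaluated in log space, so the
#' result is stable for `M` up to `1e12` and `c` up to 3.
#'
#' The limit for `alpha -> 1` is `1 - exp(-(c u / b1) M)`
#' (see [cdf_upper_limit()]); the deficit from 1 is the probability that no
#' surviving driver lineage arises before size `M`.
#'
#' @param params A [branching_params()] object with `c >= 1` and `u >= 0`.
#' @param alpha Frequencies in `[0, 1)`; vectorized.
#' @param quad A [quad_spec()].
#' @return `F[alpha]`, numeric of the same length as `alpha`, in `[0, 1]`.
#' @examples
#' p <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
#' cdf_subclonal_frequency(p, c(0.2, 0.8))
#' @export
cdf_subclonal_frequency <- function(params, alpha, quad = quad_spec()) {
  stopifnot(inherits(params, "branching_params"))
  if (any(alpha < 0 | alpha >= 1))
    stop("alpha must lie in [0, 1); the alpha -> 1 limit is cdf_upper_limit()",
         call. = FALSE)
  if (params$u == 0) return(rep(0, length(alpha)))

  lam <- params$c * params$u / params$b1
  upper <- min(lam * params$M, 45)  # exp(-45) < 3e-20: truncation negligible
  cexp <- params$c

  vapply(alpha, function(a) {
    if (a == 0) return(0)
    logB <- log_B_alpha(params, a)
    f <- function(s) {
      out <- numeric(length(s))
      pos <- s > 0
      sp <- s[pos]
      out[pos] <- exp(-sp) * (-expm1(-exp(logB + cexp * log(sp))))
      out
    }
    clip_probability(integrate_checked(f, 0, upper, quad),
                     what = "F[alpha]")
  }, numeric(1))
}

#' Closed-form upper limit of the frequency CDF
#'
#' The limit of [cdf_subclonal_frequency()] as `alpha -> 1`:
#' `1 - exp(-(c u / b1) M)`, the probability that at least one surviving
#' driver lineage arises before the tumor reaches `M` cells.
#'
#' @inheritParams cdf_subclonal_frequency
#' @return A probability.
#' @export
cdf_upper_limit <- function(params) {
  stopifnot(inherits(params, "branching_params"))
  -expm1(-(params$c * params$u / params$b1) * params$M)
}

# Log of the integrand of the density integral after the same substitution
# s = lam * X0; the prefactor is folded in so under/overflow cancels:
#   f(alpha) = int exp(logpref + c*log(s) - s - exp(logB + c*log(s))) ds
log_pdf_integrand_parts <- function(params, alpha) {
  lam <- params$c * params$u / params$b1
  logpref <- with(params,
                  2 * log(c / b1) + log(r) + log(u) + (1 - c) * log(M) -
                    (1 + c) * log(lam) - (1 + c) * log1p(-alpha) +
                    log1p((c - 1) * alpha))
  list(logpref = logpref, logB = log_B_alpha(params, alpha), lam = lam)
}

#' Probability density of subclonal driver frequency
#'
#' Density of the continuous part of the driver-frequency distribution at
#' tumor size `M`:
#' \deqn{f(\alpha) = \left(\frac{c}{b_1}\right)^2 r\,u\,M^{1-c}
#'   (1-\alpha)^{-1-c}\,(1+(c-1)\alpha)
#'   \int_0^M X_0^c \exp\!\left(-\frac{c}{b_1}\left(u X_0 +
#'   r M^{1-c} X_0^c (1-\alpha)^{-c}\alpha\right)\right) dX_0.}
#' The prefactor and exponent are combined in log space, keeping the
#' evaluation finite for `alpha` up to `1 - 1e-12`. The integrand can be
#' sharply peaked; its mode is located first and the integral split there.
#'
#' @inheritParams cdf_subclonal_frequency
#' @param alpha Frequencies strictly inside `(0, 1)`; vectorized.
#' @return Density values `f(alpha) >= 0`.
#' @examples
#' p <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
#' pdf_subclonal_frequency(p, c(0.25, 0.5, 0.75))
#' @export
pdf_subclonal_frequency <- function(params, alpha, quad = quad_spec()) {
  stopifnot(inherits(params, "branching_params"))
  if (any(alpha <= 0 | alpha >= 1))
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  if (params$u == 0) return(rep(0, length(alpha)))
  cexp <- params$c

  vapply(alpha, function(a) {
    parts <- log_pdf_integrand_parts(params, a)
    upper <- min(parts$lam * params$M, 60)
    # locate the mode of the log-integrand
    #   l(s) = c*log(s) - s - exp(logB + c*log(s))
    # in w = log(s): for large B it sits near B^(-1/c), far below `upper`,
    # and a derivative-free search in w cannot fail on bracket signs
    ell_w <- function(w) cexp * w - exp(w) - exp(parts$logB + cexp * w)
    w_guess <- if (is.finite(parts$logB)) {
      min(-parts$logB / cexp, log(upper))
    } else {
      log(upper)
    }
    opt <- stats::optimize(ell_w, c(w_guess - 45, log(upper)),
                           maximum = TRUE, tol = 1e-10)
    w_star <- opt$maximum
    lmax <- opt$objective
    # integrate in w = log(s), splitting at the peak: the integrand can be a
    # spike many orders of magnitude narrower than the s-range, which a
    # one-piece adaptive rule silently misses; in w the spike has width O(1)
    fw <- function(w) exp(ell_w(w) + w - lmax)
    w_lo <- w_star - 45 / cexp - 8
    w_hi <- log(upper)
    scaled <- if (w_star < w_hi) {
      integrate_checked(fw, w_lo, w_star, quad) +
        integrate_checked(fw, w_star, w_hi, quad)
    } else {
      integrate_checked(fw, w_lo, w_hi, quad)
    }
    val <- exp(parts$logpref + lmax) * scaled
    if (val < 0) stop("negative density from quadrature", call. = FALSE)
    val
  }, numeric(1))
}

#' Probability that a subclonal driver is detectable
#'
#' `P_det = F[hi] - F[lo]`: the probability that the driver's cancer-cell
#' frequency falls inside the detection window when the tumor holds `M`
#' cells.
#'
#' @inheritParams cdf_subclonal_frequency
#' @param window A [detection_window()] or numeric `c(lo, hi)`.
#' @return A probability in `[0, 1]`.
#' @examples
#' p <- branching_params(b = 0.14, r = 0.01, g = 0.3, u = 1e-5, M = 1e9)
#' detection_probability(p)                       # default [0.2, 0.8] window
#' detection_probability(p, c(0.24, 0.48))
#' @export
detection_probability <- function(params, window = detection_window(),
                                  quad = quad_spec()) {
  window <- as_detection_window(window)
  if (window[["lo"]] == window[["hi"]]) return(0)
  Fhi <- if (window[["hi"]] >= 1) cdf_upper_limit(params)
         else cdf_subclonal_frequency(params, window[["hi"]], quad)
  Flo <- if (window[["lo"]] <= 0) 0
         else cdf_subclonal_frequency(params, window[["lo"]], quad)
  clip_probability(Fhi - Flo, what = "P_det")
}

#' Detection probability of a second sequential driver
#'
#' Probability that a second driver, arising inside the first driver's
#' clone, sits in the detectable window while the first driver itself is
#' above the window (and therefore undetectable):
#' \deqn{P_2 \approx \int_{hi}^{1} f_1(\alpha_1)\,
#'   \left[F_2(hi/\alpha_1) - F_2(lo/\alpha_1)\right] d\alpha_1,}
#' where \eqn{f_1} is the first driver's frequency density at size `M` and
#' \eqn{F_2} the frequency CDF of the second driver within the first clone,
#' parameterized with background net growth rate `r1 = c r`, growth ratio
#' `(r1 + delta_r)/r1`, the same `b1` and `u`, and population size
#' `alpha_1 * M` (the size of the first-driver clone). The outer integral
#' is taken in the variable `1 - alpha_1`, where the integrand's
#' near-fixation concentration is resolved accurately.
#'
#' @inheritParams detection_probability
#' @param delta_r Absolute increment of the net growth rate conferred by the
#'   second driver (per day, > 0). Drivers of equal effect have
#'   `delta_r = g * r`.
#' @param outer_nodes Order of the fixed Gauss-Legendre rule used for the
#'   outer integral (default 64, accurate to well below the model error);
#'   `NULL` switches to adaptive quadrature.
#' @return The probability `P2`.
#' @examples
#' p <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
#' two_driver_detection(p, delta_r = p$g * p$r)
#' @export
two_driver_detection <- function(params, delta_r,
                                 window = detection_window(),
                                 quad = quad_spec(),
                                 outer_nodes = 64) {
  stopifnot(inherits(params, "branching_params"), delta_r > 0)
  window <- as_detection_window(window)
  lo <- window[["lo"]]; hi <- window[["hi"]]
  if (lo == hi) return(0)
  if (params$u == 0) return(0)
  r2bg <- params$r1
  d2 <- params$b1 - (r2bg + delta_r)
  if (d2 < 0)
    stop("delta_r implies a negative second-driver death rate b1 - (r1 + delta_r)",
         call. = FALSE)

  params2 <- function(M2) {
    branching_params(b = params$b1, d = params$b1 - r2bg, b1 = params$b1,
                     d1 = d2, u = params$u, M = M2)
  }
  one_alpha1 <- function(a1) {
    p2 <- params2(a1 * params$M)
    F2hi <- if (hi / a1 >= 1) cdf_upper_limit(p2)
            else cdf_subclonal_frequency(p2, hi / a1, quad)
    F2lo <- cdf_subclonal_frequency(p2, lo / a1, quad)
    pdf_subclonal_frequency(params, a1, quad) * max(F2hi - F2lo, 0)
  }
  # integrate over w = log(1 - alpha1): the first driver's density
  # concentrates near fixation, where the log scale resolves it smoothly;
  # the truncation below beta = 1e-12 is far inside that concentration
  outer <- function(w) {
    vapply(w, function(ww) {
      beta <- exp(ww)
      beta * one_alpha1(1 - beta)
    }, numeric(1))
  }
  w_lo <- log(1e-12)
  w_hi <- log(1 - hi)
  if (is.null(outer_nodes)) {
    outer_quad <- quad_spec(rel_tol = max(quad$rel_tol, 1e-6), abs_tol = 1e-10,
                            max_subdivisions = quad$max_subdivisions)
    val <- integrate_checked(outer, w_lo, w_hi, outer_quad)
  } else {
    # composite Gauss-Legendre with panels refined toward w_hi, where the
    # integrand's mass concentrates; node counts scale with `outer_nodes`
    breaks <- c(w_lo, w_hi - 12, w_hi - 4, w_hi)
    orders <- pmax(8, round(outer_nodes * c(0.2, 0.35, 0.45)))
    val <- 0
    for (j in seq_along(orders)) {
      gl <- gauss_legendre(orders[j])
      half <- (breaks[j + 1] - breaks[j]) / 2
      mid <- (breaks[j + 1] + breaks[j]) / 2
      val <- val + half * sum(gl$weights * outer(mid + half * gl$nodes))
    }
  }
  clip_probability(val, tol = 1e-8, what = "P2")
}

#' Bounds on the driver mutation rate
#'
#' Each bound is the product of a driver-gene count, the average number of
#' positions per gene producing a functional driver, and a per-base-pair
#' mutation rate. The defaults combine genomic estimates: an upper bound of
#' 600 driver genes at a hypermutated point rate of `6e-8` /bp/day, and a
#' lower bound of 20 strong driver genes in one cancer type at `4e-11`
#' /bp/day, both with 90 driver positions per gene, giving rates on the
#' order of `1e-3` and `1e-7` per day.
#'
#' @param upper,lower [rate_bound_inputs()] for the upper and lower bound.
#' @return A tibble with one row per bound: the inputs and the resulting
#'   `rate` (per day).
#' @examples
#' driver_mutation_rate_bounds()
#' @export
driver_mutation_rate_bounds <- function(
    upper = rate_bound_inputs(600, 90, 6e-8),
    lower = rate_bound_inputs(20, 90, 4e-11)) {
  stopifnot(inherits(upper, "rate_bound_inputs"),
            inherits(lower, "rate_bound_inputs"))
  one <- function(x, which) {
    tibble::tibble(
      bound = which,
      n_driver_genes = x$n_driver_genes,
      positions_per_gene = x$positions_per_gene,
      per_bp_rate = x$per_bp_rate,
      rate = x$n_driver_genes * x$positions_per_gene * x$per_bp_rate
    )
  }
  dplyr::bind_rows(one(lower, "lower"), one(upper, "upper"))
}
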