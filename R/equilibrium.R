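# Equilibrium unfolding analysis: normalization of thermal/chemical melts to
# unfolded fraction and midpoint extraction from derivative maxima.

#' Normalize a melt to the unfolded fraction
#'
#' Maps a raw unfolding signal (mean residue ellipticity, emission peak
#' wavelength, ...) onto the fraction of unfolded protein,
#' `alpha = (theta_T - theta_f) / (theta_u - theta_f)`, which is 0 at the
#' folded baseline and 1 at the unfolded baseline. (The common shorthand
#' `alpha = (theta_T - theta_u)/(theta_u - theta_f)` found in print
#' evaluates to -1 at the folded baseline; the normalization implemented
#' here is the evident intent of that definition.) Values are clipped to
#' [-0.05, 1.05] and out-of-range points flagged.
#'
#' Baselines are either supplied as constants or fitted as linear segments
#' to the pre- and post-transition ends of the curve.
#'
#' @param curve Tibble with columns `x` (temperature K or denaturant M) and
#'   `signal`.
#' @param theta_f,theta_u Folded/unfolded baseline signals (constants);
#'   leave `NULL` to fit linear baselines.
#' @param baseline_frac Fraction of points at each end used for baseline
#'   fitting.
#' @return The curve with added columns `alpha` and `clipped`, and
#'   attribute `baselines`.
#' @export
fraction_unfolded <- function(curve, theta_f = NULL, theta_u = NULL,
                              baseline_frac = 0.15) {
  if (is.unsorted(curve$x, strictly = TRUE)) {
    abort("abscissa must be strictly increasing")
  }
  n <- nrow(curve)
  if (is.null(theta_f) || is.null(theta_u)) {
    k <- max(2L, floor(n * baseline_frac))
    pre <- stats::lm(signal ~ x, data = curve[seq_len(k), ])
    post <- stats::lm(signal ~ x, data = curve[(n - k + 1L):n, ])
    th_f <- stats::predict(pre, curve["x"])
    th_u <- stats::predict(post, curve["x"])
    baselines <- list(mode = "fitted", pre = stats::coef(pre),
                      post = stats::coef(post))
  } else {
    th_f <- rep(theta_f, n); th_u <- rep(theta_u, n)
    baselines <- list(mode = "supplied", theta_f = theta_f, theta_u = theta_u)
  }
  if (any(abs(th_u - th_f) < 1e-12)) {
    abort("degenerate baselines: theta_f equals theta_u")
  }
  alpha <- (curve$signal - th_f) / (th_u - th_f)
  clipped <- alpha < -0.05 | alpha > 1.05
  if (any(clipped)) {
    warn(sprintf("%d point(s) outside [-0.05, 1.05] were clipped", sum(clipped)))
  }
  curve$alpha <- pmin(1.05, pmax(-0.05, alpha))
  curve$clipped <- clipped
  attr(curve, "baselines") <- baselines
  curve
}

#' Melting midpoint from the normalized derivative
#'
#' Central-difference derivative of the unfolded fraction with respect to
#' the abscissa, normalized to unit peak; the midpoint (Tm or Cm) is the
#' parabolically interpolated position of the derivative maximum, and the
#' reported uncertainty is the half-width of the derivative peak at 90% of
#' its maximum.
#'
#' @param curve Tibble with columns `x` and `alpha` (see
#'   [fraction_unfolded()]).
#' @return A list with `midpoint`, `uncertainty`, and `derivative` (tibble
#'   `x`, `dalpha_dx`, `normalized`).
#' @export
midpoint_from_derivative <- function(curve) {
  x <- curve$x; a <- curve$alpha
  n <- length(x)
  if (n < 7L) abort("need at least 7 points spanning the transition")
  d <- numeric(n)
  d[2:(n - 1)] <- (a[3:n] - a[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (a[2] - a[1]) / (x[2] - x[1])
  d[n] <- (a[n] - a[n - 1]) / (x[n] - x[n - 1])
  k <- which.max(d)
  if (k == 1L || k == n) {
    abort("no interior derivative peak: no transition within the data range")
  }
  dn <- d / d[k]
  # parabolic interpolation: least-squares quadratic through the peak and
  # its neighbours (up to 2 on each side), vertex = midpoint
  win <- max(2, k - 2):min(n - 1, k + 2)
  qf <- stats::lm(d[win] ~ x[win] + I(x[win]^2))
  cf <- stats::coef(qf)
  midpoint <- if (is.na(cf[3]) || cf[3] >= 0) x[k] else
    unname(-cf[2] / (2 * cf[3]))
  h <- mean(diff(x)[pmax(1, win - 1)])
  if (!is.finite(midpoint) || abs(midpoint - x[k]) > h) midpoint <- x[k]
  # half-width at 90% of the normalized peak
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(k - 1)) else (k + 1):n
    for (i in idx) {
      if (dn[i] < 0.9) {
        # linear interpolation between i and its neighbour towards the peak
        j <- if (side == "left") i + 1L else i - 1L
        return(x[i] + (0.9 - dn[i]) * (x[j] - x[i]) / (dn[j] - dn[i]))
      }
    }
    NA_real_
  }
  xl <- cross("left"); xr <- cross("right")
  unc <- if (is.na(xl) || is.na(xr)) NA_real_ else (xr - xl) / 2
  list(midpoint = midpoint, uncertainty = unc,
       derivative = tibble(x = x, dalpha_dx = d, normalized = dn))
}
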