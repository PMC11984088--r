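# Circular helpers used throughout the pipeline. All public angles are in
# degrees on [0, 360); internal resultant computations are in radians.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360)
#'
#' @param x angles in degrees.
#' @return angles in degrees wrapped to `[0, 360)`.
#' @export
wrap_deg <- function(x) x %% 360

#' Signed shortest-arc difference between angles
#'
#' `circ_diff_deg(a, b)` is the signed circular difference `a - b` mapped to
#' `(-180, 180]`; `circ_dist_deg()` is its absolute value, the shortest-arc
#' distance.
#'
#' @param a,b angles in degrees.
#' @return difference (or distance) in degrees.
#' @export
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' @rdname circ_diff_deg
#' @export
circ_dist_deg <- function(a, b) abs(circ_diff_deg(a, b))

#' Weighted circular mean of angles
#'
#' @param x angles in degrees.
#' @param w optional non-negative weights (e.g. posterior probabilities).
#' @return circular mean in degrees in `[0, 360)`; `NA` if the resultant is
#'   (numerically) zero.
#' @export
circ_mean_deg <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  z <- sum(w * exp(1i * deg2rad(x)))
  if (Mod(z) < 1e-12 * max(sum(w), 1)) return(NA_real_)
  wrap_deg(rad2deg(Arg(z)))
}

# Mean resultant length of angles (degrees), optionally weighted.
circ_resultant <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  Mod(sum(w * exp(1i * deg2rad(x)))) / sum(w)
}

# Circular variance 1 - R of angles in degrees.
circ_var <- function(x, w = NULL) 1 - circ_resultant(x, w)

#' Unwrap a circular degree series
#'
#' Cumulative signed shortest-arc increments; the first value is kept
#' as-is, so the result is a continuous (non-wrapping) trace.
#'
#' @param x angles in degrees.
#' @return unwrapped angles.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  x[1] + c(0, cumsum(circ_diff_deg(x[-1], x[-length(x)])))
}

#' Circular-linear regression by resultant-length maximization
#'
#' Fits `phase ~ slope * x + intercept` where `phase` is circular (degrees)
#' and `x` is linear, by maximizing the mean resultant length of
#' `phase - slope * x` over a bounded slope range (coarse grid followed by a
#' local refinement). This is the standard estimator for phase-precession and
#' decoded-trajectory fits; bounding the slope is required because the
#' objective is periodic in `slope` for regularly spaced `x`.
#'
#' @param x linear covariate (normalized field position, or time in seconds).
#' @param phase_deg circular response in degrees.
#' @param slope_bounds numeric length-2, admissible slope range in degrees
#'   per unit of `x`.
#' @param n_grid number of coarse grid points across the slope range.
#' @return list with `slope` (deg per unit x), `intercept_deg` (phase at
#'   x = 0, degrees), and `resultant` (mean resultant length at the optimum,
#'   in `[0, 1]`).
#' @export
circ_lin_fit <- function(x, phase_deg, slope_bounds = c(-1080, 1080),
                         n_grid = 241L) {
  stopifnot(length(x) == length(phase_deg), length(x) >= 2)
  phi <- deg2rad(phase_deg)
  ephi <- exp(1i * phi)
  obj <- function(a) {
    Mod(mean(exp(1i * (phi - deg2rad(a) * x))))
  }
  grid <- seq(slope_bounds[1], slope_bounds[2], length.out = n_grid)
  # vectorized grid evaluation: one complex matrix product
  G <- exp(-1i * outer(deg2rad(grid), x))
  rg <- Mod(as.vector(G %*% ephi)) / length(x)
  i <- which.max(rg)
  step <- if (n_grid > 1) grid[2] - grid[1] else 0
  lo <- max(slope_bounds[1], grid[i] - step)
  hi <- min(slope_bounds[2], grid[i] + step)
  slope <- if (hi > lo) {
    stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum
  } else {
    grid[i]
  }
  z <- mean(exp(1i * (phi - deg2rad(slope) * x)))
  list(
    slope = slope,
    intercept_deg = wrap_deg(rad2deg(Arg(z))),
    resultant = Mod(z)
  )
}

#' Circular-linear correlation coefficient
#'
#' Correlation between a circular variable (degrees) and a linear variable,
#' computed from the Pearson correlations of the linear variable with the
#' sine and cosine components of the circular one. The magnitude lies in
#' `[0, 1]`; the p-value uses the chi-squared approximation
#' `n * r^2 ~ chisq(2)`.
#'
#' @param x linear variable.
#' @param phase_deg circular variable, degrees.
#' @return list with `r` and `p_value`.
#' @export
circ_lin_corr <- function(x, phase_deg) {
  stopifnot(length(x) == length(phase_deg))
  n <- length(x)
  phi <- deg2rad(phase_deg)
  s <- sin(phi); c <- cos(phi)
  if (stats::sd(x) == 0 || (stats::sd(s) == 0 && stats::sd(c) == 0)) {
    return(list(r = 0, p_value = 1))
  }
  rxs <- if (stats::sd(s) > 0) stats::cor(x, s) else 0
  rxc <- if (stats::sd(c) > 0) stats::cor(x, c) else 0
  rcs <- if (stats::sd(s) > 0 && stats::sd(c) > 0) stats::cor(c, s) else 0
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  r <- sqrt(max(0, min(1, r2)))
  list(r = r, p_value = stats::pchisq(n * r^2, df = 2, lower.tail = FALSE))
}

# Gaussian kernel over integer offsets, truncated at `trunc` sigma and
# renormalized to sum 1. sigma in bins (samples).
gauss_kernel <- function(sigma, trunc = 4) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(trunc * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

#' Gaussian smoothing on circular and linear supports
#'
#' `smooth_circular()` convolves a vector defined on equally spaced
#' circular bins with a wrap-around Gaussian kernel (truncated at `trunc`
#' standard deviations and renormalized); it preserves the vector's sum.
#' `smooth_linear()` smooths an ordinary series with edge renormalization,
#' so constants are preserved at the boundaries.
#'
#' @param x numeric vector.
#' @param sigma_bins,sigma_samples kernel SD in bins/samples.
#' @param trunc kernel truncation, in SDs.
#' @return smoothed vector of the same length.
#' @export
smooth_circular <- function(x, sigma_bins, trunc = 4) {
  k <- gauss_kernel(sigma_bins, trunc)
  if (length(k) == 1) return(x)
  if (length(k) > length(x)) {
    # fold the kernel onto the circle so it never exceeds the support
    idx <- ((seq_along(k) - (length(k) + 1) / 2) %% length(x)) + 1
    kf <- numeric(length(x))
    for (j in seq_along(k)) kf[idx[j]] <- kf[idx[j]] + k[j]
    # kf is centered at bin 1; smooth by circular convolution via filter
    n <- length(x)
    out <- numeric(n)
    for (s in seq_len(n)) {
      out[s] <- sum(x * kf[((s - seq_len(n)) %% n) + 1])
    }
    return(out)
  }
  as.numeric(stats::filter(x, k, method = "convolution", sides = 2,
                           circular = TRUE))
}

#' @rdname smooth_circular
#' @export
smooth_linear <- function(x, sigma_samples, trunc = 4) {
  k <- gauss_kernel(sigma_samples, trunc)
  if (length(k) == 1) return(x)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, length(x)), rev(k), type = "open")
  h <- (length(k) - 1) / 2
  idx <- seq.int(h + 1, h + length(x))
  num[idx] / den[idx]
}
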