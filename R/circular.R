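# Circular statistics and von Mises primitives.
#
# Convention used throughout the package: angles are degrees at every interface,
# radians internally, canonical range (-180, 180].

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap angles into the canonical range
#'
#' Maps any finite angle (degrees) to its congruent value in `(-180, 180]`.
#'
#' @param angle_deg numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in `(-180, 180]`.
#' @examples
#' wrap_deg(c(190, -180, 360))  # -170, 180, 0
#' @export
wrap_deg <- function(angle_deg) {
  if (!is.numeric(angle_deg)) stop("`angle_deg` must be numeric")
  if (any(!is.finite(angle_deg))) stop("non-finite angle")
  angle_deg - 360 * ceiling((angle_deg - 180) / 360)
}

#' Circular summary statistics
#'
#' Computes the (optionally weighted) circular mean, mean resultant length R,
#' circular variance `1 - R`, and angular dispersion (circular standard
#' deviation, `sqrt(-2 log R)` converted to degrees) of a sample of angles.
#'
#' @param angles_deg numeric vector of angles in degrees (at least one).
#' @param weights optional nonnegative weights, same length, positive sum.
#' @return a list of class `circ_summary` with elements `mean_deg` (`NA` when
#'   the mean direction is undefined), `mean_defined`, `R`, `variance`,
#'   `dispersion_deg` (`Inf` when `R = 0`) and `n`.
#' @details The mean direction is flagged undefined when `R < 1e-9` (e.g.
#'   antipodal cancellation), in which case `mean_deg` is `NA`.
#' @examples
#' circ_summary(c(0, 90))  # mean 45, R ~ 0.707
#' @export
circ_summary <- function(angles_deg, weights = NULL) {
  if (length(angles_deg) < 1L) stop("empty angle sample")
  if (any(!is.finite(angles_deg))) stop("non-finite angle")
  if (is.null(weights)) {
    weights <- rep(1, length(angles_deg))
  } else {
    if (length(weights) != length(angles_deg)) stop("weights length mismatch")
    if (any(weights < 0) || any(!is.finite(weights))) stop("weights must be finite and nonnegative")
    if (sum(weights) <= 0) stop("weights must have positive sum")
  }
  th <- angles_deg * DEG2RAD
  w <- sum(weights)
  C <- sum(weights * cos(th)) / w
  S <- sum(weights * sin(th)) / w
  R <- min(sqrt(C^2 + S^2), 1)
  defined <- R >= 1e-9
  structure(list(
    mean_deg = if (defined) wrap_deg(atan2(S, C) * RAD2DEG) else NA_real_,
    mean_defined = defined,
    R = R,
    variance = 1 - R,
    dispersion_deg = if (R > 0) sqrt(-2 * log(R)) * RAD2DEG else Inf,
    n = length(angles_deg)
  ), class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf(
    "circular summary (n = %d): mean %s deg, R = %.4f, variance = %.4f, dispersion = %s deg\n",
    x$n,
    if (x$mean_defined) sprintf("%.2f", x$mean_deg) else "undefined",
    x$R, x$variance,
    if (is.finite(x$dispersion_deg)) sprintf("%.2f", x$dispersion_deg) else "Inf"
  ))
  invisible(x)
}

#' Circular mean direction
#'
#' Convenience wrapper returning only the mean direction of [circ_summary()].
#'
#' @inheritParams circ_summary
#' @return mean direction in degrees, `NA` if undefined.
#' @export
circ_mean <- function(angles_deg, weights = NULL) {
  circ_summary(angles_deg, weights)$mean_deg
}

#' von Mises probability density
#'
#' Density `exp(kappa * cos(theta - mu)) / (2 pi I0(kappa))`, per radian,
#' evaluated at angles in degrees. `kappa = 0` gives the uniform density
#' `1 / (2 pi)`.
#'
#' @param theta_deg numeric vector of evaluation angles, degrees.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration, `>= 0`.
#' @return densities (per radian), same length as `theta_deg`.
#' @export
vm_pdf <- function(theta_deg, mu_deg, kappa) {
  if (!is.finite(kappa) || kappa < 0) stop("`kappa` must be finite and >= 0")
  d <- (theta_deg - mu_deg) * DEG2RAD
  # scaled Bessel keeps this stable for very large kappa
  exp(kappa * (cos(d) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Mean resultant length of a von Mises distribution
#'
#' The Bessel-function ratio `A1(kappa) = I1(kappa) / I0(kappa)`, i.e. the
#' population mean resultant length at concentration `kappa`.
#'
#' @param kappa concentration, `>= 0` (vectorised).
#' @return values in `[0, 1)`.
#' @export
vm_mean_resultant <- function(kappa) {
  if (any(kappa < 0)) stop("`kappa` must be >= 0")
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampling; uses R's RNG stream so draws are
#' reproducible under `set.seed()`.
#'
#' @param n number of draws, `>= 1`.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration, `>= 0`; `0` samples uniformly on the circle.
#' @return `n` angles in degrees, wrapped to `(-180, 180]`.
#' @references Best, D.J. and Fisher, N.I. (1979) Efficient simulation of the
#'   von Mises distribution. Applied Statistics 28, 152-157.
#' @export
vm_sample <- function(n, mu_deg, kappa) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  if (!is.finite(kappa) || kappa < 0) stop("`kappa` must be finite and >= 0")
  if (kappa == 0) {
    return(wrap_deg(stats::runif(n, -180, 180)))
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    nk <- sum(keep)
    if (nk > 0L) {
      u3 <- stats::runif(nk)
      out[(got + 1L):(got + nk)] <- sign(u3 - 0.5) * acos(f[keep])
      got <- got + nk
    }
  }
  wrap_deg(mu_deg + out * RAD2DEG)
}

#' Mean of the product of two von Mises distributions
#'
#' The product of two von Mises kernels is itself a von Mises kernel whose mean
#' is the direction of the resultant of the two concentration vectors:
#' `mu3 = mu1 + atan2(k2 sin(mu2 - mu1), k1 + k2 cos(mu2 - mu1))`.
#' The full-quadrant arctangent keeps the result correct when the two means are
#' nearly opposed. This is the posterior mean of a Bayesian observer combining
#' a prior (`mu1`, `k1`) with a likelihood (`mu2`, `k2`).
#'
#' @param mu1_deg,kappa1 mean (degrees) and concentration of the first kernel.
#' @param mu2_deg,kappa2 mean (degrees) and concentration of the second kernel.
#' @return product mean in degrees, wrapped to `(-180, 180]`. Vectorised over
#'   the means.
#' @export
vm_product_mean <- function(mu1_deg, kappa1, mu2_deg, kappa2) {
  if (any(kappa1 < 0) || any(kappa2 < 0)) stop("concentrations must be >= 0")
  if (all(kappa1 == 0) && all(kappa2 == 0)) stop("product mean undefined when both kappas are zero")
  d <- (mu2_deg - mu1_deg) * DEG2RAD
  wrap_deg(mu1_deg + atan2(kappa2 * sin(d), kappa1 + kappa2 * cos(d)) * RAD2DEG)
}

#' Resultant concentration of the product of two von Mises kernels
#'
#' `kappa3 = sqrt(k1^2 + k2^2 + 2 k1 k2 cos(mu2 - mu1))`, the concentration of
#' the (unnormalised) product kernel; used as the posterior concentration of
#' the Bayesian observer.
#'
#' @inheritParams vm_product_mean
#' @return concentration, `>= 0`.
#' @export
vm_product_kappa <- function(mu1_deg, kappa1, mu2_deg, kappa2) {
  d <- (mu2_deg - mu1_deg) * DEG2RAD
  sqrt(pmax(kappa1^2 + kappa2^2 + 2 * kappa1 * kappa2 * cos(d), 0))
}
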