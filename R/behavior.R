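# Bayesian cue-integration fits to reach behavior.
#
# The observer model: reach direction follows the mean of the product of a von
# Mises prior over target direction (mu1 = session prior mean, concentration
# k1) and a von Mises likelihood centred on the trial's cue centroid (mu2,
# concentration k2). Only the ratio r = k1/k2 is identifiable from the mean
# rule, and the reported summary is the cue-weighting slope
# w = k2/(k1 + k2) = 1/(1 + r): 1 = pure cue reliance, 0 = pure prior reliance.

#' Predicted reach direction of the cue-integration model
#'
#' @param prior_mean_deg prior mean direction, degrees.
#' @param centroid_deg cue centroid direction(s), degrees.
#' @param ratio concentration ratio `r = k1/k2 >= 0`.
#' @return predicted reach direction(s), degrees.
#' @export
predict_reach <- function(prior_mean_deg, centroid_deg, ratio) {
  vm_product_mean(prior_mean_deg, ratio, centroid_deg, 1)
}

#' Fit the cue-weighting model to one session and condition
#'
#' Finds the concentration ratio `r = k1/k2` minimising the sum of squared
#' wrapped residuals between observed reaches and the product-mean prediction
#' (the exact product-mean rule is used for prediction, not its small-angle
#' linearisation; the slope `w = 1/(1 + r)` is still the reported summary).
#' The 1-D objective is minimised over `log r` in `[-6, 6]` by a 1,000-point
#' grid followed by golden-section refinement, which avoids local minima and
#' the infinite-ratio degeneracies at the bounds.
#'
#' @param prior_mean_deg session prior mean, degrees.
#' @param centroids_deg per-trial cue centroids, degrees.
#' @param reaches_deg per-trial reach directions, degrees (same length).
#' @param condition condition label stored in the fit (`"low"`/`"high"`/other).
#' @param min_trials minimum number of trials required (default 10).
#' @return list of class `behavior_fit`: `condition`, `ratio`, `slope` (w),
#'   `sse` (degrees^2), `residuals_deg`, `dispersion_deg` (angular dispersion
#'   of the residuals = behavioral uncertainty), `n_trials`, `at_bound`,
#'   `identifiable`.
#' @export
fit_cue_weighting <- function(prior_mean_deg, centroids_deg, reaches_deg,
                              condition = NA_character_, min_trials = 10L) {
  if (length(centroids_deg) != length(reaches_deg)) {
    stop("centroids and reaches must be paired")
  }
  n <- length(reaches_deg)
  if (n < min_trials) stop("need at least ", min_trials, " trials, got ", n)
  identifiable <- diff(range(wrap_deg(centroids_deg - centroids_deg[1]))) > 1e-6
  if (!identifiable) warning("all cue centroids identical; ratio is unidentifiable")

  # precomputed-trig form of the product-mean prediction (k1 = r, k2 = 1)
  d <- wrap_deg(centroids_deg - prior_mean_deg) * DEG2RAD
  sd_ <- sin(d)
  cd_ <- cos(d)
  dev <- wrap_deg(reaches_deg - prior_mean_deg) * DEG2RAD
  sse_of <- function(logr) {
    pred <- atan2(sd_, exp(logr) + cd_)
    e <- (dev - pred) %% (2 * pi)
    e[e > pi] <- e[e > pi] - 2 * pi
    sum(e^2) * RAD2DEG^2
  }
  grid <- seq(-6, 6, length.out = 1000L)
  vals <- vapply(grid, sse_of, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(sse_of, c(lo, hi), tol = 1e-8)
  logr <- opt$minimum
  at_bound <- i == 1L || i == length(grid)
  if (at_bound) logr <- grid[i]
  ratio <- exp(logr)
  resid <- wrap_deg(reaches_deg - predict_reach(prior_mean_deg, centroids_deg, ratio))
  structure(list(
    condition = condition,
    ratio = ratio,
    slope = 1 / (1 + ratio),
    sse = sum(resid^2),
    residuals_deg = resid,
    dispersion_deg = circ_summary(resid)$dispersion_deg,
    n_trials = n,
    at_bound = at_bound,
    identifiable = identifiable
  ), class = "behavior_fit")
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat(sprintf("cue-weighting fit (%s, n = %d): w = %.3f (r = %.3g), dispersion = %.2f deg, sse = %.1f%s\n",
              x$condition, x$n_trials, x$slope, x$ratio, x$dispersion_deg, x$sse,
              if (x$at_bound) " [ratio at search bound]" else ""))
  invisible(x)
}

#' Behavioral uncertainty of a fit
#'
#' The angular dispersion (circular standard deviation, degrees) of the
#' residual reach errors around the fitted cue-integration prediction.
#'
#' @param fit a `behavior_fit`.
#' @return dispersion in degrees.
#' @export
behavioral_uncertainty <- function(fit) {
  stopifnot(inherits(fit, "behavior_fit"))
  if (length(fit$residuals_deg) == 0L) stop("fit has no residuals")
  circ_summary(fit$residuals_deg)$dispersion_deg
}

#' Session-level behavioral deltas
#'
#' The two session summaries driving the neural analyses:
#' `delta_cue_weighting = w_high - w_low` and
#' `delta_behavioral_uncertainty = dispersion_high - dispersion_low` (degrees).
#'
#' @param low,high `behavior_fit` objects for the low and high uncertainty
#'   conditions of the same session.
#' @return data.frame with one row: `delta_cue_weighting`,
#'   `delta_behavioral_uncertainty`.
#' @export
session_deltas <- function(low, high) {
  stopifnot(inherits(low, "behavior_fit"), inherits(high, "behavior_fit"))
  data.frame(
    delta_cue_weighting = high$slope - low$slope,
    delta_behavioral_uncertainty = high$dispersion_deg - low$dispersion_deg
  )
}

#' Fit behavior for every uncertainty condition of a session
#'
#' @param session a [reach_session()].
#' @param min_trials per-condition minimum trial count.
#' @return list with `fits` (named list of `behavior_fit`, conditions `low`,
#'   `high`) and `deltas` (one-row data.frame with `session_id` prepended).
#' @export
fit_session_behavior <- function(session, min_trials = 10L) {
  tr <- session$trials[session$trials$block == "uncertainty", ]
  if (nrow(tr) == 0L) stop("no uncertainty trials in session ", session$session_id)
  fits <- lapply(c(low = "low", high = "high"), function(cond) {
    tc <- tr[tr$condition == cond, ]
    if (nrow(tc) == 0L) return(NULL)
    fit_cue_weighting(tc$prior_mean_deg[1], tc$cue_centroid_deg, tc$reach_deg,
                      condition = cond, min_trials = min_trials)
  })
  deltas <- if (!is.null(fits$low) && !is.null(fits$high)) {
    cbind(session_id = session$session_id, session_deltas(fits$low, fits$high))
  }
  list(fits = fits, deltas = deltas)
}
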