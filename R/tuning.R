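# Directional tuning: Poisson GLM with cosine drive,
#   counts ~ Poisson(duration * exp(alpha + beta * cos(theta - pd))),
# fitted in the equivalent linear parameterisation
#   log rate = alpha + b1 cos(theta) + b2 sin(theta),
# with beta = sqrt(b1^2 + b2^2) and pd = atan2(b2, b1). Exposure enters as an
# offset of log duration so alpha is in log spikes/s.

#' Spike counts per trial in an analysis epoch
#'
#' Counts spikes whose aligned time falls in the half-open window
#' `[start_ms, end_ms)` of `epoch`, for every trial and neuron.
#'
#' @param spikes spike-events data.frame (`trial_id`, `neuron_id`, `t_s`).
#' @param trials trials data.frame.
#' @param epoch an [epoch_window()].
#' @param neuron_ids neurons to include (default: all in `spikes`).
#' @return list of class `epoch_counts`: `epoch`, `trial_id`, `counts`
#'   (trials x neurons integer matrix), `durations_s` (per trial),
#'   `directions_deg` (per-trial reach direction), `conditions`.
#' @export
epoch_spike_counts <- function(spikes, trials, epoch, neuron_ids = NULL) {
  counts <- window_count_matrix(spikes, trials, epoch, neuron_ids)
  structure(list(
    epoch = epoch,
    trial_id = trials$trial_id,
    counts = counts,
    durations_s = rep((epoch$end_ms - epoch$start_ms) / 1000, nrow(trials)),
    directions_deg = trials$reach_deg,
    conditions = trials$condition
  ), class = "epoch_counts")
}

#' Fit cosine tuning by Poisson GLM
#'
#' Maximum-likelihood fit of the cosine tuning model to one neuron's epoch
#' counts via [stats::glm()] with Poisson family and log-duration offset.
#'
#' @param counts nonnegative integer spike counts, one per trial.
#' @param durations_s epoch durations in seconds (positive, same length).
#' @param directions_deg reach directions in degrees (same length).
#' @return list of class `tuning_fit`: `alpha` (log spikes/s), `beta` (>= 0),
#'   `pd_deg`, `pd_stable` (FALSE when modulation is numerically zero),
#'   `converged`, `all_zero`, `loglik`, `n_trials`.
#' @export
fit_poisson_tuning <- function(counts, durations_s, directions_deg) {
  n <- length(counts)
  if (length(durations_s) != n || length(directions_deg) != n) stop("length mismatch")
  if (n < 8L) stop("need at least 8 trials")
  if (length(unique(round(wrap_deg(directions_deg), 6))) < 3L) {
    stop("need at least 3 distinct directions")
  }
  if (any(durations_s <= 0)) stop("durations must be positive")
  if (all(counts == 0L)) {
    return(structure(list(alpha = -Inf, beta = 0, pd_deg = NA_real_,
                          pd_stable = FALSE, converged = TRUE, all_zero = TRUE,
                          loglik = 0, n_trials = n), class = "tuning_fit"))
  }
  th <- directions_deg * DEG2RAD
  dat <- data.frame(y = counts, c = cos(th), s = sin(th), off = log(durations_s))
  fit <- suppressWarnings(
    stats::glm(y ~ c + s + offset(off), family = stats::poisson(), data = dat,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  b <- stats::coef(fit)
  beta <- sqrt(b[["c"]]^2 + b[["s"]]^2)
  structure(list(
    alpha = unname(b[["(Intercept)"]]),
    beta = unname(beta),
    pd_deg = if (beta > 1e-6) wrap_deg(atan2(b[["s"]], b[["c"]]) * RAD2DEG) else NA_real_,
    pd_stable = beta > 1e-6,
    converged = fit$converged,
    all_zero = FALSE,
    loglik = as.numeric(stats::logLik(fit)),
    n_trials = n
  ), class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("cosine tuning fit (n = %d): alpha = %.3f (rate %.1f sp/s), beta = %.3f, pd = %s deg\n",
              x$n_trials, x$alpha, exp(x$alpha), x$beta,
              if (x$pd_stable) sprintf("%.1f", x$pd_deg) else "unstable"))
  if (!is.null(x$significant)) {
    cat(sprintf("  bootstrap: %d refits, significant (%.0f deg criterion): %s\n",
                length(x$pd_boot_deg), x$criterion_deg,
                if (isTRUE(x$unfit)) "unfit" else as.character(x$significant)))
  }
  invisible(x)
}

# Weighted Newton solver for the 3-parameter Poisson cosine model, vectorised
# over B weight vectors (bootstrap replicates expressed as multinomial trial
# weights). X is the n x 3 design [1, cos, sin]; off the log-exposure.
# Returns a 3 x B coefficient matrix with NA columns where a refit failed.
pois_cos_newton <- function(y, X, off, W, beta0, max_iter = 60L, tol = 1e-8) {
  n <- length(y)
  B <- ncol(W)
  Beta <- matrix(beta0, nrow = 3L, ncol = B)
  cX <- X[, 2L]
  sX <- X[, 3L]
  yW <- W * y
  ok <- colSums(yW) > 0            # all-zero resample: alpha diverges
  active <- ok
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    Eta <- X %*% Beta[, idx, drop = FALSE] + off
    Eta[Eta > 30] <- 30
    Mu <- exp(Eta)
    WM <- W[, idx, drop = FALSE] * Mu
    G <- crossprod(X, yW[, idx, drop = FALSE] - WM)   # 3 x b gradient
    h11 <- colSums(WM); h12 <- colSums(WM * cX); h13 <- colSums(WM * sX)
    h22 <- colSums(WM * cX * cX); h23 <- colSums(WM * cX * sX)
    h33 <- colSums(WM * sX * sX)
    # closed-form symmetric 3x3 inverse, vectorised over replicates
    A11 <- h22 * h33 - h23 * h23
    A12 <- h13 * h23 - h12 * h33
    A13 <- h12 * h23 - h13 * h22
    A22 <- h11 * h33 - h13 * h13
    A23 <- h12 * h13 - h11 * h23
    A33 <- h11 * h22 - h12 * h12
    det <- h11 * A11 + h12 * A12 + h13 * A13
    bad <- !is.finite(det) | abs(det) < 1e-12
    det[bad] <- 1
    d1 <- (A11 * G[1L, ] + A12 * G[2L, ] + A13 * G[3L, ]) / det
    d2 <- (A12 * G[1L, ] + A22 * G[2L, ] + A23 * G[3L, ]) / det
    d3 <- (A13 * G[1L, ] + A23 * G[2L, ] + A33 * G[3L, ]) / det
    step <- rbind(d1, d2, d3)
    # damp oversized steps for stability
    nrm <- sqrt(colSums(step^2))
    shrink <- pmin(1, 4 / pmax(nrm, 1e-12))
    step <- sweep(step, 2L, shrink, `*`)
    Beta[, idx] <- Beta[, idx, drop = FALSE] + step
    conv <- apply(abs(G), 2L, max) < tol
    fail <- bad | !is.finite(colSums(step))
    ok[idx[fail]] <- FALSE
    active[idx] <- !(conv | fail)
    if (it == max_iter) ok[active] <- FALSE   # non-converged
  }
  Beta[, !ok] <- NA_real_
  list(coef = Beta, ok = ok)
}

#' Bootstrap preferred-direction significance
#'
#' Trial-resampling bootstrap (with replacement, same n; implemented as
#' multinomial trial weights) of the cosine tuning fit. A neuron is
#' significantly tuned when at least 95% of the bootstrap preferred-direction
#' estimates lie within `criterion_deg` of their circular mean (default 45
#' degrees; 90 is the relaxation used for low neuron counts).
#'
#' @param counts,durations_s,directions_deg as in [fit_poisson_tuning()].
#' @param n_boot number of bootstrap refits (>= 100; default 1000).
#' @param criterion_deg angular criterion, 45 or 90.
#' @param seed optional integer seed (set locally).
#' @return `tuning_fit` with added fields `pd_boot_deg`, `significant`,
#'   `criterion_deg`, `n_boot`, `boot_fail_rate` and `unfit` (TRUE when more
#'   than 10% of refits failed, in which case `significant` is NA).
#' @export
bootstrap_pd_significance <- function(counts, durations_s, directions_deg,
                                      n_boot = 1000L, criterion_deg = 45,
                                      seed = NULL) {
  if (n_boot < 100L) stop("`n_boot` must be >= 100")
  fit <- fit_poisson_tuning(counts, durations_s, directions_deg)
  n <- length(counts)
  if (!is.null(seed)) set.seed(seed)
  W <- stats::rmultinom(n_boot, n, rep(1 / n, n))
  th <- directions_deg * DEG2RAD
  X <- cbind(1, cos(th), sin(th))
  pd0 <- if (is.na(fit$pd_deg)) 0 else fit$pd_deg
  beta0 <- if (fit$all_zero) c(log(0.5 / mean(durations_s)), 0, 0) else {
    c(fit$alpha, fit$beta * cos(pd0 * DEG2RAD), fit$beta * sin(pd0 * DEG2RAD))
  }
  res <- pois_cos_newton(counts, X, log(durations_s), W, beta0)
  pd_boot <- rep(NA_real_, n_boot)
  okc <- res$ok
  pd_boot[okc] <- wrap_deg(atan2(res$coef[3L, okc], res$coef[2L, okc]) * RAD2DEG)
  fail_rate <- mean(!okc)
  unfit <- fail_rate > 0.10
  significant <- NA
  if (!unfit) {
    pds <- pd_boot[okc]
    anchor <- circ_mean(pds)
    significant <- if (is.na(anchor)) FALSE else {
      mean(abs(wrap_deg(pds - anchor)) <= criterion_deg) >= 0.95
    }
  }
  fit$pd_boot_deg <- pd_boot
  fit$significant <- significant
  fit$criterion_deg <- criterion_deg
  fit$n_boot <- n_boot
  fit$boot_fail_rate <- fail_rate
  fit$unfit <- unfit
  fit
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Fit tuning for all neurons of a session
#'
#' Counts spikes in the requested epochs over the chosen trial block
#' (center-out by default, as preferred directions are characterised from
#' zero-uncertainty reaches) and runs the bootstrap significance test for each
#' neuron.
#'
#' @param session a [reach_session()].
#' @param epochs named list of [epoch_window()] (default: visual, delay,
#'   movement).
#' @param block trial block used for fitting (default `"center_out"`).
#' @param n_boot,criterion_deg,seed passed to [bootstrap_pd_significance()].
#' @return data.frame of class `tuning_table`: one row per neuron x epoch with
#'   `session_id`, `neuron_id`, `epoch`, `alpha`, `beta`, `pd_deg`,
#'   `significant`, `unfit`, `criterion_deg`, `n_boot`.
#' @export
fit_session_tuning <- function(session, epochs = default_epochs()[c("visual", "delay", "movement")],
                               block = "center_out", n_boot = 1000L,
                               criterion_deg = 45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- session$trials[session$trials$block == block, ]
  if (nrow(trials) == 0L) stop("no trials in block ", block)
  spikes <- session$spikes[session$spikes$trial_id %in% trials$trial_id, ]
  neuron_ids <- sort(unique(session$spikes$neuron_id))
  rows <- list()
  for (ep_name in names(epochs)) {
    ec <- epoch_spike_counts(spikes, trials, epochs[[ep_name]], neuron_ids)
    for (nid in neuron_ids) {
      f <- bootstrap_pd_significance(ec$counts[, nid], ec$durations_s,
                                     ec$directions_deg, n_boot = n_boot,
                                     criterion_deg = criterion_deg)
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = session$session_id, neuron_id = nid, epoch = ep_name,
        alpha = f$alpha, beta = f$beta, pd_deg = f$pd_deg,
        significant = isTRUE(f$significant), unfit = isTRUE(f$unfit),
        criterion_deg = criterion_deg, n_boot = n_boot
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tuning_table", class(out))
  out
}

#' Fraction of significantly tuned neurons
#'
#' @param fits a `tuning_table` (or compatible data.frame with `epoch`,
#'   `significant`, `unfit` columns).
#' @param epoch epoch name to evaluate.
#' @return percentage (0-100) of fit-able neurons (not `unfit`) that are
#'   significantly tuned in `epoch`.
#' @export
tuned_fraction <- function(fits, epoch) {
  f <- fits[fits$epoch == epoch & !fits$unfit, ]
  if (nrow(f) == 0L) stop("no fit-able neurons for epoch ", epoch)
  100 * mean(f$significant)
}
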