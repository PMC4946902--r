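# Single-trial decoding of reach direction from PD-binned population activity.
#
# Neurons are grouped into sixteen 22.5-degree preferred-direction bins (PDs
# from the zero-uncertainty center-out block); per trial, the baseline-
# subtracted rates are averaged within bins and a cosine is fitted to the bin
# profile. The cosine peak is the decoded direction, and performance is one
# minus the circular variance of the decode errors.

N_PD_BINS <- 16L
PD_BIN_WIDTH <- 360 / N_PD_BINS

#' Assign neurons to preferred-direction bins
#'
#' Bin `b` (1-based) covers `[-180 + 22.5 (b - 1), -180 + 22.5 b)` degrees;
#' +180 is identified with -180 and falls in bin 1.
#'
#' @param pds_deg named numeric vector of preferred directions (names =
#'   neuron ids), degrees.
#' @return integer vector of bin indices in `1..16`, same names.
#' @export
build_pd_bins <- function(pds_deg) {
  if (any(!is.finite(pds_deg))) stop("all PDs must be finite")
  bins <- floor(((pds_deg + 180) %% 360) / PD_BIN_WIDTH) + 1L
  storage.mode(bins) <- "integer"
  bins
}

pd_bin_centers <- function() -180 + PD_BIN_WIDTH * (seq_len(N_PD_BINS) - 0.5)

#' Decode one trial from a PD-bin activity profile
#'
#' Least-squares fit of `a + b cos(phi - phi0)` to the profile over occupied
#' bin centers `phi` (linear fit in `cos phi`, `sin phi`); the decoded
#' direction is `phi0`. Bins without neurons are excluded from the fit; at
#' least `min_bins` occupied bins are required.
#'
#' @param bin_profile length-16 numeric: mean baseline-subtracted rate per PD
#'   bin, `NA` for empty bins.
#' @param min_bins minimum occupied bins (default 8).
#' @return decoded direction in degrees, or `NA` with attribute
#'   `reason = "flat"` when the fitted amplitude is below `1e-9`.
#' @export
decode_trial <- function(bin_profile, min_bins = 8L) {
  if (length(bin_profile) != N_PD_BINS) stop("profile must have 16 bins")
  occ <- is.finite(bin_profile)
  if (sum(occ) < min_bins) {
    stop("undecodable trial: only ", sum(occ), " occupied bins (need ", min_bins, ")")
  }
  phi <- pd_bin_centers()[occ] * DEG2RAD
  y <- bin_profile[occ]
  X <- cbind(1, cos(phi), sin(phi))
  cf <- stats::lm.fit(X, y)$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  if (!is.finite(amp) || amp < 1e-9) {
    return(structure(NA_real_, reason = "flat"))
  }
  wrap_deg(atan2(cf[3], cf[2]) * RAD2DEG)
}

#' Decoder performance
#'
#' One minus the circular variance of the decode errors, i.e. the mean
#' resultant length of the error sample. 1 = perfect decoding, 0 = chance.
#'
#' @param errors_deg decode errors (decoded - reach, wrapped), degrees;
#'   `NA` entries (undecodable/flat trials) are dropped.
#' @return performance in `[0, 1]`.
#' @export
decoder_performance <- function(errors_deg) {
  e <- errors_deg[is.finite(errors_deg)]
  if (length(e) == 0L) stop("no defined decode errors")
  1 - circ_summary(e)$variance
}

#' Decode a session across time windows and conditions
#'
#' Decodes every uncertainty-block trial in each analysis window from the
#' PD-binned population profile (center-out PDs), and summarises performance
#' per window and condition. A session-wide inclusion flag marks sessions
#' whose mean low-uncertainty performance exceeds `inclusion_threshold`.
#'
#' @param session a [reach_session()].
#' @param pds_deg named vector of center-out preferred directions (degrees)
#'   for the neurons to use (typically significantly tuned neurons).
#' @param windows list of [epoch_window()]; default four 200-ms windows
#'   spanning target appearance to movement (the last aligned to movement
#'   onset).
#' @param conditions conditions to decode (default low and high).
#' @param inclusion_threshold low-condition performance required for the
#'   session to be `included` (default 0.5).
#' @param min_bins minimum occupied PD bins per trial.
#' @return list with `results` (data.frame: `session_id`, `window`,
#'   `condition`, `n_trials`, `n_decoded`, `performance`, `included`) and
#'   `trial_errors` (list, per window x condition, of per-trial wrapped
#'   decode errors in degrees).
#' @export
decode_session <- function(session, pds_deg, windows = NULL,
                           conditions = c("low", "high"),
                           inclusion_threshold = 0.5, min_bins = 8L) {
  if (is.null(windows)) {
    windows <- list(
      epoch_window("target_0_200", "target_on", 0, 200),
      epoch_window("target_200_400", "target_on", 200, 400),
      epoch_window("target_400_600", "target_on", 400, 600),
      epoch_window("move_0_200", "move_on", 0, 200)
    )
  }
  bins <- build_pd_bins(pds_deg)
  trials <- session$trials[session$trials$condition %in% conditions, ]
  if (nrow(trials) == 0L) stop("no trials in requested conditions")
  spikes <- session$spikes[session$spikes$trial_id %in% trials$trial_id, ]
  rows <- list()
  errs <- list()
  for (w in windows) {
    dr <- delta_rate_matrix(spikes, trials, w, names(pds_deg))
    # mean profile per trial x bin
    profile <- t(apply(dr, 1L, function(v) {
      vapply(seq_len(N_PD_BINS), function(b) {
        sel <- bins == b
        if (!any(sel)) NA_real_ else mean(v[sel])
      }, 0)
    }))
    decoded <- apply(profile, 1L, function(p) {
      tryCatch(as.numeric(decode_trial(p, min_bins = min_bins)),
               error = function(e) NA_real_)
    })
    err <- wrap_deg_na(decoded - trials$reach_deg)
    for (cond in conditions) {
      sel <- trials$condition == cond
      e <- err[sel]
      perf <- if (any(is.finite(e))) decoder_performance(e) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = session$session_id, window = w$name, condition = cond,
        n_trials = sum(sel), n_decoded = sum(is.finite(e)), performance = perf
      )
      errs[[paste(w$name, cond, sep = ".")]] <- e
    }
  }
  results <- do.call(rbind, rows)
  low_perf <- results$performance[results$condition == "low"]
  results$included <- mean(low_perf, na.rm = TRUE) > inclusion_threshold
  list(results = results, trial_errors = errs)
}

wrap_deg_na <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  out[ok] <- wrap_deg(x[ok])
  out
}

#' Paired comparison of decoder performance between conditions
#'
#' Paired t-test of the per-session low-minus-high performance difference in
#' one window, over included sessions.
#'
#' @param results data.frame of stacked [decode_session()] `results` rows
#'   across sessions.
#' @param window window name to compare.
#' @param min_sessions minimum number of included sessions (default 3).
#' @return one-row data.frame: `window`, `n_sessions`, `mean_diff`
#'   (low - high), `t`, `p`.
#' @export
compare_conditions <- function(results, window, min_sessions = 3L) {
  r <- results[results$window == window & results$included, ]
  lo <- r[r$condition == "low", c("session_id", "performance")]
  hi <- r[r$condition == "high", c("session_id", "performance")]
  m <- merge(lo, hi, by = "session_id", suffixes = c("_low", "_high"))
  m <- m[is.finite(m$performance_low) & is.finite(m$performance_high), ]
  if (nrow(m) < min_sessions) {
    stop("need at least ", min_sessions, " included sessions, got ", nrow(m))
  }
  d <- m$performance_low - m$performance_high
  if (stats::sd(d) < 1e-15) {
    return(data.frame(window = window, n_sessions = nrow(m),
                      mean_diff = mean(d), t = NA_real_, p = 1))
  }
  tt <- stats::t.test(d)
  data.frame(window = window, n_sessions = nrow(m), mean_diff = mean(d),
             t = unname(tt$statistic), p = tt$p.value)
}
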