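# Study-level pipeline: per-session behavior fits, tuning fits, direction-
# group rate differences, and cross-session regressions against the
# behavioral uncertainty contrast.

#' Analyse one session end to end
#'
#' Fits behavior for both uncertainty conditions, fits (bootstrap-validated)
#' tuning on the center-out block for the requested epoch, and computes the
#' SD/ORTH/OD rate differences in the analysis window.
#'
#' @param session a [reach_session()].
#' @param window analysis window (default 500-700 ms after target onset, the
#'   headline comparison window).
#' @param epoch_name tuning epoch providing the PDs (default `"delay"`).
#' @param area restrict to neurons of this area when ground truth is present
#'   (default `"PMd"`; `NULL` uses all neurons).
#' @param n_boot_tuning bootstrap refits per neuron for PD significance.
#' @param criterion_deg PD significance criterion, degrees.
#' @param groups direction groups to evaluate.
#' @param n_boot_delta bootstrap replicates for the per-group delta CI.
#' @return list: `behavior` (fits + deltas), `tuning` (tuning table),
#'   `group_deltas` (data.frame), `metrics` (one-row data.frame with
#'   session_id, behavioral deltas, per-group deltas, tuned fraction).
#' @export
analyze_session <- function(session,
                            window = epoch_window("target_500_700", "target_on", 500, 700),
                            epoch_name = "delay", area = "PMd",
                            n_boot_tuning = 200L, criterion_deg = 45,
                            groups = c("SD", "ORTH", "OD"),
                            n_boot_delta = 0L) {
  ses <- session
  if (!is.null(area) && !is.null(ses$neurons) && "area" %in% names(ses$neurons)) {
    keep <- ses$neurons$neuron_id[ses$neurons$area %in% area]
    ses$spikes <- ses$spikes[ses$spikes$neuron_id %in% keep, ]
    ses$neurons <- ses$neurons[ses$neurons$neuron_id %in% keep, ]
  }
  behavior <- fit_session_behavior(ses)
  epochs <- default_epochs()[epoch_name]
  tuning <- fit_session_tuning(ses, epochs = epochs, n_boot = n_boot_tuning,
                               criterion_deg = criterion_deg)
  epf <- tuning[tuning$epoch == epoch_name & tuning$significant &
                  !is.na(tuning$pd_deg), ]
  if (nrow(epf) > 0L) {
    trials <- ses$trials[ses$trials$condition %in% c("low", "high"), ]
    spikes <- ses$spikes[ses$spikes$trial_id %in% trials$trial_id, ]
    dr <- delta_rate_matrix(spikes, trials, window, epf$neuron_id)
    grp <- outer(trials$reach_deg, epf$pd_deg,
                 function(r, p) partition_direction_groups(p, r))
    deltas <- group_delta_core(dr, grp, trials$condition, c("low", "high"), groups)
    gd <- data.frame(session_id = ses$session_id, group = groups,
                     window = window$name, delta = unname(deltas),
                     ci_lo = NA_real_, ci_hi = NA_real_,
                     n_neurons = vapply(groups, function(g)
                       sum(apply(grp == g, 2L, any)), 0L))
    if (n_boot_delta > 0L) {
      for (g in groups) {
        r <- group_rate_difference(ses, tuning, g, window,
                                   epoch_name = epoch_name,
                                   n_boot = n_boot_delta)
        gd[gd$group == g, c("ci_lo", "ci_hi")] <- r[, c("ci_lo", "ci_hi")]
      }
    }
  } else {
    gd <- data.frame(session_id = ses$session_id, group = groups,
                     window = window$name, delta = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_, n_neurons = 0L)
  }
  rownames(gd) <- NULL
  metrics <- data.frame(
    session_id = ses$session_id,
    delta_cue_weighting = behavior$deltas$delta_cue_weighting,
    delta_behavioral_uncertainty = behavior$deltas$delta_behavioral_uncertainty,
    tuned_fraction = tuned_fraction(tuning, epoch_name)
  )
  for (g in groups) {
    metrics[[paste0(tolower(g), "_delta")]] <- gd$delta[gd$group == g]
  }
  list(behavior = behavior, tuning = tuning, group_deltas = gd, metrics = metrics)
}

#' Analyse a study of sessions
#'
#' Runs [analyze_session()] on every session and regresses the per-session
#' group rate deltas on the behavioral uncertainty contrast.
#'
#' @param sessions a `reach_study` (from [generate_study()]) or list of
#'   [reach_session()].
#' @param ... passed to [analyze_session()].
#' @return list of class `study_analysis`: `session_metrics` (one row per
#'   session), `regressions` (one `regression_result` row per group),
#'   `session_results` (list of per-session [analyze_session()] outputs).
#' @export
analyze_study <- function(sessions, ...) {
  if (inherits(sessions, "reach_study")) sessions <- sessions$sessions
  res <- lapply(sessions, analyze_session, ...)
  metrics <- do.call(rbind, lapply(res, `[[`, "metrics"))
  groups <- intersect(c("sd_delta", "orth_delta", "od_delta"), names(metrics))
  regs <- do.call(rbind, lapply(groups, function(g) {
    tryCatch(
      uncertainty_activity_regression(metrics[[g]],
                                      metrics$delta_behavioral_uncertainty,
                                      group = toupper(sub("_delta$", "", g)),
                                      window = res[[1]]$group_deltas$window[1]),
      error = function(e) NULL)
  }))
  structure(list(session_metrics = metrics, regressions = regs,
                 session_results = res), class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("study analysis: %d sessions\n", nrow(x$session_metrics)))
  cat(sprintf("  mean delta cue weighting: %.3f; mean delta behavioral uncertainty: %.1f deg\n",
              mean(x$session_metrics$delta_cue_weighting),
              mean(x$session_metrics$delta_behavioral_uncertainty)))
  if (!is.null(x$regressions)) {
    for (i in seq_len(nrow(x$regressions))) {
      r <- x$regressions[i, ]
      cat(sprintf("  %-4s slope = %+.4f (sp/s)/deg, r2 = %.2f, p = %.3g (n = %d)\n",
                  r$group, r$slope, r$r2, r$p, r$n_sessions))
    }
  }
  invisible(x)
}

#' Decode every session of a study
#'
#' Uses each session's significantly tuned center-out PDs from `epoch_name`
#' to decode the uncertainty-block trials, then compares conditions per
#' window across included sessions.
#'
#' @param sessions a `reach_study` or list of [reach_session()].
#' @param tuning_list optional list of tuning tables (recomputed if missing).
#' @param epoch_name tuning epoch for the decoder PDs (default `"delay"`).
#' @param area area restriction as in [analyze_session()].
#' @param ... passed to [decode_session()].
#' @return list: `results` (stacked per-session decode results),
#'   `comparisons` (one row per window from [compare_conditions()], `NA` rows
#'   where too few sessions were included).
#' @export
decode_study <- function(sessions, tuning_list = NULL, epoch_name = "delay",
                         area = "PMd", ...) {
  if (inherits(sessions, "reach_study")) sessions <- sessions$sessions
  all_res <- list()
  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    if (!is.null(area) && !is.null(ses$neurons) && "area" %in% names(ses$neurons)) {
      keep <- ses$neurons$neuron_id[ses$neurons$area %in% area]
      ses$spikes <- ses$spikes[ses$spikes$neuron_id %in% keep, ]
      ses$neurons <- ses$neurons[ses$neurons$neuron_id %in% keep, ]
    }
    tuning <- if (!is.null(tuning_list)) tuning_list[[i]] else {
      fit_session_tuning(ses, epochs = default_epochs()[epoch_name],
                         n_boot = 200L)
    }
    tf <- tuning[tuning$epoch == epoch_name & tuning$significant &
                   !is.na(tuning$pd_deg), ]
    if (nrow(tf) == 0L) next
    pds <- stats::setNames(tf$pd_deg, tf$neuron_id)
    dec <- tryCatch(decode_session(ses, pds, ...), error = function(e) NULL)
    if (!is.null(dec)) all_res[[length(all_res) + 1L]] <- dec$results
  }
  results <- do.call(rbind, all_res)
  comparisons <- do.call(rbind, lapply(unique(results$window), function(w) {
    tryCatch(compare_conditions(results, w),
             error = function(e) data.frame(window = w, n_sessions = NA_integer_,
                                            mean_diff = NA_real_, t = NA_real_,
                                            p = NA_real_))
  }))
  list(results = results, comparisons = comparisons)
}
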