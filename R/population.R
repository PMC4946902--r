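# Population analyses: PD-offset spatiotemporal maps, the SD/ORTH/OD
# direction-group partition, uncertainty-condition rate differences, and
# cross-session regressions against the behavioral deltas.

#' Partition a neuron-trial into a direction group
#'
#' Classifies the offset `wrap(pd - reach)` into same-direction (SD, offset in
#' `[-45, 45)`), opposite-direction (OD, offset in `[135, 180]` or
#' `[-180, -135)`) or orthogonal (ORTH, everything else). The three labels
#' tile the circle.
#'
#' @param pd_deg preferred direction(s), degrees.
#' @param reach_deg reach direction(s), degrees.
#' @return character vector of labels `"SD"`, `"ORTH"`, `"OD"`.
#' @export
partition_direction_groups <- function(pd_deg, reach_deg) {
  offset <- wrap_deg(pd_deg - reach_deg)
  out <- rep("ORTH", length(offset))
  out[offset >= -45 & offset < 45] <- "SD"
  out[offset >= 135 | offset < -135] <- "OD"
  out
}

#' Pre-target baseline firing rate
#'
#' Spike count in the baseline window divided by its duration, per trial and
#' neuron.
#'
#' @param spikes,trials as in [epoch_spike_counts()].
#' @param window baseline [epoch_window()] (default `[-300, 0)` ms before
#'   target onset).
#' @param neuron_ids neurons to include.
#' @return trials x neurons matrix of rates in spikes/s.
#' @export
baseline_rate <- function(spikes, trials, window = default_epochs()$baseline,
                          neuron_ids = NULL) {
  counts <- window_count_matrix(spikes, trials, window, neuron_ids)
  counts / ((window$end_ms - window$start_ms) / 1000)
}

# Baseline-subtracted rate matrix (trials x neurons) for a window.
delta_rate_matrix <- function(spikes, trials, window, neuron_ids = NULL,
                              baseline_window = default_epochs()$baseline) {
  r <- window_count_matrix(spikes, trials, window, neuron_ids) /
    ((window$end_ms - window$start_ms) / 1000)
  b <- baseline_rate(spikes, trials, baseline_window, neuron_ids)
  r - b
}

#' Spatiotemporal PD-offset activity map
#'
#' Bins every (trial, neuron) contribution by the offset between the neuron's
#' preferred direction and the trial's reach direction, and by time, and
#' averages the baseline-subtracted firing rate per cell. Only neurons with
#' significant tuning contribute; each time bin uses the PDs of the matching
#' epoch (target-aligned bins before 250 ms use visual-epoch PDs, later
#' target-aligned bins delay-epoch PDs; movement-aligned bins movement-epoch
#' PDs).
#'
#' @param session a [reach_session()].
#' @param fits `tuning_table` from [fit_session_tuning()].
#' @param alignment `"target_on"` or `"move_on"`.
#' @param t_start_ms,t_end_ms,time_bin_ms time-bin layout (default 20 ms bins).
#' @param n_offset_bins number of offset bins tiling `(-180, 180]`
#'   (default 16 bins of 22.5 degrees).
#' @param conditions trial conditions to include (default all).
#' @return list of class `population_map`: `alignment`, `time_bin_edges_ms`,
#'   `offset_bin_edges_deg`, `values` (offset x time matrix of mean rate
#'   change, spikes/s; `NA` where no contribution), `n` (contribution counts).
#' @export
spatiotemporal_map <- function(session, fits, alignment = "target_on",
                               t_start_ms = -100, t_end_ms = 800,
                               time_bin_ms = 20, n_offset_bins = 16L,
                               conditions = c("zero", "low", "high")) {
  alignment <- match.arg(alignment, c("target_on", "move_on"))
  trials <- session$trials[session$trials$condition %in% conditions, ]
  if (nrow(trials) == 0L) stop("no trials in requested conditions")
  spikes <- session$spikes[session$spikes$trial_id %in% trials$trial_id, ]
  t_edges <- seq(t_start_ms, t_end_ms, by = time_bin_ms)
  o_edges <- seq(-180, 180, length.out = n_offset_bins + 1L)
  n_t <- length(t_edges) - 1L
  vals <- matrix(0, n_offset_bins, n_t)
  nmat <- matrix(0L, n_offset_bins, n_t)
  bl <- baseline_rate(spikes, trials, neuron_ids = unique(fits$neuron_id))
  for (ti in seq_len(n_t)) {
    mid <- (t_edges[ti] + t_edges[ti + 1L]) / 2
    ep_name <- if (alignment == "move_on") "movement" else if (mid < 250) "visual" else "delay"
    epf <- fits[fits$epoch == ep_name & fits$significant & !is.na(fits$pd_deg), ]
    if (nrow(epf) == 0L) next
    win <- epoch_window("map", alignment, t_edges[ti], t_edges[ti + 1L])
    dr <- window_count_matrix(spikes, trials, win, epf$neuron_id) /
      (time_bin_ms / 1000) - bl[, epf$neuron_id, drop = FALSE]
    offs <- outer(trials$reach_deg, epf$pd_deg, function(r, p) wrap_deg(p - r))
    bin <- floor((offs + 180) %% 360 / (360 / n_offset_bins)) + 1L
    sums <- tapply(as.vector(dr), as.vector(bin), sum)
    cnts <- tapply(as.vector(dr), as.vector(bin), length)
    idx <- as.integer(names(sums))
    vals[idx, ti] <- vals[idx, ti] + sums
    nmat[idx, ti] <- nmat[idx, ti] + cnts
  }
  values <- vals / nmat
  values[nmat == 0L] <- NA_real_
  if (all(nmat == 0L)) stop("no tuned neurons contribute to the map")
  structure(list(alignment = alignment, time_bin_edges_ms = t_edges,
                 offset_bin_edges_deg = o_edges, values = values, n = nmat),
            class = "population_map")
}

# Shared core of group_rate_difference: per-neuron per-group condition-mean
# rate differences from a precomputed baseline-subtracted rate matrix.
group_delta_core <- function(dr, grp, cond, conditions, groups, take = NULL) {
  if (is.null(take)) take <- seq_len(nrow(dr))
  sapply(groups, function(g) {
    d <- vapply(seq_len(ncol(dr)), function(j) {
      gj <- grp[take, j] == g
      sel1 <- gj & cond[take] == conditions[1L]
      sel2 <- gj & cond[take] == conditions[2L]
      if (!any(sel1) || !any(sel2)) return(NA_real_)
      mean(dr[take, j][sel2]) - mean(dr[take, j][sel1])
    }, 0)
    if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  })
}

#' Uncertainty-condition rate difference for a direction group
#'
#' For each significantly tuned neuron, trials are assigned per trial to
#' SD/ORTH/OD by the offset between the neuron's (epoch-matched) PD and the
#' reach direction; within the requested group the neuron's mean
#' baseline-subtracted rate in `window` is computed per condition. The group
#' delta is the mean over neurons of (high - low). The confidence interval is
#' a percentile bootstrap over trials within each condition.
#'
#' @param session a [reach_session()].
#' @param fits `tuning_table`; rows of `epoch_name` supply the PDs.
#' @param group `"SD"`, `"ORTH"` or `"OD"`.
#' @param window analysis [epoch_window()].
#' @param epoch_name epoch whose PDs to use (default `"delay"`).
#' @param n_boot bootstrap replicates for the CI (0 skips the CI).
#' @param conditions length-2 character, conditions to difference
#'   (`delta = mean(rate[cond2]) - mean(rate[cond1])`).
#' @param seed optional seed.
#' @return one-row data.frame of class `group_rate_delta`: `session_id`,
#'   `group`, `window`, `delta`, `ci_lo`, `ci_hi`, `n_neurons`.
#' @export
group_rate_difference <- function(session, fits, group, window,
                                  epoch_name = "delay", n_boot = 1000L,
                                  conditions = c("low", "high"), seed = NULL) {
  stopifnot(group %in% c("SD", "ORTH", "OD"), length(conditions) == 2L)
  if (!is.null(seed)) set.seed(seed)
  epf <- fits[fits$epoch == epoch_name & fits$significant & !is.na(fits$pd_deg), ]
  if (nrow(epf) == 0L) stop("no significantly tuned neurons in epoch ", epoch_name)
  trials <- session$trials[session$trials$condition %in% conditions, ]
  if (!all(conditions %in% trials$condition)) stop("both conditions must be present")
  spikes <- session$spikes[session$spikes$trial_id %in% trials$trial_id, ]
  dr <- delta_rate_matrix(spikes, trials, window, epf$neuron_id)
  grp <- outer(trials$reach_deg, epf$pd_deg,
               function(r, p) partition_direction_groups(p, r))
  cond <- trials$condition
  delta <- unname(group_delta_core(dr, grp, cond, conditions, group))
  if (is.na(delta)) stop("no neuron has trials of both conditions in group ", group)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    i1 <- which(cond == conditions[1L])
    i2 <- which(cond == conditions[2L])
    boots <- vapply(seq_len(n_boot), function(b) {
      group_delta_core(dr, grp, cond, conditions, group,
                       take = c(sample(i1, length(i1), replace = TRUE),
                                sample(i2, length(i2), replace = TRUE)))
    }, 0)
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  out <- data.frame(session_id = session$session_id, group = group,
                    window = window$name, delta = delta,
                    ci_lo = ci[1], ci_hi = ci[2],
                    n_neurons = sum(apply(grp == group, 2L, any)))
  class(out) <- c("group_rate_delta", class(out))
  out
}

#' Regress activity differences on behavioral uncertainty differences
#'
#' Ordinary least squares of per-session group rate deltas (high - low,
#' spikes/s) on per-session differences in behavioral uncertainty (degrees).
#'
#' @param deltas numeric vector of group rate deltas, one per session.
#' @param behavior_deltas numeric vector of `delta_behavioral_uncertainty`,
#'   same order.
#' @param group,window labels stored in the result.
#' @return one-row data.frame of class `regression_result`: `group`, `window`,
#'   `slope` ((spikes/s) per degree), `intercept`, `r2`, `p` (two-sided, slope
#'   = 0), `n_sessions`, `underdetermined`.
#' @export
uncertainty_activity_regression <- function(deltas, behavior_deltas,
                                            group = NA_character_,
                                            window = NA_character_) {
  keep <- is.finite(deltas) & is.finite(behavior_deltas)
  y <- deltas[keep]
  x <- behavior_deltas[keep]
  n <- length(y)
  if (n < 2L) stop("need at least 2 sessions with both quantities")
  if (diff(range(x)) < 1e-12) stop("degenerate predictor: all behavioral deltas equal")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  under <- n < 4L
  se <- if (n > 2L) sm$coefficients[2L, 2L] else NA_real_
  tq <- if (n > 2L) stats::qt(0.975, n - 2L) else NA_real_
  out <- data.frame(
    group = group, window = window,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    slope_lo = unname(stats::coef(fit)[2L]) - tq * se,
    slope_hi = unname(stats::coef(fit)[2L]) + tq * se,
    r2 = sm$r.squared,
    p = if (n > 2L) sm$coefficients[2L, 4L] else NA_real_,
    n_sessions = n, underdetermined = under
  )
  if (under) warning("regression under-determined with ", n, " sessions")
  class(out) <- c("regression_result", class(out))
  out
}

#' Sliding-window regressions across trial phases
#'
#' Runs [uncertainty_activity_regression()] per direction group in the visual
#' window (50-250 ms post-target, visual-epoch PDs), consecutive 100-ms delay
#' windows (300-700 ms post-target, delay-epoch PDs) and 100-ms movement
#' windows (0-200 ms post-movement-onset, movement-epoch PDs).
#'
#' @param sessions list of [reach_session()].
#' @param fits_list list of `tuning_table`, parallel to `sessions`.
#' @param behavior_deltas data.frame with `session_id` and
#'   `delta_behavioral_uncertainty`.
#' @param groups direction groups to analyse.
#' @param n_boot bootstrap replicates inside [group_rate_difference()]
#'   (default 0: the regression does not need per-session CIs).
#' @return data.frame: one `regression_result` row per group x window
#'   (windows that fail are recorded with `NA` statistics, not fatal).
#' @export
sliding_window_regression <- function(sessions, fits_list, behavior_deltas,
                                      groups = c("SD", "ORTH", "OD"),
                                      n_boot = 0L) {
  windows <- c(
    list(epoch_window("visual_50_250", "target_on", 50, 250)),
    lapply(seq(300, 600, by = 100), function(s)
      epoch_window(sprintf("delay_%d_%d", s, s + 100), "target_on", s, s + 100)),
    lapply(seq(0, 100, by = 100), function(s)
      epoch_window(sprintf("move_%d_%d", s, s + 100), "move_on", s, s + 100))
  )
  epoch_for <- function(w) {
    if (w$alignment == "move_on") "movement"
    else if (w$end_ms <= 250) "visual" else "delay"
  }
  rows <- list()
  for (w in windows) {
    ep <- epoch_for(w)
    for (g in groups) {
      d <- vapply(seq_along(sessions), function(i) {
        tryCatch(group_rate_difference(sessions[[i]], fits_list[[i]], g, w,
                                       epoch_name = ep, n_boot = n_boot)$delta,
                 error = function(e) NA_real_)
      }, 0)
      ids <- vapply(sessions, function(s) s$session_id, "")
      bu <- behavior_deltas$delta_behavioral_uncertainty[
        match(ids, behavior_deltas$session_id)]
      res <- tryCatch(
        uncertainty_activity_regression(d, bu, group = g, window = w$name),
        error = function(e) data.frame(group = g, window = w$name,
                                       slope = NA_real_, intercept = NA_real_,
                                       slope_lo = NA_real_, slope_hi = NA_real_,
                                       r2 = NA_real_, p = NA_real_,
                                       n_sessions = sum(is.finite(d) & is.finite(bu)),
                                       underdetermined = TRUE))
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metric-subsampling correlation analysis
#'
#' Draws unique random session subsets and, per subset, computes the three
#' pairwise correlations between the OD activity difference, the behavioral
#' uncertainty difference and the cue-weighting difference. Also returns the
#' subsets maximising and minimising the uncertainty/cue-weighting correlation
#' found by greedy swap search from random starts.
#'
#' @param od_delta,delta_unc,delta_cw per-session metric vectors (same order).
#' @param subset_size sessions per subsample (>= 4).
#' @param n_subsamples number of unique subsamples.
#' @param n_starts random starts for the greedy extreme-subset search.
#' @param seed optional seed.
#' @return list with `correlations` (data.frame: `cor_od_unc`, `cor_od_cw`,
#'   `cor_unc_cw`, one row per subsample), `subsets` (list of index vectors),
#'   `extreme_max`, `extreme_min` (index vectors for the extreme
#'   uncertainty/cue-weighting correlation subsets).
#' @export
metric_subsample_analysis <- function(od_delta, delta_unc, delta_cw,
                                      subset_size, n_subsamples = 1000L,
                                      n_starts = 200L, seed = NULL) {
  n <- length(od_delta)
  stopifnot(length(delta_unc) == n, length(delta_cw) == n)
  if (subset_size < 4L) stop("`subset_size` must be >= 4")
  if (subset_size > n) stop("`subset_size` exceeds number of sessions")
  if (!is.null(seed)) set.seed(seed)
  max_unique <- choose(n, subset_size)
  if (n_subsamples > max_unique) stop("fewer than `n_subsamples` unique subsets exist")
  seen <- new.env(hash = TRUE)
  subsets <- vector("list", n_subsamples)
  got <- 0L
  while (got < n_subsamples) {
    s <- sort(sample.int(n, subset_size))
    key <- paste(s, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      subsets[[got]] <- s
    }
  }
  cors <- t(vapply(subsets, function(s) c(
    cor_od_unc = stats::cor(od_delta[s], delta_unc[s]),
    cor_od_cw = stats::cor(od_delta[s], delta_cw[s]),
    cor_unc_cw = stats::cor(delta_unc[s], delta_cw[s])
  ), c(cor_od_unc = 0, cor_od_cw = 0, cor_unc_cw = 0)))
  obj <- function(s) stats::cor(delta_unc[s], delta_cw[s])
  greedy <- function(sgn) {
    best_s <- NULL
    best_v <- -Inf
    for (k in seq_len(n_starts)) {
      s <- sort(sample.int(n, subset_size))
      v <- sgn * obj(s)
      repeat {
        out_cand <- setdiff(seq_len(n), s)
        improved <- FALSE
        for (i in seq_along(s)) {
          for (j in out_cand) {
            s2 <- s
            s2[i] <- j
            v2 <- sgn * obj(s2)
            if (v2 > v + 1e-12) {
              s <- sort(s2)
              v <- v2
              improved <- TRUE
              break
            }
          }
          if (improved) break
        }
        if (!improved) break
      }
      if (v > best_v) {
        best_v <- v
        best_s <- s
      }
    }
    best_s
  }
  list(correlations = as.data.frame(cors), subsets = subsets,
       extreme_max = greedy(1), extreme_min = greedy(-1))
}

#' Reverse the sign of a covariate's condition difference by subsampling
#'
#' Rank-based trimming of the extreme of one condition until the sign of
#' `mean(covariate | high) - mean(covariate | low)` is reversed relative to
#' the full trial set, retaining at least half of that condition's trials when
#' feasible. Used as a kinematic control: if an uncertainty effect survives a
#' trial subset in which the kinematic difference points the other way, the
#' covariate does not explain the effect.
#'
#' @param trials trials data.frame (uncertainty block, conditions low/high).
#' @param covariate `"peak_speed_cms"` or `"reaction_time_s"`.
#' @param target_sign optional `+1`/`-1`: the wanted sign of the high - low
#'   covariate difference. Default: the opposite of the full-set sign. When
#'   the input already has the target sign it is returned unchanged.
#' @param min_retain minimum retained fraction of the trimmed condition.
#' @return trials subset with the covariate difference sign reversed; the
#'   input unchanged if already reversed.
#' @export
covariate_reversal_resample <- function(trials, covariate = c("peak_speed_cms", "reaction_time_s"),
                                        target_sign = NULL, min_retain = 0.5) {
  covariate <- match.arg(covariate)
  tr <- trials[trials$condition %in% c("low", "high"), ]
  x <- tr[[covariate]]
  if (any(!is.finite(x))) stop("covariate has missing values")
  d_full <- mean(x[tr$condition == "high"]) - mean(x[tr$condition == "low"])
  if (abs(d_full) < 1e-12) stop("condition means of the covariate do not differ")
  if (is.null(target_sign)) target_sign <- -sign(d_full)
  if (sign(d_full) == target_sign) return(tr)
  # trim the condition whose extreme drives the difference: drop the largest
  # values of the higher-mean condition
  trim_cond <- if (d_full > 0) "high" else "low"
  keep <- rep(TRUE, nrow(tr))
  ord <- order(x, decreasing = TRUE)
  ord <- ord[tr$condition[ord] == trim_cond]
  n_cond <- length(ord)
  min_keep <- ceiling(min_retain * n_cond)
  diff_now <- function(k) {
    mean(x[k & tr$condition == "high"]) - mean(x[k & tr$condition == "low"])
  }
  i <- 0L
  while (sign(diff_now(keep)) != target_sign) {
    i <- i + 1L
    if (n_cond - i < min_keep) {
      stop("covariate reversal infeasible while retaining ",
           round(100 * min_retain), "% of ", trim_cond, " trials")
    }
    keep[ord[i]] <- FALSE
  }
  tr[keep, ]
}

#' Within-group regressions for sessions sharing a prior mean
#'
#' Partitions sessions by their (rounded) prior mean direction and runs
#' [uncertainty_activity_regression()] within each group of at least
#' `min_sessions` sessions; smaller groups are skipped with a warning. This
#' controls for the average reach direction: a gain mechanism tied to
#' uncertainty should appear within every group regardless of where reaches
#' point.
#'
#' @param deltas,behavior_deltas per-session metric vectors.
#' @param prior_means_deg per-session prior mean directions, degrees.
#' @param group_label,window labels stored in the results.
#' @param min_sessions minimum group size (default 4).
#' @return data.frame: one `regression_result` row per retained prior-mean
#'   group, with a `prior_mean_deg` column.
#' @export
grouped_prior_analysis <- function(deltas, behavior_deltas, prior_means_deg,
                                   group_label = "OD", window = NA_character_,
                                   min_sessions = 4L) {
  pm <- wrap_deg(round(prior_means_deg))
  rows <- list()
  for (g in sort(unique(pm))) {
    sel <- pm == g
    if (sum(sel) < min_sessions) {
      warning("skipping prior-mean group ", g, " deg with only ", sum(sel), " sessions")
      next
    }
    res <- uncertainty_activity_regression(deltas[sel], behavior_deltas[sel],
                                           group = group_label, window = window)
    res$prior_mean_deg <- g
    rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) stop("no prior-mean group has enough sessions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
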