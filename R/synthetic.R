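# Synthetic session generator: von Mises target prior, noisy cue lines, a
# Bayesian observer with posterior and motor noise, and cosine-tuned Poisson
# neurons whose off-direction activity gains with the session's uncertainty
# contrast. Every generated quantity has recorded ground truth so recovery
# tests can be scored.

# mean of the off-direction gain shape (1 - cos)/2 over the OD offset band
# [135, 225] degrees; used to calibrate the peak gain so the planted OD-group
# effect equals the gain-law coefficient.
OD_SHAPE_MEAN <- 0.5 * (1 + 2 * sqrt(2) / pi)

#' Observer / task configuration
#'
#' Parameters of the simulated task and observer. `prior_kappa_true` and
#' `like_kappa_*` govern the actual stimulus generation (target draws and cue
#' lines); the `subj_*` concentrations are the observer's internal beliefs and
#' determine cue weighting and posterior width; `motor_kappa` is downstream
#' motor noise.
#'
#' @param prior_mean_deg prior mean direction, degrees.
#' @param prior_kappa_true concentration of the generating target prior.
#' @param like_kappa_low,like_kappa_high concentration of the cue-line
#'   likelihood per condition (per line).
#' @param n_lines cue lines per trial (5 or 10).
#' @param subj_prior_kappa,subj_like_kappa_low,subj_like_kappa_high the
#'   observer's internal prior/likelihood concentrations.
#' @param motor_kappa motor noise concentration.
#' @return list of class `observer_config`.
#' @export
observer_config <- function(prior_mean_deg = 90, prior_kappa_true = 0.8,
                            like_kappa_low = 30, like_kappa_high = 6,
                            n_lines = 5L,
                            subj_prior_kappa = 0.7, subj_like_kappa_low = 12,
                            subj_like_kappa_high = 3, motor_kappa = 30) {
  kappas <- c(prior_kappa_true, like_kappa_low, like_kappa_high,
              subj_prior_kappa, subj_like_kappa_low, subj_like_kappa_high,
              motor_kappa)
  if (any(kappas < 0)) stop("all concentrations must be >= 0")
  if (!n_lines %in% c(5L, 10L)) stop("`n_lines` must be 5 or 10")
  structure(as.list(environment()), class = "observer_config")
}

#' Neuron population configuration
#'
#' @param n_pmd,n_m1 neurons per area. The off-direction uncertainty gain is
#'   applied only to the PMd-like area; the M1-like area gets zero gain.
#' @param baseline_hz_range range of baseline rates, spikes/s.
#' @param beta_range range of per-epoch cosine modulation depths.
#' @param od_gain peak added rate (spikes/s) on high-uncertainty trials at
#'   180 degrees PD-reach offset; the angular profile is `(1 - cos(offset))/2`.
#' @param gain_onset_ms time after target onset when the gain activates
#'   (default 250 ms; the early visual burst is left gain-free).
#' @return list of class `neuron_config`.
#' @export
neuron_config <- function(n_pmd = 20L, n_m1 = 0L,
                          baseline_hz_range = c(5, 25),
                          beta_range = c(0.4, 1.2),
                          od_gain = 0, gain_onset_ms = 250) {
  if (n_pmd + n_m1 < 1L) stop("need at least one neuron")
  if (od_gain < 0) stop("`od_gain` must be >= 0 (uncertainty only ever adds activity)")
  structure(as.list(environment()), class = "neuron_config")
}

#' Expected angular dispersion of the observer's residual reach errors
#'
#' Analytic session-level behavioral uncertainty implied by the generator: the
#' resultant length of the sum of posterior noise (concentration
#' `subj_prior + subj_like`) and motor noise is the product of their Bessel
#' ratios, and the dispersion is `sqrt(-2 log R)` in degrees.
#'
#' @param cfg an [observer_config()].
#' @param condition `"low"` or `"high"`.
#' @return expected dispersion, degrees.
#' @export
expected_dispersion <- function(cfg, condition = c("low", "high")) {
  condition <- match.arg(condition)
  k_like <- if (condition == "low") cfg$subj_like_kappa_low else cfg$subj_like_kappa_high
  R <- vm_mean_resultant(cfg$subj_prior_kappa + k_like) *
    vm_mean_resultant(cfg$motor_kappa)
  sqrt(-2 * log(R)) * RAD2DEG
}

#' Generate behavioral trials for one session
#'
#' Center-out block: eight equispaced zero-uncertainty targets, reach = target
#' plus motor noise. Uncertainty block (conditions randomly interleaved):
#' target drawn from the von Mises prior, `n_lines` cue lines drawn from the
#' condition's likelihood around the target; the observer reaches to the
#' product mean of its subjective prior and a likelihood centred on the cue
#' centroid, with posterior-concentration noise plus motor noise. Event times
#' use a 700-1000 ms center hold and a 700-1000 ms instructed delay; reaction
#' times and peak speeds carry a small uncertainty effect (slower, slightly
#' gentler reaches under high uncertainty) for covariate controls.
#'
#' @param cfg an [observer_config()].
#' @param n_center_out trials in the center-out block (multiple of 8 advised).
#' @param n_per_condition trials per uncertainty condition.
#' @param session_id session label.
#' @param seed optional seed.
#' @return trials data.frame in the session layout, with attribute
#'   `ground_truth` (true w and expected dispersion per condition).
#' @export
generate_behavior <- function(cfg, n_center_out = 96L, n_per_condition = 150L,
                              session_id = "synth", seed = NULL) {
  stopifnot(inherits(cfg, "observer_config"))
  if (!is.null(seed)) set.seed(seed)
  if (n_center_out < 8L) stop("need at least 8 center-out trials")

  co_targets <- wrap_deg(rep(seq(0, 315, by = 45), length.out = n_center_out))
  co_reach <- wrap_deg(co_targets + vm_sample(n_center_out, 0, cfg$motor_kappa))
  co <- data.frame(
    block = "center_out", condition = "zero",
    cue_lines = I(replicate(n_center_out, numeric(0), simplify = FALSE)),
    cue_centroid_deg = co_targets, target_deg = co_targets, reach_deg = co_reach
  )

  one_condition <- function(cond) {
    n <- n_per_condition
    k_like_true <- if (cond == "low") cfg$like_kappa_low else cfg$like_kappa_high
    k_like_subj <- if (cond == "low") cfg$subj_like_kappa_low else cfg$subj_like_kappa_high
    target <- vm_sample(n, cfg$prior_mean_deg, cfg$prior_kappa_true)
    lines <- lapply(target, function(tg) vm_sample(cfg$n_lines, tg, k_like_true))
    centroid <- vapply(lines, circ_mean, 0)
    mu3 <- vm_product_mean(cfg$prior_mean_deg, cfg$subj_prior_kappa,
                           centroid, k_like_subj)
    kappa3 <- vm_product_kappa(cfg$prior_mean_deg, cfg$subj_prior_kappa,
                               centroid, k_like_subj)
    post_noise <- vapply(kappa3, function(k) vm_sample(1, 0, k), 0)
    reach <- wrap_deg(mu3 + post_noise + vm_sample(n, 0, cfg$motor_kappa))
    data.frame(block = "uncertainty", condition = cond,
               cue_lines = I(lines), cue_centroid_deg = centroid,
               target_deg = target, reach_deg = reach)
  }
  unc <- rbind(one_condition("low"), one_condition("high"))
  unc <- unc[sample.int(nrow(unc)), ]    # random interleaving

  tr <- rbind(co, unc)
  n <- nrow(tr)
  is_high <- tr$condition == "high"
  t_target_on <- stats::runif(n, 0.7, 1.0)
  t_go <- t_target_on + stats::runif(n, 0.7, 1.0)
  rt <- stats::runif(n, 0.15, 0.30) + 0.02 * is_high
  out <- data.frame(
    session_id = session_id,
    trial_id = seq_len(n),
    block = tr$block, condition = tr$condition,
    prior_mean_deg = cfg$prior_mean_deg,
    cue_lines_deg = format_cue_lines(tr$cue_lines),
    cue_centroid_deg = tr$cue_centroid_deg,
    target_deg = tr$target_deg, reach_deg = tr$reach_deg,
    t_target_on_s = t_target_on, t_go_s = t_go, t_move_on_s = t_go + rt,
    reaction_time_s = rt,
    peak_speed_cms = stats::rnorm(n, 25, 2) - 1 * is_high
  )
  attr(out, "ground_truth") <- data.frame(
    session_id = session_id,
    w_low = cfg$subj_like_kappa_low / (cfg$subj_prior_kappa + cfg$subj_like_kappa_low),
    w_high = cfg$subj_like_kappa_high / (cfg$subj_prior_kappa + cfg$subj_like_kappa_high),
    dispersion_low = expected_dispersion(cfg, "low"),
    dispersion_high = expected_dispersion(cfg, "high")
  )
  out
}

#' Generate a neuron ground-truth table
#'
#' Preferred directions are stratified-uniform on the circle (one neuron per
#' equal arc, uniform within it, so moderate populations occupy every decoder
#' bin); baselines and per-epoch modulation depths are uniform in their
#' configured ranges. M1-like neurons get zero uncertainty gain.
#'
#' @param ncfg a [neuron_config()].
#' @param seed optional seed.
#' @return data.frame: `neuron_id`, `area`, `pd_deg`, `baseline_hz`,
#'   `beta_visual`, `beta_delay`, `beta_move`, `od_gain`, `gain_onset_ms`.
#' @export
generate_neurons <- function(ncfg, seed = NULL) {
  stopifnot(inherits(ncfg, "neuron_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- ncfg$n_pmd + ncfg$n_m1
  pd <- wrap_deg(360 * (seq_len(n) - 1 + stats::runif(n)) / n - 180)
  pd <- sample(pd)    # decouple pd from area/id ordering
  rb <- function(lo, hi) stats::runif(n, lo, hi)
  data.frame(
    neuron_id = sprintf("n%03d", seq_len(n)),
    area = rep(c("PMd", "M1"), c(ncfg$n_pmd, ncfg$n_m1)),
    pd_deg = pd,
    baseline_hz = rb(ncfg$baseline_hz_range[1], ncfg$baseline_hz_range[2]),
    beta_visual = rb(ncfg$beta_range[1], ncfg$beta_range[2]),
    beta_delay = rb(ncfg$beta_range[1], ncfg$beta_range[2]),
    beta_move = rb(ncfg$beta_range[1], ncfg$beta_range[2]),
    od_gain = ifelse(rep(c(TRUE, FALSE), c(ncfg$n_pmd, ncfg$n_m1)), ncfg$od_gain, 0),
    gain_onset_ms = ncfg$gain_onset_ms
  )
}

#' Generate spike events for a session
#'
#' Each neuron fires as an inhomogeneous Poisson process with piecewise-
#' constant rate: baseline before 50 ms post-target and after the movement
#' segment; epoch rates `baseline * exp(beta_epoch * (cos(reach - pd)))`
#' during the visual (50-250 ms), delay (250 ms to movement onset) and
#' movement (0-400 ms after movement onset) segments; on high-uncertainty
#' trials an additive gain `od_gain * (1 - cos(pd - reach))/2` applies from
#' `gain_onset_ms` to the end of the movement segment.
#'
#' @param trials trials data.frame (from [generate_behavior()]).
#' @param neurons neuron table (from [generate_neurons()]).
#' @param rec_pre_s,rec_post_s recorded span before target onset and after the
#'   movement segment, seconds.
#' @param seed optional seed.
#' @return spikes data.frame (`trial_id`, `neuron_id`, `t_s`) with attribute
#'   `rec_span`.
#' @export
generate_spikes <- function(trials, neurons, rec_pre_s = 0.4, rec_post_s = 0.05,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nn <- nrow(neurons)
  pd <- neurons$pd_deg
  logb <- log(neurons$baseline_hz)
  betas <- rbind(visual = neurons$beta_visual, delay = neurons$beta_delay,
                 move = neurons$beta_move)
  onset_s <- neurons$gain_onset_ms[1] / 1000
  out_trial <- vector("list", nrow(trials))
  out_neuron <- vector("list", nrow(trials))
  out_t <- vector("list", nrow(trials))
  max_end <- 0
  for (i in seq_len(nrow(trials))) {
    move_rel <- trials$t_move_on_s[i] - trials$t_target_on_s[i]
    edges <- sort(unique(c(-rec_pre_s, 0.05, 0.25, onset_s, move_rel,
                           move_rel + 0.4, move_rel + 0.4 + rec_post_s)))
    n_seg <- length(edges) - 1L
    mids <- (edges[-1] + edges[-(n_seg + 1L)]) / 2
    cosd <- cos((trials$reach_deg[i] - pd) * DEG2RAD)
    rate <- matrix(exp(logb), nn, n_seg)
    for (s in seq_len(n_seg)) {
      m <- mids[s]
      if (m >= 0.05 && m < 0.25) rate[, s] <- exp(logb + betas["visual", ] * cosd)
      else if (m >= 0.25 && m < move_rel) rate[, s] <- exp(logb + betas["delay", ] * cosd)
      else if (m >= move_rel && m < move_rel + 0.4) rate[, s] <- exp(logb + betas["move", ] * cosd)
      if (trials$condition[i] == "high" && m >= onset_s && m < move_rel + 0.4) {
        rate[, s] <- rate[, s] + neurons$od_gain * (1 - cosd) / 2
      }
    }
    stopifnot(all(rate >= 0))
    durs <- diff(edges)
    cnt <- stats::rpois(nn * n_seg, as.vector(rate) * rep(durs, each = nn))
    tot <- sum(cnt)
    if (tot > 0L) {
      lo <- rep(rep(edges[-(n_seg + 1L)], each = nn), cnt)
      hi <- rep(rep(edges[-1], each = nn), cnt)
      out_t[[i]] <- stats::runif(tot, lo, hi)
      out_neuron[[i]] <- rep(rep(neurons$neuron_id, n_seg), cnt)
      out_trial[[i]] <- rep(trials$trial_id[i], tot)
    }
    max_end <- max(max_end, move_rel + 0.4 + rec_post_s)
  }
  sp <- data.frame(trial_id = unlist(out_trial),
                   neuron_id = unlist(out_neuron),
                   t_s = unlist(out_t))
  attr(sp, "rec_span") <- c(-rec_pre_s, max_end)
  sp
}

#' Generate a complete synthetic session
#'
#' @param cfg an [observer_config()].
#' @param ncfg a [neuron_config()].
#' @param n_center_out,n_per_condition trial counts.
#' @param session_id session label.
#' @param seed optional seed (drives behavior, neurons and spikes).
#' @return a [reach_session()]; its `neurons` slot holds the ground truth,
#'   and attribute `ground_truth` carries the behavioral truths.
#' @export
generate_session <- function(cfg = observer_config(), ncfg = neuron_config(),
                             n_center_out = 96L, n_per_condition = 150L,
                             session_id = "synth", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- generate_behavior(cfg, n_center_out, n_per_condition, session_id)
  neurons <- generate_neurons(ncfg)
  spikes <- generate_spikes(trials, neurons)
  ses <- reach_session(trials, spikes, neurons)
  attr(ses, "ground_truth") <- attr(trials, "ground_truth")
  ses
}

# Angular dispersion of the observer's realized residual errors (reach minus
# subjective product mean) for one condition of a generated trials table.
realized_dispersion <- function(trials, cfg, condition) {
  tc <- trials[trials$condition == condition, ]
  k_like <- if (condition == "low") cfg$subj_like_kappa_low else cfg$subj_like_kappa_high
  mu3 <- vm_product_mean(cfg$prior_mean_deg, cfg$subj_prior_kappa,
                         tc$cue_centroid_deg, k_like)
  circ_summary(wrap_deg(tc$reach_deg - mu3))$dispersion_deg
}

# Neuron-weighted mean of the gain shape (1 - cos(offset))/2 over
# high-condition OD-band trials, restricted to PMd neurons that have OD
# trials in both conditions (mirroring the analysis-side averaging).
effective_od_shape <- function(trials, neurons) {
  pm <- neurons[neurons$area == "PMd", ]
  hi <- trials$reach_deg[trials$condition == "high"]
  lo <- trials$reach_deg[trials$condition == "low"]
  vals <- vapply(pm$pd_deg, function(pd) {
    off_h <- wrap_deg(pd - hi)
    od_h <- off_h >= 135 | off_h < -135
    off_l <- wrap_deg(pd - lo)
    od_l <- off_l >= 135 | off_l < -135
    if (!any(od_h) || !any(od_l)) return(NA_real_)
    mean((1 - cos(off_h[od_h] * DEG2RAD)) / 2)
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Generate a multi-session synthetic study
#'
#' Sessions vary the observer's subjective high-uncertainty likelihood
#' concentration (and, mildly, the subjective prior and low-condition
#' likelihood) so the study spans a range of behavioral-uncertainty contrasts
#' of roughly 0-30 degrees. The planted off-direction gain follows the law
#' `OD effect = gain_coef * delta_unc_target + noise` (in spikes/s per degree);
#' the peak gain is scaled by the mean of the angular gain profile over the OD
#' band so that the planted OD-group regression slope equals `gain_coef`.
#'
#' @param n_sessions number of sessions (>= 4).
#' @param gain_coef slope `a` of the gain law, (spikes/s) per degree of
#'   delta behavioral uncertainty; `0` gives a null study.
#' @param gain_noise_sd standard deviation of the gain-law noise, spikes/s.
#' @param prior_means_deg prior mean directions cycled across sessions.
#' @param n_center_out,n_per_condition per-session trial counts.
#' @param ncfg_base [neuron_config()] whose `od_gain` is overwritten per
#'   session by the gain law.
#' @param seed optional seed.
#' @return list of class `reach_study`: `sessions` (list of
#'   [reach_session()]) and `ground_truth` (data.frame per session: subjective
#'   kappas, true w per condition, `delta_unc_target`, `od_gain_peak`).
#' @export
generate_study <- function(n_sessions = 20L, gain_coef = 0.15,
                           gain_noise_sd = 0.75,
                           prior_means_deg = c(0, 90),
                           n_center_out = 96L, n_per_condition = 150L,
                           ncfg_base = neuron_config(), seed = NULL) {
  if (n_sessions < 4L) stop("need at least 4 sessions")
  if (!is.null(seed)) set.seed(seed)
  sessions <- vector("list", n_sessions)
  gt <- vector("list", n_sessions)
  # span the subjective high-condition likelihood widely (log-spaced sweep
  # with jitter) so delta behavioral uncertainty covers ~0-30 degrees; the
  # subjective prior is kept weak so the cue-weighting contrast (and with it
  # the difference between the conditions' reach-direction distributions)
  # stays modest while the posterior width varies strongly
  k_high_grid <- exp(seq(log(1.3), log(11), length.out = n_sessions))
  k_high_grid <- sample(k_high_grid)
  for (i in seq_len(n_sessions)) {
    cfg <- observer_config(
      prior_mean_deg = prior_means_deg[(i - 1L) %% length(prior_means_deg) + 1L],
      subj_prior_kappa = stats::runif(1, 0.4, 1.0),
      subj_like_kappa_low = stats::runif(1, 9, 15),
      subj_like_kappa_high = k_high_grid[i] * exp(stats::runif(1, -0.15, 0.15))
    )
    sid <- sprintf("S%02d", i)
    # generate behavior and neurons first, then calibrate the peak gain
    # against the realized trial/neuron geometry: with per-neuron averaging
    # the effective OD gain shape is the neuron-weighted mean of
    # (1 - cos(offset))/2 over each neuron's high-condition OD trials, which
    # can deviate from the uniform-band value; scaling the peak by the
    # session's own value plants an OD-group effect of exactly `od_eff`
    trials <- generate_behavior(cfg, n_center_out, n_per_condition,
                                session_id = sid)
    # the gain law is driven by the session's REALIZED behavioral uncertainty
    # contrast (angular dispersion of the observer's true residual errors),
    # which the generator knows exactly; this is the quantity the analysis
    # regresses on, so planting against it keeps the planted slope
    # interpretable as (spikes/s) per degree
    d_unc <- realized_dispersion(trials, cfg, "high") -
      realized_dispersion(trials, cfg, "low")
    od_eff <- max(0, gain_coef * d_unc + stats::rnorm(1, 0, gain_noise_sd))
    ncfg <- ncfg_base
    neurons <- generate_neurons(ncfg)
    s_eff <- effective_od_shape(trials, neurons)
    ncfg$od_gain <- if (is.finite(s_eff) && s_eff > 0.1) od_eff / s_eff else
      od_eff / OD_SHAPE_MEAN
    neurons$od_gain <- ifelse(neurons$area == "PMd", ncfg$od_gain, 0)
    spikes <- generate_spikes(trials, neurons)
    sessions[[i]] <- reach_session(trials, spikes, neurons)
    attr(sessions[[i]], "ground_truth") <- attr(trials, "ground_truth")
    gt[[i]] <- data.frame(
      session_id = sid,
      prior_mean_deg = cfg$prior_mean_deg,
      subj_prior_kappa = cfg$subj_prior_kappa,
      subj_like_kappa_low = cfg$subj_like_kappa_low,
      subj_like_kappa_high = cfg$subj_like_kappa_high,
      w_low = attr(sessions[[i]], "ground_truth")$w_low,
      w_high = attr(sessions[[i]], "ground_truth")$w_high,
      delta_unc_target = d_unc,
      od_eff = od_eff,
      od_gain_peak = ncfg$od_gain
    )
  }
  gt <- do.call(rbind, gt)
  if (diff(range(gt$delta_unc_target)) < 1e-9) {
    warning("degenerate gain law: all sessions have identical uncertainty contrast")
  }
  structure(list(sessions = sessions, ground_truth = gt), class = "reach_study")
}

#' @export
print.reach_study <- function(x, ...) {
  cat(sprintf("reach study: %d sessions, delta-uncertainty span %.1f-%.1f deg, peak od gain up to %.1f sp/s\n",
              length(x$sessions), min(x$ground_truth$delta_unc_target),
              max(x$ground_truth$delta_unc_target), max(x$ground_truth$od_gain_peak)))
  invisible(x)
}
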