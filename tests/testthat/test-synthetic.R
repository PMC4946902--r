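test_that("generation is reproducible bit-for-bit under a fixed seed", {
  a <- small_session(seed = 9, n_pmd = 4L, n_center_out = 16L,
                     n_per_condition = 20L)
  b <- small_session(seed = 9, n_pmd = 4L, n_center_out = 16L,
                     n_per_condition = 20L)
  expect_identical(a$trials, b$trials)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$neurons, b$neurons)
})

test_that("observer limits: infinite cue reliance and the circular midpoint", {
  set.seed(81)
  cfg <- observer_config(subj_like_kappa_low = 1e9, subj_like_kappa_high = 1e9,
                         motor_kappa = 1e12)
  tr <- generate_behavior(cfg, n_center_out = 8, n_per_condition = 30)
  unc <- tr[tr$block == "uncertainty", ]
  expect_lt(max(abs(wrap_deg(unc$reach_deg - unc$cue_centroid_deg))), 0.2)

  # equal subjective concentrations: plan is the circular midpoint of prior
  # mean and centroid (posterior noise is tiny at such concentrations)
  cfg2 <- observer_config(subj_prior_kappa = 5e8, subj_like_kappa_low = 5e8,
                          subj_like_kappa_high = 5e8, motor_kappa = 1e12)
  tr2 <- generate_behavior(cfg2, n_center_out = 8, n_per_condition = 30)
  unc2 <- tr2[tr2$block == "uncertainty", ]
  mid <- wrap_deg(cfg2$prior_mean_deg +
                    wrap_deg(unc2$cue_centroid_deg - cfg2$prior_mean_deg) / 2)
  expect_lt(max(abs(wrap_deg(unc2$reach_deg - mid))), 0.2)
})

test_that("cue centroids equal the circular mean of the generated lines", {
  set.seed(82)
  tr <- generate_behavior(observer_config(), n_center_out = 8,
                          n_per_condition = 25)
  unc <- tr[tr$block == "uncertainty", ][1:10, ]
  for (i in seq_len(nrow(unc))) {
    lines <- as.numeric(strsplit(unc$cue_lines_deg[i], ";")[[1]])
    expect_equal(length(lines), 5L)
    expect_lt(abs(wrap_deg(circ_mean(lines) - unc$cue_centroid_deg[i])), 1e-3)
  }
})

test_that("generated spike counts are Poisson at the configured baseline", {
  # one untuned neuron at 20 spikes/s, counted over a 1 s delay window
  neurons <- data.frame(neuron_id = "n1", area = "PMd", pd_deg = 0,
                        baseline_hz = 20, beta_visual = 0, beta_delay = 0,
                        beta_move = 0, od_gain = 0, gain_onset_ms = 250)
  n_tr <- 6000L
  tr <- tiny_trials(1)[rep(1, n_tr), ]
  tr$trial_id <- seq_len(n_tr)
  tr$t_go_s <- 2.6
  tr$t_move_on_s <- 2.8   # delay segment covers 0.25 - 1.8 s post-target
  set.seed(83)
  sp <- generate_spikes(tr, neurons)
  w <- epoch_window("one_sec", "target_on", 300, 1300)
  counts <- epoch_spike_counts(sp, tr, w)$counts[, "n1"]
  expect_equal(mean(counts), 20, tolerance = 0.5)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.05)
  expect_true(all(sp$t_s >= -0.4))
})

test_that("the off-direction gain has the planted magnitude and angular shape", {
  neurons <- data.frame(neuron_id = c("od", "sd"), area = "PMd",
                        pd_deg = c(180, 0), baseline_hz = 10,
                        beta_visual = 0, beta_delay = 0, beta_move = 0,
                        od_gain = 5, gain_onset_ms = 250)
  n_tr <- 800L
  tr <- tiny_trials(1)[rep(1, n_tr), ]
  tr$trial_id <- seq_len(n_tr)
  tr$block <- "uncertainty"
  tr$condition <- rep(c("low", "high"), n_tr / 2)
  tr$reach_deg <- 0
  tr$cue_lines_deg <- "0;0;0"
  set.seed(84)
  sp <- generate_spikes(tr, neurons)
  w <- epoch_window("delay_part", "target_on", 300, 700)
  ec <- epoch_spike_counts(sp, tr, w)
  rate <- ec$counts / 0.4
  hi <- tr$condition == "high"
  # gain shape is 1 at 180-degree offset, 0 at 0 offset
  expect_equal(mean(rate[hi, "od"]) - mean(rate[!hi, "od"]), 5, tolerance = 0.6)
  expect_equal(mean(rate[hi, "sd"]) - mean(rate[!hi, "sd"]), 0, tolerance = 0.6)
  # no gain before its onset
  w_vis <- epoch_window("visual", "target_on", 50, 250)
  rv <- epoch_spike_counts(sp, tr, w_vis)$counts / 0.2
  expect_equal(mean(rv[hi, "od"]) - mean(rv[!hi, "od"]), 0, tolerance = 0.8)
})

test_that("stratified preferred directions occupy every decoder bin", {
  set.seed(85)
  nn <- generate_neurons(neuron_config(n_pmd = 64L))
  bins <- build_pd_bins(stats::setNames(nn$pd_deg, nn$neuron_id))
  expect_equal(length(unique(bins)), 16L)
  # M1-like area never gets the gain
  nn2 <- generate_neurons(neuron_config(n_pmd = 4L, n_m1 = 4L, od_gain = 3))
  expect_true(all(nn2$od_gain[nn2$area == "M1"] == 0))
  expect_true(all(nn2$od_gain[nn2$area == "PMd"] == 3))
})

test_that("behavioral uncertainty contrast decreases with the subjective likelihood concentration", {
  cfgs <- lapply(c(1, 3, 8), function(k)
    observer_config(subj_like_kappa_high = k))
  analytic <- sapply(cfgs, function(cfg)
    expected_dispersion(cfg, "high") - expected_dispersion(cfg, "low"))
  expect_true(all(diff(analytic) < 0))
  # realized behavior follows the analytic ordering
  realized <- sapply(seq_along(cfgs), function(i) {
    set.seed(860 + i)
    tr <- generate_behavior(cfgs[[i]], n_center_out = 8, n_per_condition = 200)
    uncertainreach:::realized_dispersion(tr, cfgs[[i]], "high") -
      uncertainreach:::realized_dispersion(tr, cfgs[[i]], "low")
  })
  expect_true(all(diff(realized) < 0))
})

test_that("the generated behavior closes the loop with the cue-weighting fit", {
  cfg <- observer_config()
  for (cond in c("low", "high")) {
    k2 <- if (cond == "low") cfg$subj_like_kappa_low else cfg$subj_like_kappa_high
    w_true <- k2 / (cfg$subj_prior_kappa + k2)
    errs <- vapply(1:5, function(s) {
      set.seed(870 + s)
      tr <- generate_behavior(cfg, n_center_out = 8, n_per_condition = 400)
      tc <- tr[tr$condition == cond, ]
      f <- fit_cue_weighting(cfg$prior_mean_deg, tc$cue_centroid_deg,
                             tc$reach_deg)
      abs(f$slope - w_true)
    }, 0)
    expect_lt(median(errs), 0.05)
  }
})

test_that("generate_study plants the gain law against the realized uncertainty contrast", {
  set.seed(88)
  study <- generate_study(n_sessions = 6, gain_coef = 0.2, gain_noise_sd = 0,
                          n_center_out = 24L, n_per_condition = 60L,
                          ncfg_base = neuron_config(n_pmd = 6L))
  gt <- study$ground_truth
  expect_equal(nrow(gt), 6L)
  expect_true(all(gt$od_eff >= 0))
  expect_equal(gt$od_eff, pmax(0, 0.2 * gt$delta_unc_target), tolerance = 1e-9)
  # prior means cycle across sessions
  expect_setequal(unique(gt$prior_mean_deg), c(0, 90))
  expect_error(generate_study(n_sessions = 3), "at least 4")
})
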