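truth_fits <- function(session, epoch = "delay") {
  nn <- session$neurons
  data.frame(session_id = session$session_id, neuron_id = nn$neuron_id,
             epoch = epoch, alpha = log(nn$baseline_hz), beta = nn$beta_delay,
             pd_deg = nn$pd_deg, significant = TRUE, unfit = FALSE,
             criterion_deg = 45, n_boot = 0)
}

test_that("SD/ORTH/OD partition tiles the circle with the documented boundaries", {
  expect_equal(partition_direction_groups(0, 0), "SD")
  expect_equal(partition_direction_groups(180, 0), "OD")
  expect_equal(partition_direction_groups(90, 0), "ORTH")
  # boundary convention: offset exactly 45 is ORTH, exactly 135 is OD
  expect_equal(partition_direction_groups(45, 0), "ORTH")
  expect_equal(partition_direction_groups(-45, 0), "SD")
  expect_equal(partition_direction_groups(135, 0), "OD")
  labs <- partition_direction_groups(0:359, 0)
  expect_equal(unname(table(labs)["SD"]), 90L)
  expect_equal(unname(table(labs)["ORTH"]), 180L)
  expect_equal(unname(table(labs)["OD"]), 90L)
})

test_that("baseline_rate counts pre-target spikes per second", {
  tr <- tiny_trials()
  sp <- tiny_spikes(c(1, 1, 1, 2), "n1", c(-0.25, -0.10, -0.01, 0.01))
  b <- baseline_rate(sp, tr)
  expect_equal(unname(b[1, "n1"]), 3 / 0.3)
  expect_equal(unname(b[2, "n1"]), 0)   # 0.01 is post-target

  # homogeneous Poisson neuron at 20 spikes/s averages to 20
  set.seed(61)
  n_tr <- 500
  trh <- tiny_trials(1)[rep(1, n_tr), ]
  trh$trial_id <- seq_len(n_tr)
  counts <- rpois(n_tr, 20 * 0.3)
  sph <- data.frame(trial_id = rep(trh$trial_id, counts), neuron_id = "n1",
                    t_s = runif(sum(counts), -0.3, 0))
  expect_equal(mean(baseline_rate(sph, trh)[, "n1"]), 20, tolerance = 0.5)
})

test_that("spatiotemporal map localises activity and is offset invariant", {
  ses <- small_session(seed = 3, n_pmd = 12L, n_center_out = 64L,
                       n_per_condition = 30L)
  fits <- truth_fits(ses)
  fits_v <- truth_fits(ses, "visual")
  fits_all <- rbind(fits, fits_v)
  map <- spatiotemporal_map(ses, fits_all, t_start_ms = 300, t_end_ms = 700,
                            time_bin_ms = 100, conditions = "zero")
  expect_equal(dim(map$values), c(16L, 4L))
  expect_true(all(map$n >= 0))
  # during the delay the population is most active at small PD-reach offsets
  prof <- rowMeans(map$values, na.rm = TRUE)
  center_bins <- c(8, 9)    # offsets straddling 0
  far_bins <- c(1, 16)      # offsets near 180
  expect_gt(mean(prof[center_bins]), mean(prof[far_bins]))

  # rotating all PDs and reaches together leaves the map unchanged
  ses_rot <- ses
  ses_rot$trials$reach_deg <- wrap_deg(ses$trials$reach_deg + 90)
  fits_rot <- fits_all
  fits_rot$pd_deg <- wrap_deg(fits_all$pd_deg + 90)
  map_rot <- spatiotemporal_map(ses_rot, fits_rot, t_start_ms = 300,
                                t_end_ms = 700, time_bin_ms = 100,
                                conditions = "zero")
  expect_equal(map_rot$values, map$values, tolerance = 1e-9)
})

test_that("group_rate_difference recovers a planted off-direction gain", {
  set.seed(62)
  ses <- generate_session(cfg = observer_config(),
                          ncfg = neuron_config(n_pmd = 16L, od_gain = 5),
                          n_center_out = 48L, n_per_condition = 120L)
  fits <- truth_fits(ses)
  w <- epoch_window("target_500_700", "target_on", 500, 700)
  od <- group_rate_difference(ses, fits, "OD", w, n_boot = 200, seed = 1)
  sd_ <- group_rate_difference(ses, fits, "SD", w, n_boot = 200, seed = 2)
  # peak gain 5 with shape (1-cos)/2 averages to ~0.95 * 5 over the OD band
  expect_gt(od$delta, 3.2)
  expect_lt(od$delta, 6.5)
  expect_true(od$ci_lo <= od$delta && od$delta <= od$ci_hi)
  # SD neurons see almost none of the gain
  expect_true(sd_$ci_lo < 1 & sd_$ci_hi > -1)

  # relabeling the conditions negates the delta
  od_swap <- group_rate_difference(ses, fits, "OD", w, n_boot = 0,
                                   conditions = c("high", "low"))
  expect_equal(od_swap$delta, -od$delta, tolerance = 1e-9)
})

test_that("label-shuffled conditions give group deltas centred at zero", {
  set.seed(63)
  ses <- generate_session(cfg = observer_config(),
                          ncfg = neuron_config(n_pmd = 12L, od_gain = 4),
                          n_center_out = 16L, n_per_condition = 80L)
  fits <- truth_fits(ses)
  w <- epoch_window("target_500_700", "target_on", 500, 700)
  unc <- ses$trials$block == "uncertainty"
  deltas <- sapply(1:8, function(s) {
    set.seed(800 + s)
    shuf <- ses
    shuf$trials$condition[unc] <- sample(ses$trials$condition[unc])
    group_rate_difference(shuf, fits, "OD", w, n_boot = 0)$delta
  })
  expect_lt(abs(mean(deltas)), 1.5)
})

test_that("uncertainty_activity_regression recovers a planted linear relation", {
  set.seed(64)
  x <- runif(25, 0, 30)
  y <- 0.2 * x + rnorm(25, 0, 0.5)
  r <- uncertainty_activity_regression(y, x, group = "OD", window = "w")
  fit <- lm(y ~ x)
  ci <- confint(fit)[2, ]
  expect_true(ci[1] <= 0.2 && 0.2 <= ci[2])
  expect_lt(r$p, 0.05)
  expect_true(r$r2 > 0 && r$r2 <= 1)

  expect_warning(r2 <- uncertainty_activity_regression(c(1, 2), c(0, 10)),
                 "under-determined")
  expect_equal(r2$r2, 1)
  expect_true(r2$underdetermined)
  expect_error(uncertainty_activity_regression(c(1, 2, 3), c(5, 5, 5)),
               "degenerate")
})

test_that("null planted slope stays non-significant most of the time", {
  rejections <- sapply(1:20, function(s) {
    set.seed(900 + s)
    x <- runif(20, 0, 30)
    y <- rnorm(20, 0, 0.8)
    uncertainty_activity_regression(y, x)$p < 0.05
  })
  expect_lte(mean(rejections), 0.10 + 1e-9)
})

test_that("sliding_window_regression returns one row per group and window", {
  set.seed(65)
  sessions <- lapply(1:4, function(i) {
    generate_session(cfg = observer_config(subj_like_kappa_high = c(1.5, 3, 6, 10)[i]),
                     ncfg = neuron_config(n_pmd = 8L, od_gain = i),
                     n_center_out = 24L, n_per_condition = 40L,
                     session_id = sprintf("S%d", i))
  })
  fits <- lapply(sessions, function(s) {
    rbind(truth_fits(s, "visual"), truth_fits(s, "delay"), truth_fits(s, "movement"))
  })
  bd <- data.frame(session_id = sprintf("S%d", 1:4),
                   delta_behavioral_uncertainty = c(25, 15, 8, 2))
  out <- sliding_window_regression(sessions, fits, bd)
  # 1 visual + 4 delay + 2 movement windows, 3 groups
  expect_equal(nrow(out), 7L * 3L)
  expect_setequal(unique(out$group), c("SD", "ORTH", "OD"))
  expect_equal(sum(out$window == "visual_50_250"), 3L)
})

test_that("metric subsampling reproduces full-set correlations and is deterministic", {
  set.seed(66)
  unc <- runif(12, 0, 30)
  od <- 0.2 * unc + rnorm(12, 0, 0.6)
  cw <- -0.01 * unc + rnorm(12, 0, 0.05)
  full <- metric_subsample_analysis(od, unc, cw, subset_size = 12,
                                    n_subsamples = 1, seed = 1)
  expect_equal(full$correlations$cor_od_unc[1], cor(od, unc))
  expect_equal(full$correlations$cor_unc_cw[1], cor(unc, cw))

  a <- metric_subsample_analysis(od, unc, cw, 8, n_subsamples = 50, seed = 9)
  b <- metric_subsample_analysis(od, unc, cw, 8, n_subsamples = 50, seed = 9)
  expect_identical(a$subsets, b$subsets)
  expect_equal(a$correlations, b$correlations)
  # subsets are unique
  keys <- sapply(a$subsets, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  # extreme subsets bracket the subsample distribution
  expect_gte(cor(unc[a$extreme_max], cw[a$extreme_max]),
             max(a$correlations$cor_unc_cw))
  expect_lte(cor(unc[a$extreme_min], cw[a$extreme_min]),
             min(a$correlations$cor_unc_cw))
  expect_error(metric_subsample_analysis(od, unc, cw, 3), ">= 4")
})

test_that("covariate reversal flips the condition difference by trimming", {
  set.seed(67)
  tr <- data.frame(condition = rep(c("low", "high"), each = 100),
                   trial_id = 1:200,
                   peak_speed_cms = c(rnorm(100, 25, 1), rnorm(100, 25.2, 1)))
  out <- covariate_reversal_resample(tr, "peak_speed_cms")
  d <- mean(out$peak_speed_cms[out$condition == "high"]) -
    mean(out$peak_speed_cms[out$condition == "low"])
  expect_lt(d, 0)
  expect_true(all(out$trial_id %in% tr$trial_id))
  expect_gte(sum(out$condition == "high"), 50)

  # already-reversed input is a no-op
  out2 <- covariate_reversal_resample(tr, "peak_speed_cms", target_sign = 1)
  expect_equal(nrow(out2), 200L)

  # infeasible when supports are disjoint
  tr_bad <- tr
  tr_bad$peak_speed_cms <- ifelse(tr_bad$condition == "high",
                                  rnorm(200, 40, 0.1), rnorm(200, 20, 0.1))
  expect_error(covariate_reversal_resample(tr_bad, "peak_speed_cms"),
               "infeasible")
})

test_that("grouped prior analysis partitions sessions and matches the global fit", {
  set.seed(68)
  x <- runif(16, 0, 30)
  y <- 0.15 * x + rnorm(16, 0, 0.5)
  pm <- rep(c(0, 90), each = 8)
  out <- grouped_prior_analysis(y, x, pm, window = "w")
  expect_equal(nrow(out), 2L)
  expect_equal(sum(out$n_sessions), 16L)
  expect_true(all(out$slope > 0))

  # a single group reproduces the global regression
  g1 <- grouped_prior_analysis(y, x, rep(45, 16))
  glob <- uncertainty_activity_regression(y, x)
  expect_equal(g1$slope, glob$slope)
  expect_equal(g1$p, glob$p)

  expect_warning(grouped_prior_analysis(y, x, c(rep(0, 13), rep(90, 3))),
                 "skipping")
})
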