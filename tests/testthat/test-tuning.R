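test_that("epoch_spike_counts respects half-open windows and alignment", {
  tr <- tiny_trials()   # t_target_on 1.0, t_move_on 2.0 => move at +1.0 s
  sp <- tiny_spikes(
    trial_id = c(1, 1, 1, 2, 2),
    neuron_id = "n1",
    t_s = c(0.100, 0.150, 0.250, 1.050, 0.999)
  )
  vis <- epoch_spike_counts(sp, tr, default_epochs()$visual)
  # 0.100 and 0.150 in [0.050, 0.250); 0.250 excluded at the boundary
  expect_equal(unname(vis$counts[1, "n1"]), 2L)
  mov <- epoch_spike_counts(sp, tr, default_epochs()$movement)
  # movement window [0, 200) ms after move onset (= +1.0 s): 1.050 in, 0.999 out
  expect_equal(unname(mov$counts[2, "n1"]), 1L)
  expect_equal(vis$durations_s[1], 0.2)
})

test_that("fit_poisson_tuning recovers a noiseless cosine-tuned neuron", {
  dirs <- rep(seq(0, 315, by = 45), 20)
  dur <- rep(1, length(dirs))
  counts <- round(dur * exp(2 + 1 * cos((dirs - 40) * pi / 180)))
  f <- fit_poisson_tuning(counts, dur, dirs)
  expect_lt(abs(wrap_deg(f$pd_deg - 40)), 2)
  expect_equal(f$beta, 1, tolerance = 0.05)
  # model identity: fitted rate ratio at PD vs anti-PD is exp(2 beta)
  rate_at <- function(th) exp(f$alpha + f$beta * cos((th - f$pd_deg) * pi / 180))
  expect_equal(rate_at(f$pd_deg) / rate_at(f$pd_deg + 180), exp(2 * f$beta),
               tolerance = 1e-6)
})

test_that("degenerate inputs are flagged rather than mis-fit", {
  dirs <- rep(seq(0, 315, by = 45), 3)
  dur <- rep(0.5, length(dirs))
  f <- fit_poisson_tuning(rep(4L, length(dirs)), dur, dirs)
  expect_lt(f$beta, 1e-6)
  expect_false(f$pd_stable)
  expect_equal(f$alpha, log(4 / 0.5), tolerance = 1e-6)

  fz <- fit_poisson_tuning(rep(0L, length(dirs)), dur, dirs)
  expect_true(fz$all_zero)
  expect_identical(fz$alpha, -Inf)

  expect_error(fit_poisson_tuning(1:6, rep(1, 6), c(0, 45, 90, 135, 180, 225)),
               "at least 8")
  expect_error(fit_poisson_tuning(rep(1L, 10), rep(1, 10), rep(c(0, 90), 5)),
               "3 distinct")
})

test_that("tuning fit is rotation equivariant", {
  set.seed(51)
  dirs <- rep(seq(0, 315, by = 45), 15)
  dur <- rep(0.2, length(dirs))
  counts <- rpois(length(dirs), dur * 15 * exp(1.2 * cos((dirs - 70) * pi / 180)))
  f0 <- fit_poisson_tuning(counts, dur, dirs)
  f1 <- fit_poisson_tuning(counts, dur, wrap_deg(dirs + 33))
  expect_equal(f1$alpha, f0$alpha, tolerance = 1e-6)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-6)
  expect_equal(wrap_deg(f1$pd_deg - f0$pd_deg), 33, tolerance = 1e-6)
})

test_that("fitted log-likelihood beats the untuned null model", {
  set.seed(52)
  dirs <- rep(seq(0, 315, by = 45), 10)
  dur <- rep(0.2, length(dirs))
  for (beta in c(0, 0.5, 2)) {
    y <- rpois(length(dirs), dur * 12 * exp(beta * cos(dirs * pi / 180)))
    if (all(y == 0)) next
    f <- fit_poisson_tuning(y, dur, dirs)
    null_ll <- as.numeric(logLik(glm(y ~ offset(log(dur)), family = poisson())))
    expect_gte(f$loglik, null_ll - 1e-8)
  }
})

test_that("bootstrap refits agree with glm on explicit resamples", {
  set.seed(53)
  dirs <- rep(seq(0, 315, by = 45), 12)
  dur <- rep(0.2, length(dirs))
  y <- rpois(length(dirs), dur * 20 * exp(1.5 * cos((dirs - 100) * pi / 180)))
  n <- length(y)
  W <- rmultinom(5, n, rep(1 / n, n))
  th <- dirs * pi / 180
  X <- cbind(1, cos(th), sin(th))
  res <- uncertainreach:::pois_cos_newton(y, X, log(dur), W,
                                          c(log(mean(y) / 0.2), 0, 0))
  for (j in 1:5) {
    idx <- rep(seq_len(n), W[, j])
    g <- glm(y[idx] ~ cos(th[idx]) + sin(th[idx]) + offset(log(dur[idx])),
             family = poisson(), control = glm.control(epsilon = 1e-12))
    expect_equal(unname(res$coef[, j]), unname(coef(g)), tolerance = 1e-8)
  }
})

test_that("bootstrap significance separates tuned from untuned neurons", {
  dirs <- rep(seq(0, 315, by = 45), 25)
  dur <- rep(0.2, length(dirs))
  n_rep <- 12L
  sig_tuned <- sig_flat <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    set.seed(600 + s)
    y_t <- rpois(length(dirs), dur * 20 * exp(2 * cos((dirs - 60) * pi / 180)))
    y_f <- rpois(length(dirs), dur * 20)
    sig_tuned[s] <- bootstrap_pd_significance(y_t, dur, dirs, n_boot = 200)$significant
    sig_flat[s] <- bootstrap_pd_significance(y_f, dur, dirs, n_boot = 200)$significant
  }
  expect_gte(mean(sig_tuned), 0.95)
  expect_lte(mean(sig_flat), 0.10)
})

test_that("the 90-degree criterion admits every neuron the 45-degree criterion admits", {
  dirs <- rep(seq(0, 315, by = 45), 15)
  dur <- rep(0.2, length(dirs))
  for (s in 1:6) {
    set.seed(700 + s)
    beta <- runif(1, 0, 1.5)
    y <- rpois(length(dirs), dur * 15 * exp(beta * cos((dirs - 10) * pi / 180)))
    b45 <- bootstrap_pd_significance(y, dur, dirs, n_boot = 200,
                                     criterion_deg = 45, seed = 900 + s)
    b90 <- bootstrap_pd_significance(y, dur, dirs, n_boot = 200,
                                     criterion_deg = 90, seed = 900 + s)
    if (isTRUE(b45$significant)) expect_true(b90$significant)
  }
  expect_error(bootstrap_pd_significance(rpois(80, 2), rep(0.2, 80),
                                         rep(seq(0, 315, by = 45), 10),
                                         n_boot = 50), ">= 100")
})

test_that("tuned_fraction counts significant neurons among fit-able ones", {
  fits <- data.frame(epoch = "delay", significant = c(TRUE, TRUE, FALSE, TRUE),
                     unfit = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(tuned_fraction(fits, "delay"), 100 * 2 / 3)
  fits$significant <- TRUE
  fits$unfit <- FALSE
  expect_equal(tuned_fraction(fits, "delay"), 100)
  fits$significant <- FALSE
  expect_equal(tuned_fraction(fits, "delay"), 0)
  expect_error(tuned_fraction(fits, "visual"), "no fit-able")
})
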