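# Independent oracles and small fixture builders used across the suite.

# Circular mean of the normalized product of two von Mises densities,
# computed by quadrature (independent of vm_product_mean's closed form).
product_mean_quadrature <- function(mu1_deg, k1, mu2_deg, k2) {
  m1 <- mu1_deg * pi / 180
  m2 <- mu2_deg * pi / 180
  # scale by the peak exponent (the resultant length of the two
  # concentration vectors) so the integrand stays O(1) at large kappa
  peak <- sqrt(k1^2 + k2^2 + 2 * k1 * k2 * cos(m2 - m1))
  f <- function(th) exp(k1 * cos(th - m1) + k2 * cos(th - m2) - peak)
  C <- stats::integrate(function(th) cos(th) * f(th), -pi, pi,
                        rel.tol = 1e-10, abs.tol = 1e-13,
                        subdivisions = 400L)$value
  S <- stats::integrate(function(th) sin(th) * f(th), -pi, pi,
                        rel.tol = 1e-10, abs.tol = 1e-13,
                        subdivisions = 400L)$value
  atan2(S, C) * 180 / pi
}

# Bessel-ratio mean resultant length I1(k)/I0(k), written independently of
# the package's vm_mean_resultant.
bessel_ratio_R <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Invert R = I1(k)/I0(k) numerically.
kappa_from_R <- function(R) {
  stats::uniroot(function(k) bessel_ratio_R(k) - R, c(1e-6, 500),
                 tol = 1e-10)$root
}

# Minimal hand-built session: a few trials and spikes with exactly known
# placement, for counting and alignment tests.
tiny_trials <- function(n = 4L, reach = c(0, 90, 180, -90)) {
  data.frame(
    session_id = "tiny", trial_id = seq_len(n),
    block = "center_out", condition = "zero",
    prior_mean_deg = 0, cue_lines_deg = "",
    cue_centroid_deg = reach[seq_len(n)], target_deg = reach[seq_len(n)],
    reach_deg = reach[seq_len(n)],
    t_target_on_s = 1.0, t_go_s = 1.8, t_move_on_s = 2.0,
    reaction_time_s = 0.2, peak_speed_cms = 25
  )
}

tiny_spikes <- function(trial_id, neuron_id, t_s) {
  data.frame(trial_id = trial_id, neuron_id = neuron_id, t_s = t_s)
}

# Small complete synthetic session for integration-style tests.
small_session <- function(seed = 1, n_pmd = 8L, n_center_out = 48L,
                          n_per_condition = 60L, od_gain = 0) {
  set.seed(seed)
  generate_session(
    cfg = observer_config(),
    ncfg = neuron_config(n_pmd = n_pmd, od_gain = od_gain),
    n_center_out = n_center_out, n_per_condition = n_per_condition,
    session_id = paste0("S", seed)
  )
}
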