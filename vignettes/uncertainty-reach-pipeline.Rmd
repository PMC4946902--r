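---
title: "Methods: uncertainty-dependent population analysis of reach planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-dependent population analysis of reach planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uncertainreach)
```

This vignette is the package's own account of its models, numerical choices
and the design decisions that were genuinely open, in the spirit of a methods
section. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The task and the behavioral model

The pipeline targets two-block reaching sessions. A center-out block presents
eight equispaced, unambiguous targets with an instructed delay (center hold
700–1000 ms, delay 700–1000 ms). An uncertainty block draws targets from a
von Mises prior with fixed mean and cues them with 5 or 10 lines sampled from
a von Mises likelihood around the target; two likelihood widths (low/high
uncertainty) are randomly interleaved.

Behavior is summarised by a Bayesian cue-integration observer. The product of
a von Mises prior (μ₁, k₁) and likelihood (μ₂, k₂) is a von Mises kernel
whose mean is the direction of the resultant of the two concentration
vectors; `vm_product_mean()` implements this with a full-quadrant arctangent
so near-opposed means are handled. `fit_cue_weighting()` substitutes the
session's prior mean for μ₁ and each trial's cue centroid for μ₂ and fits the
single free parameter r = k₁/k₂ by minimising the sum of squared *wrapped*
residuals. Two decisions matter here:

* **Exact rule, linear summary.** Predictions use the exact product mean, not
  its linear approximation μ₁ + w(μ₂ − μ₁), because the exact rule is valid
  for any centroid offset; the linearisation is regression-tested to agree
  within 1° for offsets up to 45° and w in [0.2, 0.8]. The reported summary
  remains the slope w = 1/(1 + r), the field's usual cue-weighting number.
* **1-D search, not gradient descent.** The objective is one-dimensional in
  log r; a 1,000-point grid on [−6, 6] followed by golden-section refinement
  is cheap, immune to local minima, and makes the w ≈ 0 and w ≈ 1
  degeneracies explicit (`at_bound` flag instead of an infinite ratio).
* **The observer's internal prior mean is taken to be the true prior mean.**
  Any systematic bias the subject has folds into the residual dispersion.

"Behavioral uncertainty" is the angular dispersion of the fit residuals.
Since no single convention dominates, the package exposes both the circular
variance 1 − R and the circular standard deviation √(−2 ln R) (degrees) from
`circ_summary()`, and uses the latter as *the* dispersion; both are monotone
in R, so cross-session correlations are insensitive to the choice. A mean
direction is flagged undefined when R < 1e−9 (antipodal cancellation), and
angles live in degrees at every interface, canonical range (−180°, 180°],
radians internally.

## Tuning fits

Counts in an epoch are modelled as Poisson with rate
duration × exp(α + b₁cos θ + b₂sin θ); β = √(b₁² + b₂²), θ\* = atan2(b₂, b₁).
The exposure offset keeps α in log spikes/s across epochs of different
lengths. Point fits go through `stats::glm` (Poisson family; the
log-likelihood is concave, so IRLS converges globally). Bootstrap refits are
the computational bottleneck, so `bootstrap_pd_significance()` expresses
trial resampling as multinomial weights and runs a damped Newton solver for
all replicates simultaneously; it is unit-tested to agree with `stats::glm`
on explicitly materialised resamples to 1e−8. A neuron is significantly tuned
when ≥95% of bootstrap θ\* estimates fall within 45° of their circular mean —
the bootstrap mean, not the point estimate, anchors the criterion — with a
90° relaxation for low-yield datasets. The bootstrap count defaults to 1,000
(unstratified resampling; the pipeline wrappers use 100–200 where many
neurons are refit). Epochs: visual 50–250 ms and delay 300–700 ms after
target onset, movement 0–200 ms after movement onset; PDs are fit per epoch
and used epoch-matched downstream, and only neurons significant in the
analysed epoch enter population analyses.

## Population analyses

`partition_direction_groups()` classes each neuron-trial by
offset = wrap(PD − reach): SD in [−45°, 45°), OD in [135°, 180°] ∪
(−180°, −135°), ORTH otherwise — a partition of the circle (90/180/90 of 360
integer offsets). Rates are baseline-subtracted; the baseline window is
[−300, 0) ms before target onset (the data format records spikes from −400 ms
by default). The spatiotemporal map uses 16 offset bins of 22.5° and 20 ms
time bins with no smoothing — bin widths chosen to match the decoder's
geometry, smoothing left to plotting — and flags empty cells as missing
rather than zero. `group_rate_difference()` averages within neuron, then
across neurons, and bootstraps trials within condition for its confidence
interval. Cross-session inference is unweighted OLS of the group rate
difference on ∆behavioral uncertainty (a weighted option would be natural
when neuron counts vary wildly; the headline fit is unweighted), in the
headline window 500–700 ms post-target and in sliding 100-ms windows across
the delay and movement periods. Whether rates should be baseline-subtracted
in these comparisons was an open choice; subtraction was adopted for
consistency with the maps, and since the baseline is condition-independent it
cancels in expectation from the high-minus-low difference anyway.

The two controls: `covariate_reversal_resample()` trims the extreme trials of
one condition (rank-based, retaining at least half of that condition) until
the sign of a kinematic covariate's condition difference reverses, so a
surviving neural effect cannot be explained by that covariate.
`metric_subsample_analysis()` draws unique session subsets and compares, per
subset, how strongly the OD activity difference correlates with each of the
two behavioral metrics; extreme subsets for the metric-metric correlation are
found by greedy single-swap search from random starts (200 by default), since
no exact method is needed for a diagnostic.

## Decoding

Sixteen 22.5° PD bins are built from center-out PDs (bin 1 starts at −180°;
+180° is identified with −180°). Per trial, baseline-subtracted rates are
averaged within bins and a + b cos(φ − φ₀) is least-squares fitted over
occupied bin centers; φ₀ is the decode. Empty bins are excluded rather than
imputed, with at least 8 occupied bins required; profiles with fitted
amplitude below 1e−9 are flagged undecodable rather than assigned a noise
direction. Performance is 1 − circular variance of the errors, i.e. the mean
resultant length of the error sample — an identity the tests assert on every
path. The four analysis windows are the target-aligned 200-ms windows
[0,200), [200,400), [400,600) plus a movement-aligned [0,200) window, spanning
target appearance to movement; exact edges are config-exposed since no single
choice is canonical. The delay-epoch center-out PDs drive binning for every
window by default (one stable PD set per session, config-exposed). A session
is `included` for condition comparisons when its mean low-uncertainty
performance exceeds 0.5, and conditions are compared by paired t-tests over
included sessions.

## The synthetic-session generator

The generator exists so every stage can be scored against ground truth. Its
defaults define the study conditions used by the tests and the acceptance
script: 20 sessions, 96 center-out plus 150 trials per uncertainty condition,
20 PMd-like neurons (uniform-stratified PDs, baselines 5–25 spikes/s, cosine
modulations β in [0.4, 1.2]), reaction times 150–300 ms. These sizes are the
package's chosen operating point for simulation studies: large enough that
per-session metrics are stable, small enough to run many replicate studies
routinely.

**Behavior.** Targets come from the prior (κ = 0.8 by default), cue lines
from the condition's likelihood; the observer reaches to the product mean of
its *subjective* prior and likelihood, plus von Mises noise at the posterior
concentration κ₃ (the resultant concentration of the two subjective kernels),
plus motor noise (κ = 30). The posterior-sampling term is the mechanism that
makes behavioral uncertainty rise as the subjective likelihood concentration
falls — without it, residual dispersion would be condition-independent motor
noise and the session contrast the analyses regress on would not exist.
High-uncertainty trials also get slightly longer reaction times (+20 ms) and
lower peak speeds (−1 cm/s) so the kinematic-covariate controls have
something to work with.

**Two deliberate choices keep the planted neural effect interpretable.**
First, the subjective prior is weak (κ ≈ 0.4–1.0) and the true prior wide, so
the cue-weighting contrast between conditions stays modest while the
posterior width varies strongly. This keeps the two conditions'
reach-direction distributions closely matched; with strongly mismatched
distributions, per-neuron conditional averaging of cosine-tuned rates
produces spurious SD/OD condition differences that have nothing to do with
any planted gain (a confound worth knowing about when interpreting real data,
too). Second, the off-direction gain — additive rate g·(1 − cos(offset))/2,
zero at the reach direction, maximal opposite it, active from 250 ms
post-target (the early visual burst is left gain-free) through the movement
segment, PMd-like area only — follows the law
OD effect = a·∆behavioral uncertainty + Gaussian noise (truncated at zero,
since the modelled phenomenon only ever adds activity), with
∆behavioral uncertainty taken as the session's *realized* residual dispersion
contrast and the peak g scaled by the session's own neuron-weighted mean of
the gain shape over the OD band. Both scalings serve one purpose: the
coefficient `a` is then exactly the slope, in (spikes/s)/degree, that the
analysis-side OD regression estimates, so parameter recovery is a clean
hypothesis rather than a calibration exercise.

**Spikes** are piecewise-constant-rate Poisson processes (baseline before
50 ms; visual, delay and movement segment rates exp(α + β_epoch cos(reach −
PD)); baseline tail), sampled segment-wise. Fano factors near 1 are asserted
in the tests.

**What the generator does not emulate.** Real PMd has temporally structured,
history-dependent firing, heterogeneous (non-cosine) tuning, correlated
noise, and an early-visual-burst suppression under uncertainty that is
deliberately not planted (the gain-free early window simply stays
gain-free). Passing recovery tests on this generator therefore shows the
*analysis chain* is correct and well-calibrated — unbiased slope recovery,
null calibration, decoder exactness — not that real cortex satisfies the
model. Sessions are independent by construction; no neuron identity is
tracked across sessions.

## Numerical conventions and degenerate inputs

* Wrapping: (−180°, 180°], with +180 the canonical image of the boundary.
* von Mises sampling is Best–Fisher rejection; densities use scaled Bessel
  functions and stay finite up to κ ≈ 1e6.
* Epoch windows are half-open [start, end) in milliseconds; a spike exactly
  at the end bound is excluded.
* All-zero spike counts give α = −∞ with an `all_zero` flag; numerically
  unmodulated fits (β < 1e−6) flag the PD unstable instead of reporting a
  noise direction.
* Bootstrap refit failures above 10% mark a neuron `unfit` (significance NA).
* Regressions with fewer than 4 points are flagged `underdetermined`;
  degenerate predictors (all sessions identical) are errors, not NaNs.

## Known limitations

The cue-weighting fit estimates only the concentration *ratio*, not the
posterior width (no κ₃ estimation); the observer model assumes the centroid
is the sufficient cue statistic; the decoder is a fixed-basis cosine fit, not
a probabilistic decoder; and the acceptance-level recovery criteria for the
cross-session regression are intrinsically tight — a correctly calibrated 95%
confidence interval misses the generating slope 5% of the time, and the fixed
gain shape leaks a small (≈5% of peak) effect into the SD band, so joint
"OD recovered, SD silent" success rates near 90% per study are the honest
ceiling, not evidence of miscalibration.
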