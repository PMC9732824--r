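---
title: "Modeling social and nonsocial decisions: accumulator fitting, single-trial EEG decoding, and EEG-informed fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling social and nonsocial decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroaccum)
```

# The problem

This package implements a model-based analysis of two-alternative economic
decisions ("play" for a risky payoff versus "keep" a sure one) made under
social uncertainty (the perceived trustworthiness of a partner's face) or
nonsocial uncertainty (an explicit reward probability). Both contexts vary
along the same five reward-probability levels, recoded as signed evidence
`(-0.5, -0.25, 0, 0.25, 0.5)` and three difficulty grades (levels 1 and 5
easy, 2 and 4 medium, 3 hard). The pipeline has three stages:

1. a sequential-sampling (Ornstein-Uhlenbeck) account of choices and
   response times,
2. single-trial EEG decoding that extracts a per-trial evidence-accumulation
   build-up rate, and
3. a BOLD general linear model in which that build-up rate is a parametric
   regressor, with a resampling-based cluster threshold and a
   psychophysiological interaction (PPI) analysis of task-dependent
   coupling.

Because every stage is exercised on synthetic data with planted ground
truth, the package also ships a first-class generator module for behavior,
epoched EEG, scanner-contaminated continuous EEG, and 4D BOLD volumes.

# The accumulator model

Evidence accumulates from 0 toward absorbing bounds at +1 (play) and -1
(keep) by the Euler recursion

```
EA[t+1] = EA[t] + leak * EA[t] * dt + k * evidence * dt + N(0, sigma) + bias
```

with `dt = 0.001` s. `leak` (1/s) is a *positive* self-coupling — an
acceleration toward the nearer bound; `k` converts signed evidence into a
mean drift; `sigma` is the per-step noise SD (deliberately tied to the 1 ms
step rather than scaled by `sqrt(dt)`, so altering `dt` changes the
effective diffusion — the constructor warns if you do); `bias` is added only
on zero-evidence trials; `ndt` is the non-decision time added to the first
passage. Typical fitted values for this task are `leak` near 5/s, `k` near
3, `sigma` near 0.01-0.02, `ndt` near 0.3 s.

Trials that fail to reach a bound within the 3 s cap are redrawn; if more
than 1% of draws would need redrawing the parameter point is rejected rather
than silently censored, which keeps RT distributions well defined.

## The pseudo-likelihood and its geometry

The fit score per evidence level is the log of the asymptotic two-sample
Kolmogorov-Smirnov p-value between observed and simulated *signed* RTs
(keep RTs carry a negative sign) plus a Gaussian penalty
`-((Pplay_data - Pplay_model)/0.01)^2` on the play fraction, summed over
levels (`ou_pseudo_loglik()`). The score is at most 0 and is extremely
sharp in `ndt`: shifting a whole RT distribution by 10 ms collapses the KS
p-values by orders of magnitude.

Two structural facts shaped the fitting code:

* **A mimicry ridge.** Parameter sets in which `k` and `sigma` are scaled
  jointly, with `leak` and `ndt` co-adjusted, reproduce both the
  psychometric curve and the signed-RT distributions almost exactly. At 400
  trials per level, profile likelihoods along this ridge are flat to about
  one log unit over roughly +/-30% in `k`, which is the practical
  identifiability limit of the drift gain under this objective — a
  limitation users should keep in mind when interpreting absolute parameter
  values (relative, between-subject ordering is much more stable).
* **Simulation noise masquerades as structure.** The objective is itself a
  Monte-Carlo estimate. All evaluations use common random numbers (a fixed
  simulator seed per fit stage) so local search sees a deterministic
  surface, and final model selection re-scores candidates at a several-fold
  larger trace count, where the KS comparison is powerful enough to reject
  mimicking parameter sets.

## The two-step fit

`ou_fit()` follows a two-step scheme — bounded derivative-free search, then
a factorial grid (default 7 points per parameter spanning +/-30%) around the
optimum — augmented with stages that target the ridge geometry:

1. a coarse random scan over `(leak, k, sigma)` in which `ndt` is *profiled
   out*: one simulation of decision times per candidate serves a dense grid
   of `ndt` values, because `ndt` only shifts RTs;
2. slice refinement: from the best candidates, a 2D grid over `leak` and the
   joint `(k, sigma)` scale (the ridge coordinates), again with `ndt`
   profiled, in a global-then-zoom pass;
3. Nelder-Mead restarts (logit-transformed to respect the bounds: `leak` in
   [0,15], `k` in [0,10], `sigma` in [1e-4, 0.1], `bias` in [-0.01, 0.01],
   `ndt` in [0.1, 0.8] s, chosen to bracket plausible estimates for this
   task) from the refined starting points;
4. the stage-two grid, a short polish, and final selection among all
   candidate optima at `n_traces_select` traces per level (default 8x the
   reporting count).

BIC is `c*log(n) - 2*LL` with `c` the number of free parameters (5, or 6
for the variable-boundary variant). Because a free boundary is exactly
equivalent to rescaling `k` and `sigma`, the variable-boundary model can
never fit better in expectation and loses by the `log(n)` penalty — the
model-recovery behavior the BIC comparison is designed to demonstrate.

# Behavioral statistics

* `lrt_single_vs_separate()` fits, per subject, one Weibull psychometric
  curve `P(play) = guess + (1 - guess - lapse) * (1 - exp(-(x/alpha)^beta))`
  jointly to both contexts and a separate-curves model in which only `alpha`
  and `beta` are context-specific (`guess` and `lapse` stay shared, so
  exactly two parameters differ and the statistic has 2 df). Subject
  likelihoods are averaged on the likelihood scale (via log-sum-exp) before
  forming `-2 log` of the ratio. The exact psychometric parameterization is
  a package choice: the lapse and guess rates are bounded at 5% and the
  curve runs over the level index 1..5.
* `fit_choice_logistic()` runs the single-trial logistic regressions of
  choice on reward-probability level, on the signed EEG build-up slope, or
  both; `rt_difficulty_regression()` regresses RT on the three-grade
  difficulty; both test per-subject coefficients with a two-tailed
  one-sample t test. Subjects with separated logistic fits are flagged and
  excluded from the group test.
* `slope_autoregression()` regresses each trial's slope on its four
  predecessors, quantifying slow attentional drifts.
* `min_sample_size()` inverts one-sample t-test power via the noncentral t
  distribution (for this task's planning effect size of d = 0.847 at alpha
  = 0.05 and power 0.95 it returns 21).

# Single-trial EEG decoding

`sliding_loo_az()` trains a regularized Fisher discriminant between easy
and hard trials in 60 ms windows stepped every 20 ms across the
stimulus-locked epoch (-100..800 ms). Channel data are averaged within the
window (one feature vector per trial), class covariances are shrunk,
`S~ = (1-gamma) S + gamma nu I` with `nu` the average eigenvalue, and the
weights solve `S_common w = m2 - m1`. Although the source description
prints the weight rule without the inverse, a Fisher discriminant requires
it — and regularizing the covariance only matters for inversion — so the
package implements `w = S~^-1 (m2 - m1)`. Performance is the area under
the ROC curve (Az) of leave-one-trial-out projections, computed by the rank
formula and cross-checked against an independent ROC implementation in the
tests; the LOO loop uses exact rank-one downdates of the class means and
scatter matrices rather than refitting from scratch. The shrinkage value is
chosen per subject by peak LOO Az over the grid
`{0, 0.01, 0.02, 0.04, 0.08, 0.16}`; argmax ties break toward the earlier
window. A bootstrap over label permutations (default 500) gives a
subject-specific Az significance threshold instead of assuming 0.5 chance.

The discriminant's sign is arbitrary, so the weights are oriented to make
the grand-average projection *rise* toward the late epoch (the build-up
convention); Az is unchanged. The peak-window weights applied across the
whole epoch give the component time course `y(t)`, z-scored per subject and
context. Onsets are detected on 50 ms-smoothed condition means as the
deepest interior minimum (the post-evoked dip) within a 150-600 ms search
window, with the build-up peak sought after that window so early evoked
deflections cannot capture it; a sustained-positive-derivative fallback is
used (and flagged) when no dip exists. Per-trial build-up slopes are OLS
slopes of `y(t)` between onset and peak; `flip_slopes()` flips the sign for
the two keep-favoring reward levels so slopes share the accumulator's
signed-drift convention. The forward model `a = X y / (y' y)` maps the
component back to channel space.

# EEG artifact pipeline

The desk-scale scanner-EEG pipeline comprises: sliding average-artifact
subtraction for the gradient artifact (a 70-volume window centered on each
volume; at the record edges the window is clipped to stay at full width,
since a symmetrically shrinking window would degenerate toward each volume
subtracting itself); a 12 ms running-median despiker; a 0.5-20 Hz zero-phase
frequency-domain bandpass with raised-cosine transitions (an IIR bandpass
with a 0.5 Hz edge at multi-kHz sampling rates is numerically unstable, so
the package filters in the frequency domain, as MEEG toolboxes commonly do)
followed by integer downsampling to 1000 Hz with exact trigger re-indexing;
blink removal by projecting out spatial principal components that explain
more than 20% of calibration-blink-segment variance (the threshold is a
package choice); and ballistocardiogram removal in which components are
estimated on a < 4 Hz low-passed copy, candidate datasets with 0..5
components subtracted are built, and the count with peak cross-validated Az
along the task dimension is kept.

# EEG-informed fMRI

`build_task_design()` constructs the eight task regressors — per context, a
response-locked regressor parametrically modulated by the trial-wise
build-up slope, a response-locked RT modulator, a stimulus-locked difficulty
modulator (-1 hard, 0 medium, +1 easy), and a stimulus-locked unmodulated
regressor — as 100 ms boxcars convolved with the canonical double-gamma HRF,
plus six AR(1) motion nuisance columns standing in for realignment
parameters. Parametric amplitudes are mean-centered within regressor so the
unmodulated columns absorb the mean response. Convolution is evaluated
analytically from the running integral of the HRF (a boxcar response is
`H(t - onset) - H(t - onset - dur)`), which both avoids grid convolution
error and lets amplitude shuffles reuse cached unit-event responses.

`fit_glm()` is voxelwise OLS with per-regressor t statistics converted to z
by matching tail probabilities. Trials with lower build-up rates take
longer to reach the bound and produce more integrated activity, so the
central prediction is a *negative* slope-regressor beta in accumulator
regions. `resample_cluster_threshold()` holds onsets and durations fixed
while permuting the parametric amplitudes across trials, reruns the
analysis (default 100 times), and records the largest surviving cluster
(`|z| > 2.57`, more than `min_size_keep` voxels) per shuffled analysis; the
95th percentile of these per-iteration maxima is the joint cluster-extent
threshold. Using maxima rather than pooling all null cluster sizes is what
makes the threshold family-wise: with several clusters per null map, the
pooled 95th percentile lets the per-map maximum exceed it far more often
than 5% of the time. Cluster connectivity is 26-neighborhood. On
unsmoothed desk-scale grids, null clusters above 10 voxels essentially
never occur, so calibration studies run the procedure with
`min_size_keep = 2`; and each simulated null dataset should carry its own
design draw, because a design's particular amplitude sequence fixes its
variance-inflation factor under AR(1) noise while shuffles resample it.
The group level is a one-sample t test across subject betas — a deliberate
desk-scale simplification of a mixed-effects model, out of scope here.

`build_ppi_design()` forms the interaction at the BOLD level (no
deconvolution): the psychological factor is a parametric boxcar whose
amplitude encodes difficulty (1 difficult .. 3 easy) and whose duration is
the trial RT, HRF-convolved; both it and the seed time series are centered
and scaled to unit SD before the product, so the interaction beta is a
coupling per SD of each factor, and the planted coupling in the generator
is recovered on the same scale. Expected couplings with valuation regions
are negative: easier trials shorten integration and reduce the area under
the accumulation curve. A constant-difficulty design makes the interaction
collinear with the physiological regressor and is rejected.

# The synthetic-data generator

`synth_behavior()` shares the accumulator simulator with the fit, so
planted parameters are recoverable in expectation. `synth_eeg_epochs()`
emulates the signal structure the decoding stage assumes: a 64-channel,
1000 Hz epoch whose component has an early evoked peak, a half-cosine
descent into a trough exactly at the trial-specific accumulation onset
(normal with mean 363 ms and SD 97 ms, clipped to 0.2-0.6 s), and a linear
build-up truncated — held, since the analysis is stimulus-locked and trials
end at the response — at the RT. Condition slopes default to 3/2/1
component units per second for easy/medium/hard with 30% per-trial
variability (the single-trial slope spread around condition means is not
reported for real data; 30% makes decoding realistically hard without
breaking the ordering in expectation). The component mixes through a fixed
unit-norm centroparietal-like topography; an orthogonal early visual
distractor and white sensor noise (SD 4, giving peak single-subject Az
around 0.7 at 100 trials per class, in the range typical of single-trial
EEG) complete the epochs. What the generator does *not* emulate: volume
conduction from a realistic head model, correlated (1/f) sensor noise,
non-stationary artifacts inside epochs, or hemodynamic nonlinearity on the
fMRI side — so green tests demonstrate the pipeline's correctness and
calibration, not its performance on any real recording.

`synth_raw_eeg_with_artifacts()` adds a volume-locked gradient template
(optionally drifting), a quasi-periodic ballistocardiogram with a fixed
spatial pattern, and stereotyped frontal blinks to a continuous record,
keeping ground-truth artifact signals for testing. `synth_bold()` builds
AR(1)-noise voxel time series (rho 0.3 by default, so the resampling
threshold faces temporally correlated noise rather than a trivial white
null) with planted regressor effects inside blob masks and an optional
planted PPI coupling.

# Numerical choices and problem sizes

* KS p-values are floored at 1e-300 before the log (the score is undefined
  at p = 0); the asymptotic (large-sample) p-value is used throughout,
  matching the two-sample test as implemented in common numerical
  environments, and is cross-checked against `stats::ks.test` in the unit
  tests.
* All generators and fits are deterministic given their seeds; fits
  additionally fix internal simulation seeds so results are reproducible
  run to run.
* The test suite runs the package's calibration studies at desk scale:
  parameter
  recovery uses 10 synthetic subjects at 400 trials per level with reduced
  search budgets (2 restarts, 800-trace search evaluations, 24,000-trace
  final selection); decoder calibration uses 100 trials per class at 64
  channels with a 500-iteration bootstrap; the likelihood-ratio null uses
  500 replicates of 31 subjects at 200 trials each; fMRI calibration uses
  100 null datasets on a 20 x 20 x 10 grid with 60 resampling iterations
  per dataset. These sizes are the package's choices for a reproducible
  desk-scale study and are stated here rather than in the tests.

# Known limitations

* Absolute recovery of the drift gain `k` from choice/RT data by the KS
  pseudo-likelihood is limited to roughly +/-30% at 400 trials per level by
  the mimicry ridge described above; rank ordering across subjects is
  reliable.
* The group-level fMRI model is a fixed/one-sample-t simplification;
  mixed-effects inference, spatial normalization, and real-data cluster
  coordinates are out of scope.
* The likelihood-scale averaging in the psychometric likelihood-ratio test
  is dominated by the best-fitting subjects; its null rejection rate is
  calibrated empirically in the acceptance suite rather than guaranteed by
  asymptotic theory.
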