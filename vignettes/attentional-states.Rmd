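---
title: "Modeling trial-level reaction-time variability and its BOLD correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trial-level reaction-time variability and its BOLD correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnstates)
```

## The problem

Attention fluctuates from moment to moment, and those fluctuations leave a
behavioral trace: trial-to-trial variability in reaction times (RT).
Episodic long RTs mark lapses; bursts of very short RTs mark impulsive
responding. `attnstates` implements three ways of turning an RT series from
a Stop-Signal Task (SST) into a per-trial index of attentional state, and
the regression machinery that relates each index to BOLD signal:

* **VTC** (variance time course): within-run z-scores of RT, absolute
  value, Gaussian-smoothed. High values mean *deviant* responding in either
  direction.
* **Smoothed z-score**: the same z-scores, signed, Gaussian-smoothed. High
  values mean *slow* responding, low values fast responding.
* **Two-state Gaussian HMM**: the posterior probability, per trial, of
  being in the slower-RT latent state, estimated by Baum-Welch. Unlike the
  first two, a single deviant trial need not change the inferred state.

Because the pediatric neuroimaging data these methods were designed for is
access-controlled, the package is organized around a synthetic-data module
that generates the full study design — SST behavior from a hidden two-state
attentional process, and parcellated BOLD with known coupling to any of the
model series — so that every downstream stage is testable end to end.

## The behavioral simulator

The SST design is fixed by `sst_design()`: 2 runs of 180 trials, 30 stop
trials per run (16.6%), a 1,000 ms response window, and a uniform
700–2,000 ms inter-trial jitter. The stop-signal delay (SSD) starts at
50 ms and moves ±50 ms after every stop trial (up after successful
inhibition, down after a failure), clipped to [0, 900] ms. The floor is
physically forced; the ceiling keeps the stop signal inside the response
window — the task description fixes only the start and step, so the bounds
are package choices, exposed in the design object.

`simulate_subject()` draws behavior from a two-state hidden Markov chain
(`attn_gen_params()`): per-state Gaussian go-RTs truncated below at 1 ms,
per-state omission probabilities, and a go-error probability that is a
U-shaped function of RT (default: error-prone below 450 ms and above
1,200 ms). Stop-trial outcomes follow the standard independent-race
account: a response escapes iff the go finisher beats `SSD + SSRT`, with a
fixed stop-signal reaction time (default 250 ms). The staircase and the
hidden chain both persist across runs, since the task keeps tracking the
same child. Stop trials are placed uniformly at random, never first in a
run; the source task does not specify an ordering.

Default generator values (fast state 450 ± 80 ms, slow state 650 ± 140 ms,
stay probabilities 0.90/0.85, omissions 2%/10%) were chosen once as
plausible child SST behavior: they produce ~75–85% go accuracy, ~20%
interpolated trials, and a right-skewed RT distribution. The staircase
equilibrium is a property of the design, not the generator: over 10,000
stop trials against a stationary RT distribution the success rate settles
at 50% (`simulate_stop_staircase()` demonstrates this; the package's
acceptance script recomputes it).

What the simulator does *not* emulate: scanner drift and physiological
noise (BOLD noise is white, plus optional leakage of the global nuisance
series), volumetric head motion, proactive slowing near stop trials, and
RT autocorrelation beyond what the two-state chain induces. Tests that
pass on this generator therefore certify the *pipeline*, not the realism
of any particular parameter estimate on real data.

## RT series preparation

`extract_rt_series()` applies the validity rule: usable RTs are go trials
with RT > 150 ms, *including* incorrect responses and responses landing
after the response window. Stop trials (all of them, regardless of
outcome), omissions, and ≤150 ms responses become gaps.
`zscore_run()` standardizes within run using the mean and SD of valid
trials only — computed *before* interpolation, because interpolated values
are functions of the valid z-scores and would otherwise shrink the scale.
The population SD (divisor *n*) is the default; either convention is
defensible and a switch is provided. `interpolate_invalid()` fills gaps
linearly between the nearest valid neighbors on the trial-index grid (the
VTC lineage interpolates across trial positions; a time-grid switch
exists), and run-edge gaps take the nearest valid value — the source
methods do not state an edge rule, so this one is flagged here as a
package decision. `gaussian_smooth_series()` smooths over *real onset
seconds* with σ = FWHM/√(8 ln 2) and renormalizes the truncated kernel at
run edges, so edge trials are averaged, not attenuated; FWHM 0 is the
identity.

`qc_subject()` applies the retention rules: pooled go accuracy ≥ 66% and
stop-success probability in [25%, 75%].

## The three models

`compute_vtc()` and `compute_zscore_model()` smooth per run at 7.2 s FWHM
by default. `fit_gaussian_hmm()` is a from-scratch Baum-Welch
implementation with a scaled forward-backward pass: random restarts
(default 10) initialize state means at random data quantiles; emission
variances are floored at 1e-4 to prevent collapse; EM stops when the
log-likelihood improves by < 1e-4 or at 500 iterations, and the best
restart by final log-likelihood wins. The log-likelihood trace is
monotone, posteriors row-normalize to 1, and states are relabeled so state
1 is always the longer-RT state — the returned probability series
therefore correlates positively with RT. The continuous series is the
forward-backward posterior (the only construct that yields a probability
per trial); the Viterbi path is exposed separately. No smoothing is
applied to the HMM series. Runs are concatenated per subject before
fitting (a per-run switch exists); whether the original analysis used raw
ms or z-units is not recoverable, so the fit accepts either — all package
defaults operate on the z-scored, interpolated series.

`accuracy_by_series_bin()` reproduces the accuracy-by-model-value
analysis: per subject, correct-go accuracy within bins of the series
value. Bin edges are caller-supplied; no canonical numeric edges exist.

## BOLD regression

The parcel-level path mirrors the voxelwise pipeline:
`preprocess_bold()` (drop 8 initial frames, scale each series to mean
100 — both conventional, both configurable), `build_confound_matrix()`
(6 motion + 6 first differences + 6 squares + WM/CSF/global = 21
columns), `regress_nuisance()` (OLS projection, intercept always
included), `build_am_regressor()` (impulses at trial onsets with
mean-centered series amplitudes, convolved with a Gaussian HRF — peak
delay 5 s, FWHM 5 s, support 16 s; the kernel family is given but its
parameters are not recoverable, so these are package defaults),
`fit_am_glm()` (per-parcel OLS), `combine_runs_fixed_effects()`
(inverse-variance weighting), and `group_level_glm()` (intercept test of
subject betas, optional centered covariates, t mapped to z through the
normal quantile of the t CDF, capped at ±40 to keep degenerate units
finite). Mean-centering the AM amplitudes per run makes the regressor
carry trial-to-trial modulation rather than the mean evoked response.

Note that residualizing and then fitting the AM regressor is *not*
identical to a joint GLM unless the AM regressor is orthogonalized against
the confounds; the two-step procedure attenuates betas by the shared
variance (visible in the package's own recovery tests, where slow
confounds absorb part of a slow regressor while leaving the coupling
*pattern* intact).

The single-trial path (`build_trial_design()`, one boxcar per trial with
duration = RT convolved with the canonical double-gamma HRF on a 16×
microtime grid; `estimate_trial_betas()`, least-squares-all) feeds
`subject_rt_bold_correlation()` (per-parcel Pearson r over go trials) and
`effect_size_table()` (per-parcel regression of r on centered age + sex;
Cohen's d = intercept / residual SD, with a t/√n switch). Trials without
an RT get a duration by mapping the interpolated z value back to ms
through the run mean/SD. Trials whose regressor lies entirely inside the
dropped initial frames are inestimable and return NA; designs with more
trials than frames fall back to ridge and are flagged.

## Map comparison

`threshold_map()`, `dice_score()` and `network_coverage()` are direct
implementations. `spatial_null_correlation()` tests map-to-map
correspondence against surrogates of the first map: plain value shuffles,
or variogram-matching surrogates (`variogram_surrogates()`) that smooth a
permuted copy over parcel-centroid distances and rank-remap the original
values onto the smoothed field — preserving the value multiset while
approximating the spatial autocorrelation. The smoothing bandwidth and a
noise-mixing fraction are selected on pilot permutations by minimizing the
squared mismatch of the surrogate's empirical variogram; pure smoothing
over-smooths clustered centroids, and the noise blend is what lets the
surrogate match the short-range variogram. The default is 10,000
permutations and the two-sided add-one p-value,
p = (1 + #{|r⋆| ≥ |r|}) / (1 + n_perm). Variogram matching was chosen
over sphere-rotation nulls because the package's native space is parcel
centroids, not a sphere; the surrogate family is configuration, not a
fidelity claim. `synthetic_parcellation()` supplies a 333-parcel /
13-network table with synthetic clustered coordinates for testing; real
parcellation tables with the same columns drop in anywhere it is used.

## What the tests demonstrate

The suite runs entirely on generated data at desk scale (problem sizes
chosen to exercise each property, stated in the tests themselves): single
subjects for transform oracles; 50 seeds × 360 trials for HMM parameter
recovery (median error ~0.03 on means, ~0.02 on stay probabilities,
comfortably inside the ±0.15 / ±0.1 bands); 10,000 stop trials for the
staircase equilibrium; and a 20-subject cohort with a (+, 0, −) network
coupling pattern for end-to-end sign recovery. For the map-overlap
ordering, the cohort uses a variance-asymmetric generator (fast state
450 ± 150 ms, slow state 650 ± 60 ms): with a mean-shift-only process the
smoothed |z| series is strongly collinear with the smoothed z series
(RT skew), and all maps coincide; giving the fast state the larger
variance decorrelates VTC from the z-score series (r ≈ −0.3) while the
HMM series stays nearly collinear with it (r ≈ 0.9) — under that
construction Dice(z-score, HMM) exceeds Dice(VTC, z-score) decisively,
the qualitative structure reported on real data. The published Dice and
map-correlation magnitudes themselves depend on the access-controlled
cohort of ~8,000 children and are not reproducible here, by design.

## Known limitations

* The HMM assumes exactly two Gaussian states; a three-state variant is
  out of scope.
* The forward BOLD model shares one HRF across parcels and subjects, and
  noise is temporally white.
* Variogram surrogates approximate, never exactly match, the empirical
  variogram; with very few parcels the approximation is coarse.
* Cohen's d from the correlation regression uses one of two plausible
  definitions (intercept/residual-SD); the alternative is a switch, and
  the two differ at small n.
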