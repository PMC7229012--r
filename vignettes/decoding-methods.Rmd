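---
title: "Decoding outcome representations during approach-avoidance deliberation"
author: "delibdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding outcome representations during approach-avoidance deliberation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

During risky decisions, the brain may transiently represent the possible
outcomes of the action under consideration. `delibdecode` implements a
complete analysis chain for testing this idea with time-resolved multivariate
decoding of MEG sensor data collected in an approach-avoidance foraging game:
a player can leave a safe position to collect a token (positive outcome, P)
at the risk of being caught by a predator (negative outcome, N). Classifiers
trained on outcome-locked sensor patterns are applied to the pre-action
deliberation period to read out, bin by bin, which outcome is being
represented, and the temporal and condition structure of these decoded
probabilities is tested against permuted-classifier null ensembles.

Because raw human MEG recordings for this paradigm are not publicly
deposited, the package ships a first-class synthetic generator that emulates
the task and the sensor data with known ground truth. Every stage of the
analysis is validated against that ground truth.

## The task generative model

`simulate_task()` renders one session: 576 trials (36 practice trials plus
five blocks of 108), a balanced 3 x 6 grid of loss probability
(low/medium/high) by loss magnitude (0-5 tokens). Token appearance delay,
token lifetime and the inter-trial interval are `min(cap, Gamma(k = 2,
theta = 1))` seconds (caps 6, 6 and 4 s), giving 2-s mean event timings.
While the player is outside the safe position, the predator wakes
independently in every 20-ms bin with probability 0.02, 0.04 or 0.06
depending on the predator level; `catch_probability()` gives the closed form
`1 - (1 - p)^(exposure / 20 ms)`, i.e. roughly 0.1, 0.2 and 0.3 per 100 ms
of exposure.

The behavioural policy (`behaviour_policy()`) is a modelling device, not an
empirical claim: approach probability is logistic in loss probability level,
loss magnitude and their product; approach latency is log-normal; exposure
outside the safe position is gamma-distributed. Defaults were fixed once so
that a simulated participant resembles the reported behaviour of real ones —
an approach rate near 0.66 of the 540 analysed trials (reported training-set
sizes average 374) and an expected catch rate near 0.15, hence a P:N outcome
ratio near 5.6:1. On approach trials the exposure clock runs to completion
and a catch at any bin gives N; the token's own timing then distinguishes P
from the rare neutral outcome F (token vanished before reach).

## The sensor generative model

`simulate_recording()` renders a trial table into a channels x samples array
at 100 Hz (600 Hz exists to exercise the filtering path):

* **Outcome-evoked patterns.** Two unit-norm spatial patterns, one per
  outcome, are projected with a Gaussian kernel (FWHM 50 ms) peaking 310 ms
  after outcome onset. Each pattern occupies 20 randomly chosen channels and
  the two supports are disjoint (hence orthogonal patterns). Sparsity
  matters: a unit-norm pattern spread evenly over all 275 channels puts
  every per-channel likelihood gradient below the default L1 penalty, and
  the lasso would return the empty model no matter how discriminable the
  pattern is as a whole. Focal support mimics the topography of real evoked
  fields and keeps the penalty meaningful.
* **Amplitudes.** Channel noise is unit-variance white Gaussian (an AR(1)
  option exists for robustness checks). The evoked amplitude default (1.8)
  was calibrated once so that the per-bin classifier's cross-validated peak
  balanced accuracy lands near the reported 0.70 at a full session's
  training-set size; the deliberation amplitude (1.5, reduced relative to
  the evoked response) was calibrated so that the decoded deliberation
  dynamics actually exhibit the structure the analysis is designed to
  detect — short-lag autocorrelation above the permuted-classifier null,
  dwell distributions shifted long, transition counts below the null
  ensemble. These two constants are the generator's only tuned quantities
  and both are anchored to published summary statistics, not to any test
  threshold.
* **Deliberation schedule.** From trial start until the movement (approach)
  or token offset (avoidance), the recording alternates between the two
  patterns following a renewal process: dwell durations are uniform on
  40-150 ms, and at each renewal the state is an independent Bernoulli draw
  whose P-probability is logistic in `-(loss magnitude - 2.5)` and in the
  upcoming choice. The true dwell-generating process of human participants
  is unknown; this renewal model is an explicit assumption of the generator,
  and adjacent dwells may repeat a state (the Bernoulli-per-renewal reading;
  the per-dwell state frequencies, not strict alternation, are the tested
  property).
* **Artifacts.** Eyeblinks occur at Poisson times (0.15/s), adding a 100-ms
  FWHM bump with amplitude 5 on a fixed channel subset (by default the first
  half of the array). Ground truth records the schedule, blink times and
  patterns so every downstream stage can be validated exactly.

Event-locked kernels are snapped to the sample grid, so with zero noise the
peak sample carries exactly `amplitude x pattern` — the machine-precision
composition property the unit tests assert.

## Preprocessing and epoching

`preprocess_continuous()` is the identity at 100 Hz; at 600 Hz it applies a
zero-phase 0.5-Hz high-pass (4th-order Butterworth), a 48-52-Hz band-stop
for mains noise, and decimation to 100 Hz. `select_channels()` scores each
channel by the mean squared amplitude of its blink-locked average (0-400 ms
after each blink annotation) and keeps the 135 cleanest channels, ties by
index. This average-power score is our stand-in for an external blink
detector; it is exact on synthetic data, where ground-truth blinks are
known, and the function is a single swappable surface.

`extract_epochs()` produces the three deliberation/outcome epoch kinds with
half-open 10-ms bins (bin `t` covers `[10t, 10t + 10)` ms, no baseline
correction): outcome epochs 0-750 ms (75 bins) locked to P/N onsets only;
trial-start epochs 0-1500 ms, dropped when the token appeared within
1500 ms or a movement fell inside the window; token epochs 0-300 ms,
dropped when the token vanished or a movement occurred before 300 ms.
Practice trials are never epoched. `extract_baseline()` draws 100 single-bin
exemplars from the second preceding trial starts, only where the preceding
inter-trial interval exceeded 2000 ms.

Under the default gamma timings a large fraction of trial-start epochs is
structurally excluded (the token often appears within 1500 ms); this is a
property of the paradigm, not an artifact filter. Among approach trials the
outcome epochs retain well over 90% per condition cell.

## Outcome classifiers

`train_l1_logistic()` minimises the mean logistic negative log-likelihood
plus `lambda * ||w||_1` with an unpenalised intercept (fitted via glmnet
without standardisation; channels share a physical scale). Performance is
always summarised as balanced accuracy, `(TP/P + TN/N) / 2`, whose chance
level is 0.5 at any class imbalance. The pipeline mirrors the original
design: per-bin accuracy curves at a fixed `lambda = 0.025`
(`accuracy_timecourse()`, stratified 5-fold CV with pooled held-out
predictions), peak-bin selection on the group-mean curve, then a second,
independent cross-validation over a 20-point log-spaced grid on `[1e-4, 1]`
to free the penalty per participant (`select_peak_and_lambda()`; ties go to
the larger, sparser penalty). `build_classifier_suite()` trains the three
contrasts (P vs N, P vs baseline, N vs baseline) at the selected bin and
penalty plus 100 label-permuted classifiers per contrast.
`cross_classification()` holds out one condition level at a time (3 + 6 = 9
classifiers per participant) and the group test is a one-sided Wilcoxon
signed-rank of held-out accuracies against 0.5. `per_condition_timecourses()`
summarises each loss-probability level by its baseline-to-peak accuracy,
where "baseline" is the mean accuracy over the first 100 ms after outcome
onset — a convention this package declares explicitly, since the quantity's
reference window is otherwise underspecified.

The number of folds (5) and the penalty grid are package conventions; the
classification threshold is 0.5 on the sigmoid probability.

## Decoding dynamics

`decode()` maps each deliberation bin through the classifier's sigmoid.
`autocorrelation_curve()` computes per-trial, trial-demeaned biased-ACF
values at lags up to 500 ms and averages over trials; a pooled
(variance-weighted) estimator is available, with per-trial weighting as the
default.
`cluster_permutation_test()` converts each lag's two-sided exceedance under
the 100 permuted-classifier ACFs into `LL = -ln((r + 1) / (n + 1))` — the
add-one correction keeps LL finite at 100 permutations — forms clusters as
runs of `LL > 3` with a common sign ("more extreme" means farther from the
null mean in absolute deviation), and compares each cluster mass with the
95th percentile of leave-one-out null maximal masses.

`map_states()` collapses probabilities to most-likely outcomes with the
participant-specific threshold `p_chance` (training-set P proportion; ties
to N by the strict-inequality rule), yielding dwell epochs and transition
counts. `dwell_transition_tests()` runs the two-sample Kolmogorov-Smirnov
test on pooled dwell durations against the permuted ensemble and reports the
lower-tail transition p-value as `r / n`, printed as `< 1/n` when no
permuted analysis shows fewer transitions.

## Condition effects

`fit_lme_timecourse()` transforms decoded probabilities with the inverse
sigmoid (clip margin `1e-6`) and fits, per bin, a linear mixed model with
the full categorical factorial of loss probability, loss magnitude and
choice (treatment coding, references low/0/avoid) and a random per-subject
intercept, by REML. Fixed-effect F values are the sequential ANOVA
statistics of the fitted model, and p-values use the conservative
denominator `df = N - K`, where `K` counts all fixed coefficients plus the
subject intercepts.

`cluster_correct_timecourse()` forms clusters of bins with uncorrected
`p < 0.05` (mass = summed F) and builds the null by permuting, within each
participant, the assignment of trials to their full label tuples — one
common permutation across bins, preserving the null's temporal structure.
Because permuting the whole tuple is equivalent to permuting the response
within participant with the design fixed, each null F time course is
recomputed by generalised least squares on data whitened with that bin's
REML variance components (`V = I + theta^2 ZZ'` per subject block, in
closed form); at the identity permutation this reproduces the mixed-model
ANOVA F exactly, which the test suite asserts, and it avoids re-running the
REML optimiser for every permutation. Singular bins (zero subject variance)
are flagged and excluded from cluster formation.

`behaviour_lme()` fits the two behavioural models — a logistic mixed model
of approach and a linear mixed model of approach latency on approach trials,
both with the loss probability x magnitude factorial and a subject
intercept — reporting sequential ANOVA F for the latency model and per-term
Wald F for the logistic model, both on `df = N - K`.

## Numerical and design choices

* Tie-breaks: channel selection by index; `p(P) = p_chance` maps to N;
  equal CV accuracy prefers the larger penalty.
* glmnet is run at `thresh = 1e-10` on a short decreasing lambda path ending
  at the target, without standardisation; a single-channel design is padded
  with a zero column (glmnet requires two) whose weight is discarded.
* The whitening constant per subject block of size `m` is
  `c = ((1 + theta^2 m)^{-1/2} - 1) / m`, giving `W = I + cJ` with
  `W V0 W' = I`.
* Degenerate inputs raise informative errors rather than propagating: single
  class labels, zero-variance trials, `p_chance` in {0, 1}, all-short ITIs,
  null ensembles under 20 members, non-positive `df`.
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; identical seeds give bit-identical output.

## What the synthetic tests do and do not show

The generator reproduces the statistical skeleton the analysis assumes —
sparse focal patterns, a fixed evoked latency, renewal dwell structure,
condition-dependent biases, Poisson blinks — but not real MEG physics: no
head geometry or forward model, no 1/f spectra or oscillations, no sensor
correlations beyond the planted patterns, no learning or sequential
dependence in behaviour. Passing tests therefore certify that the pipeline
recovers what it claims to recover when its assumptions hold, and that its
null-calibrated tests are honest under the generator's nulls; they cannot
certify sensitivity or specificity on real recordings. Reported empirical
effect sizes (e.g. the published mixed-model F values) depend on the
unavailable human data and are deliberately out of scope.

Test and acceptance runs use reduced problem sizes — sessions of 324 trials,
arrays of 16-64 channels (275 for the channel-selection check), groups of
5-21 simulated subjects, 100-200 permutations — chosen so the full suite
runs on a laptop; every procedure is nonetheless executed exactly as at
full scale.
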