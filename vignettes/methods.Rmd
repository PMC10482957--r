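---
title: "Models, parameters and design choices in pushpull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in pushpull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models the package implements, the parameters
that matter and their defaults, what the synthetic generators emulate (and
what they deliberately do not), and the numerical and design choices made
where the methods left room for interpretation.

## The task and its simulator

The task is a head-fixed two-alternative lever choice under probabilistic
reward. One action per block is "correct" and rewarded with probability
`p_reward_correct = 0.70`; the other is rewarded with `p_reward_incorrect
= 0.10`. A block reverses once it contains at least `switch_min_correct =
30` correct choices **and** the correct rate over the last `switch_window =
10` trials strictly exceeds `switch_rate_threshold = 0.79`. The strict
comparison is a deliberate reading: with ten trials the effective
requirement is at least 8/10 = 80% correct, which matches the intended
behavioral difficulty; a non-strict reading would admit 79/100-style edge
cases only for non-default windows. Within a trial, events follow hold
(0.4 s ± 0.1 s uniform jitter) → Go cue → movement onset → outcome tone →
reward 0.3 s after the tone on rewarded trials. Reaction and movement times
are drawn from log-normal distributions with medians of 218 and 143 ms;
these are placeholders for realistic event spacing, not claims about any
animal's kinematics. The inter-trial interval defaults to 4 s so that the
2–3 s pre-Go baseline window used by the firing-rate analyses contains no
task events.

The simulated chooser is a logistic policy: the log-odds of pushing are a
weighted sum over the previous `n_past = 8` trials of signed outcome
regressors. The coding — +1 for a rewarded push, −1 for a rewarded pull in
the reward regressor, and the same for unrewarded trials in the no-reward
regressor — is chosen so that a positive reward weight literally means
"repeat the rewarded choice" and a negative no-reward weight means "leave
the unrewarded choice". Histories shorter than `n_past` contribute zero
regressors; no pre-session pseudo-trials are invented. The shipped
`default_policy()` uses geometrically decaying weights (reward 2.5·0.6^j,
no-reward −1.2·0.6^j). These values were chosen once so that the agent
masters the task the way trained animals do — blocks complete in roughly
30–50 trials — and are not fitted to anything.

## Behavioral statistics

**Reward rate.** The trailing reward rate at trial *i* is the number of
rewards over trials *i−5 … i−1* divided by five, a value on the grid
{0, 0.2, …, 1}. The current trial is excluded; the first five trials of a
session are undefined and excluded from every reward-rate analysis.

**Choice regression.** `fit_choice_regression()` is a maximum-likelihood
logistic fit (IRLS via `glm`) of the push choice on the signed regressors,
excluding the first `n_past` trials. Perfect or quasi-separation (a
deterministic policy, or a session too short to constrain the weights) is
detected from the fitter's own diagnostics plus coefficient/standard-error
magnitudes and reported as a `separation` flag rather than returned as a
silently divergent fit.

**Movement-onset detection.** The detector is a one-sided CUSUM on absolute
deviations from the hold-period mean, reset at the Go cue:
`S_t = max(0, S_{t−1} + |x_t − μ| − k_ref·σ)`, with onset at the first
sample where `S_t > 3σ`. The threshold of 3 baseline SDs is the stated
criterion; the reference offset `k_ref` is a free constant of the CUSUM
family. With the textbook `k_ref = 1`, Gaussian noise alone drifts the sum
upward (E|x−μ| ≈ 0.8σ) and the false-alarm rate over a few hundred samples
is above 80%, which would make the detector useless on real hold periods.
The default is therefore `k_ref = 2`: deviations must exceed two baseline
SDs before they accumulate, the false-alarm rate on pure noise drops to
about 0.2% (the package asserts ≤ 1% as a property test), and a genuine
movement — many SDs of sustained deviation — still crosses the bound within
a sample or two of onset. Both constants are exposed as arguments.

## Photometry processing

The chain is detrend → isosbestic correction → ΔF/F → downsample → z-score.

Detrending fits `a·e^(−t/τ) + b·t + c` per channel by least squares. The
time constant is profiled: for fixed τ the model is linear, so the fit is a
one-dimensional search over log-τ with the linear coefficients solved
exactly at each step. This is numerically robust where a joint nonlinear
fit would need good starting values; a degenerate exponential (collinear
with the linear term, e.g. constant input) falls back to a linear-only fit
and is flagged.

`remove_decay()` returns the zero-mean residual. For the ratio step the
pipeline restores each channel's DC level (the mean of its fitted decay
curve) before regressing the isosbestic channel onto the signal channel:
dividing by a zero-mean residual would be meaningless, while dividing by
the restored fluorescence level makes ΔF/F a fractional change relative to
the channel's baseline brightness, which is what the quantity means. The
405→470 mapping is ordinary least squares over the whole session — the
simplest reading of "a linear fit was applied"; a robust variant was
considered and rejected as an unforced complication, since the generators
and the correction only require the shared slow components to be matched.

Downsampling from 1 kHz to 40 Hz is a block mean over 25 samples. No
anti-alias filter is applied: the dopamine-sensor kernel (rise ~50 ms,
decay ~400 ms) has negligible power near the 20 Hz Nyquist limit of the
analysis rate. z-scoring uses the whole-session mean and SD of the
downsampled ΔF/F; a pre-event-baseline z-score was the alternative reading,
but the whole-session convention is the one that makes traces comparable
across sessions and animals, which is the stated purpose of the
normalisation.

## Optogenetic identification

**Collision test.** The antidromic response window is the widest contiguous
post-stimulus interval (within 25 ms) where the averaged control and test
traces dissociate by more than 3 pre-stimulus noise SDs for at least
0.2 ms. Two practical amendments, both exposed as arguments: sub-threshold
gaps up to 0.25 ms are bridged, so the negative and positive lobes of one
biphasic spike count as a single dissociation rather than two; and the
search starts 2 ms after light onset, because the test condition by
construction contains the triggering spontaneous spike around the stimulus
and its afterwave would otherwise masquerade as the "widest" dissociation.
Striatonigral antidromic latencies are an order of magnitude longer than
this dead time.

The spike/no-spike decision uses a threshold on the in-window minimum,
chosen to maximise Youden's J over an ROC built from control in-window
minima (spike class) against minima of pre-stimulus window-width segments
of the same trials (noise class; the negative class is not stated in the
source method and pre-stimulus noise is the natural choice). Candidate
thresholds are midpoints of the pooled sorted values; ties take the middle
tied candidate; identical distributions return the pooled median, flagged
degenerate. Counts are tested with a 2×2 chi-square without continuity
correction; if any expected cell count is below 5 the test falls back to
Fisher's exact test and the result is flagged. Latency is the median and
jitter the Q3−Q1 interquartile range of in-window spike peak times, with
quartiles linearly interpolated between order statistics (R type 7) to fix
the quartile convention reproducibly. A unit passes when control spike
probability exceeds 50%, the test probability is below half of it, the
count test gives p < 0.05, latency < 25 ms, and jitter < 0.5 ms. Fewer than
10 trials per condition flags the result underpowered.

**Direct tagging.** Light-evoked units pass on latency (below 8 ms for
striatonigral stimulation next to the recording site, 10 ms for
striatopallidal stimulation at the pallidal target), jitter below 1 ms, and
a Pearson correlation above 0.9 between the mean evoked and spontaneous
four-channel waveforms within 0.125 ms around the spike peak. The peak is
located on the largest-amplitude channel of the spontaneous waveform. The
paired-pulse frequency-following criterion is provided as an advisory
helper (`frequency_following_test()`), and the "energy" of an evoked
response is implemented as the plain sum of squared waveform samples for
display purposes only, since no standard definition exists.

## Cell-type classification

Nigral units are split at a spike duration of 800 µs (onset to first
positive peak): shorter spikes are putative GABAergic cells, 800 µs and
above putative dopamine neurons. Recording positions split at 1.8 mm
lateral from bregma, with the boundary assigned to the lateral division.

Striatal units are clustered by k-means (k = 3, 50 restarts under a fixed
seed schedule, best inertia kept) on z-scored ongoing rate, spike width and
ISI CV — standardisation is necessary because Hz, µs and a dimensionless CV
are incommensurable. Clusters are named post hoc by centroid physiology:
the narrowest-waveform cluster is FSI, the higher-rate of the remaining two
is TAN, the last SPN. Mean silhouette width summarises separation. Where a
spike width must be extracted from a multi-channel waveform upstream, the
convention is the largest-amplitude channel.

## Peri-event statistics

PETHs use 20 ms bins smoothed by a 20 ms window sliding in 10 ms steps,
implemented as overlapping 20 ms windows evaluated every 10 ms (equivalent
to a two-bin moving average on a 10 ms grid). Per-trial window rates are
raw counts divided by window width — not smoothed PETH values — over the
Go (0–0.3 s), movement (0–0.3 s) and outcome (0–0.5 s) windows, z-scored
against the per-trial baseline rates from 2–3 s before the Go cue. Units
with zero baseline SD are excluded from z-based analyses with a logged
reason. Task-relatedness is a two-sided Wilcoxon rank-sum test of each
window against baseline at α = 0.05 (the conventional default; the level
is an argument). Units enter reward-rate analyses only for their preferred
action, defined by at least a 5% relative difference in mean
movement-window rate between push and pull trials.

Per-unit reward-rate correlations are Pearson r with two-sided p; no
per-unit multiple-testing correction is applied because the population-level
claim rests on the distribution of r, tested against zero with a one-sample
Wilcoxon signed-rank test. The source method names a "rank-sum" test
between an r distribution and 0; a two-sample test against a constant is
degenerate, so the one-sample signed-rank reading is used deliberately.
Pairs of correlations are compared with the Fisher z statistic
`(atanh r₁ − atanh r₂) / √(1/(n₁−3) + 1/(n₂−3))` with Bonferroni-adjusted
two-sided normal p-values, capped at 1.

## Synthetic ground truth

The generators are deterministic functions of (specification, seed); all
randomness in the pipeline flows from one global seed via fixed per-stage
offsets.

**Spike trains** are inhomogeneous Poisson, sampled by thinning: baseline
plus peak-normalised double-exponential kernels `(1 − e^(−t/rise))·e^(−t/decay)`
at the Go cue, movement onset, and rewarded/unrewarded outcome tones. Each
kernel's gain is multiplied by `1 + coupling × reward_rate`, which is the
mechanism under test in the reward-expectation analyses: positive couplings
make event responses grow with recent reward history. Poisson spiking has
no refractory period by default; an optional dead time (e.g. 2 ms) produces
the sub-Poisson ISI regularity that tonically active interneurons show.

**Photometry traces** are a baseline (100 a.u.) with exponential + linear
bleaching (30 a.u. amplitude, τ = 300 s, −0.005 a.u./s), event-locked
transients, an optional slow artifact shared between channels, and white
noise; the isosbestic channel carries the scaled bleaching and shared
artifact but no transients. A transient's absolute amplitude is its ΔF/F
amplitude times the *instantaneous* baseline `f0 + bleach(t)`: the
fluorophore pool that bleaches is the same pool that reports dopamine, so
the fractional change, not the absolute change, is the conserved quantity.
This choice is what makes the end-to-end recovery test meaningful — a
fixed-amplitude transient on a bleaching baseline would have a
time-varying true ΔF/F and no single correct answer.

**Collision ensembles** idealise the collision physics: in test trials
(stimulation triggered by a spontaneous spike) the evoked spike is deleted
with probability `collision_fidelity` (1 by default); control trials carry
the evoked spike at the conduction latency with Gaussian jitter.
Spontaneous spikes occur at a configurable rate, excluded from the
conduction window before the stimulus in control trials, which is exactly
the experimental selection that defines the control set.

**Unit features** are drawn from class-typical distributions (SPN: ~0.9 Hz,
~650 µs, CV ~1.5; TAN: ~5.5 Hz, ~480 µs, CV ~0.7; FSI: ~14 Hz, ~210 µs,
CV ~1.05) with default class proportions 716:1224:62. Dispersions were set
once so that the three clusters are clearly separable yet overlap
moderately — the resulting mean silhouette (~0.6–0.7) brackets what real
striatal populations show — and then frozen.

What the generators do **not** emulate: biophysical membrane dynamics,
spike waveform variability and sorting errors, hemodynamic or
motion-artifact structure beyond a shared slow component, licking and
orofacial behavior, or learning across sessions. A green closure test
therefore establishes that the analysis chain recovers what the stated
generative model planted — it does not establish that the model captures
every property of real recordings.

## Degenerate inputs and numerical conventions

Times are seconds from session start (serialised at 1 µs precision);
sample indices are 1-based inside R, trial indices 0-based in serialised
logs; analysis windows are half-open `[start, end)`. Constant signals,
zero-variance baselines, identical ROC distributions, all-identical
features and underpowered ensembles are each flagged or excluded with a
reason, never silently propagated. Empty PETHs are valid (zero rate);
an absent antidromic dissociation is a non-identification, not an error.

## Known limitations

The choice regression reports per-session Wald standard errors; across-
session summaries (mean ± SD of coefficients) are a thin layer the user
composes. The collision test assumes negative-going spikes on at least one
channel, as extracellular somatic spikes are. The silhouette value of the
striatal clustering depends on the feature dispersions of the population at
hand and is reported, not asserted, by the pipeline. The simulator's
reaction- and movement-time distributions are placeholders; analyses that
depend on their fine structure (e.g. reaction-time correlations) are out of
scope.
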