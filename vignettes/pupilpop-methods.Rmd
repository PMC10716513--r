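---
title: "Methods: pupil-linked arousal and visual orienting in infant eye-tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupil-linked arousal and visual orienting in infant eye-tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

`pupilpop` analyses trial-level data from an infant audiovisual pop-out
experiment: on each trial the infant fixates a central attention grabber, an
auditory cue (a social or non-social sound at high or low volume, or
silence) plays, and after a short inter-stimulus interval (ISI, 80-400 ms) a
four-image array (face, man-made object, natural object, geometric shape)
appears for 3 s. Three trial-level measures carry the science:

* **phasic arousal** — task-evoked pupil dilation, the mean pupil size in
  the 2 s after the visual onset minus the mean in the 200 ms before the
  sound onset;
* **orienting speed** — the latency of the first gaze entry into any image
  area of interest (AOI) sustained for at least 100 ms;
* **social orienting** — a binary indicator of whether that first look
  landed on the face.

Inference is by random-intercept mixed models on the trial-level measures
(Gaussian for dilation and latency, binomial-logit for face selection),
with fixed effects tested by single-term-deletion likelihood-ratio tests.

## Experiment schedules

`generate_schedule()` builds one participant's 56-trial sequence. Trials
come in pairs that share sound and volume (the *repetition* condition);
pairs are arranged in two 28-trial blocks with the same sound sequence but
volumes exchanged, so each of the 12 sounds is heard at both volumes; each
block additionally contains two silent pairs, interleaved at positions
drawn once and shared by both blocks so that the sound sequences match.
Each of the 12 sounds thus contributes one low-volume and one high-volume
pair, giving 24 high- and 24 low-volume sound trials plus 8 silent trials.
Volume assignment within a block is balanced within content category
(3 high + 3 low per content); the design gives 12 trials in every
content-by-volume cell regardless of that choice, but the balanced split
keeps the two blocks individually interpretable.

Images are drawn from pools of 56 per category, each image used exactly
once. The four images sit at the corners of a cross-like array, midpoints
12 degrees horizontal and 6 degrees vertical from the screen centre; with
11-degree square AOIs the four regions are disjoint. Those two distances
admit either a corner or a cardinal arrangement; we use the corner layout
and expose the positions in `design_config()`, so the cardinal variant is a
configuration change, not a code change. Position assignment is a per-trial
random bijection of categories onto corners, rejected and redrawn (bounded
at 1000 draws) until no category repeats its position from the previous
trial; a valid derangement always exists for four positions, so exhausting
the bound indicates a bug rather than bad luck. The ISI is drawn uniformly
on [80, 400] ms.

## Signal preprocessing

Gaze and pupil channels follow separate chains, both built from the same
grouped vector primitives so a cohort is processed as one flat array.

**Gaze**: per-eye linear interpolation over gaps strictly shorter than
150 ms (gap duration measured from the last valid sample to the next valid
sample; leading/trailing gaps never filled), then the cyclopean average of
the available eyes, AOI coding against closed 11-degree squares, and
first-entry detection. An AOI entry is a maximal run of consecutive
in-AOI samples; run duration is sample count times the nominal period, a
run broken by a single missing sample is broken, and the first run of at
least 100 ms defines the latency (from visual onset to the run's first
sample). Missingness statistics use the raw series (before interpolation)
for the whole-trial missing fraction and the interpolated series for the
on-screen fraction during the visual presentation; screen bounds default to
±21.5° × ±12.5° (a 52 × 29.5 cm monitor at 65 cm).

**Pupil**: per-eye centred moving average over a 100 ms window (61 samples
at 600 Hz, endpoints included, truncated at trial edges, missing samples
stay missing); binocular combination by a dynamic-offset mean that
reconstructs a missing eye from the linearly interpolated left-right size
offset (nearest-edge extrapolated, with a flagged plain-mean fallback when
a trial has no binocular sample); validity recoding in three passes — the
absolute 1.5-9 mm range, then ±3 SD about the trial mean, then samples
where gaze was detected off-screen; interpolation over gaps shorter than
150 ms; and finally the half-open baseline [-200, 0) ms and response
[0, 2000) ms window means. The trial mean and SD for the ±3 SD pass are
computed once, after the range pass: iterated trimming is a different
(and stronger) rule than a single pass, and the single pass is the minimal
reading of the protocol. All windows are half-open to avoid double-counting
boundary samples.

## Trial screening and the analysis table

Five rejection criteria are always all evaluated: (1) central-area
occupancy at most 40% in the 500 ms before sound onset; (2) no central-area
sample in the 200 ms before visual onset; (3) missing/off-screen gaze in
the 500 ms after visual onset, or more than 25% missing/off-screen in the
following 500 ms; (4) no qualifying AOI entry; (5) latency below 200 ms or
above 1 s. The first clause of criterion 3 is ambiguous between "any bad
sample", "the entire window bad", and "more than 25% bad"; we default to
the strictest *any* reading — consistent with the clause's stated purpose
of tolerating late disengagement but not a corrupted first gaze shift — and
expose all three as `c3_mode`. The central attention-grabber area side
defaults to 6° (not specified by the protocol) and is configurable.
Participants contributing fewer than 70% valid trials are excluded; the
comparison is inclusive (exactly 70% is kept). Pupil measures are computed
for all gaze-valid trials, with baseline/response missing fractions carried
as covariates rather than used as extra rejection rules.

Standardised dilation (`dilation_z`) is a z-score across all analysed
trials by default; the reference population for standardisation is a
genuine free choice and `per_infant` is available in the configuration.

## The synthetic-data generator

`simulate_cohort()` emulates 600 Hz binocular recordings of the full
design with known injected truths, so that every downstream stage is
testable end to end. Defaults (all exposed in `sim_params()`):

* cohort 25 + 21 infants (5- and 10-month groups), one schedule each;
* baseline pupil 4.6 / 4.4 mm by age, infant random intercept SD 0.3 mm,
  per-trial tonic jitter SD 0.10 mm, within-trial linear drift slope SD
  0.02 mm/s, per-sample noise SD 0.05 mm, constant left-right offset
  0.2 mm;
* an Erlang dilation kernel `(t/(s*tau))^s * exp(s - t/tau)` with shape
  s = 12 and tau = 0.08 s, peaking 0.96 s after sound onset and back at
  baseline by ~2.5 s — fast enough that the 2 s response window captures
  essentially all kernel mass, which keeps the window mean nearly
  insensitive to the 100 ms smoothing filter. Amplitudes are calibrated so
  the expected measured dilation equals the nominal gain: high 0.09, low
  0.07, silent 0 mm, with additive per-trial amplitude noise (SD 0.05 mm)
  and an infant amplitude intercept (SD 0.02 mm). The amplitude noise is
  deliberately untruncated so condition means equal the nominal gains
  exactly; an occasional mildly negative amplitude reads as trial-level
  constriction.
* first-look latencies drawn truncated-lognormal on [0.2, 1.0] s with the
  location calibrated numerically so the truncated means equal 0.445 s
  (5 mo) and 0.355 s (10 mo) — an injected age effect of exactly
  −0.09 s — sdlog 0.25, infant location SD 0.08, plus configurable
  fractions outside the valid range (1.2% below, 0.5% above, the tail
  fractions observed for this paradigm) to exercise the latency criterion.
  The latency model accepts an ISI slope; it defaults to 0 so the marginal
  age effect equals the nominal value, and ISI-moderation analyses are
  exercised on models with directly injected interaction coefficients
  instead;
* face selection from a logistic model: intercept −0.62, age effect
  0.94 log-odds, 0.44 for high-volume first presentations, slope 0.09 on
  standardised dilation amplitude, infant intercept SD 0.4;
* binocular blinks as Poisson events (0.10 /s, duration 250 ± 80 ms),
  off-screen episodes (probability 0.05 per trial, 0.3-1.0 s), and a
  per-infant lognormal attrition multiplier (sdlog 0.5) on both rates, so
  some infants are fussier than others and the inclusion rule has work to
  do.

Ground truth records the drawn latency, the chosen target, and the
injected dilation amplitude *under the measurement definition*: the
amplitude times the difference of the response- and baseline-window means
of the sampled kernel after the protocol's 100 ms moving-average filter
(`measure_smooth_ms`). Defining truth through the declared measurement
operator is what makes exact noise-free round-trips meaningful; with the
filter disabled on both sides the truth reduces to the raw kernel window
mean, which also matches the closed-form incomplete-gamma expression in
`kernel_window_mean()`.

What the generator does **not** emulate: saccade kinematics (gaze jumps
instantaneously at the drawn latency), pupil foreshortening with gaze
angle, luminance effects (the protocol holds room luminance constant),
response carry-over between trials, and drifting calibration. Passing
recovery tests therefore demonstrates that the pipeline and models are
faithful to their definitions on data with this structure — not that the
estimates are robust to optical artifacts absent from the generator.

## Models

`fit_mixed()` fits random-intercept models by maximum likelihood (`lme4`,
`REML = FALSE`; binomial fits use the Laplace approximation by default
with adaptive Gauss-Hermite available via `nagq`). Factors are deviation
(sum-to-zero) coded by default; the coding is configurable, and the
likelihood-ratio test is invariant to it. `lrt_single_term()` refits
without one term on the identical complete-case rows and refuses to drop a
term participating in a retained interaction. `quadratic_test()` trims the
predictor to its [1st, 99th] percentile range by default before comparing
linear and quadratic fits — curvature estimates are notoriously
edge-sensitive, and the trim quantiles are exposed; the predictor is
centred first, which changes nothing about the quadratic coefficient but
conditions the optimisation. `marginal_contrasts()` evaluates estimated
marginal means as linear combinations of the fixed effects (covariates at
chosen values or sample means, other factors averaged with equal weights)
with delta-method standard errors; it reproduces `emmeans` reference-grid
results to numerical precision, and `emmeans` is kept as an independent
cross-check in the test suite rather than as the implementation.
`critical_f()` exposes the central-F quantile used in the sensitivity
power analysis of the repeated-measures design, e.g.
`critical_f(0.05, 55, 2420)` = 1.34.

Missing trial-level cells are handled by `impute_trials()`: chained
equations with a regression-tree learner (donor sampling from the terminal
leaf, as in CART-based MICE; predictive mean matching is the alternative),
5 burn-in iterations, columns visited in order of increasing missingness,
and independent chains per imputation. Pooling is by Rubin's rules —
within-imputation variance plus (1 + 1/m) times between-imputation
variance, with the classic degrees-of-freedom formula. The learner choice
and the pooling rule are package decisions; donor-based imputation keeps
imputed values inside the observed support, which matters for bounded
measures like dilation.

## Numerical choices and problem sizes

Strict inequalities: gaps are filled only when *shorter than* 150 ms;
pupil samples are recoded when *more than* 3 SD from the trial mean;
participants *below* 70% valid are excluded. Dwell qualification uses
`ceiling(0.1 * fs)` samples. Latency is reported on the seconds scale.
Degenerate inputs are values, not errors: an empty window yields a missing
mean with missing-fraction 1, absence of a qualifying AOI entry yields a
missing latency (criterion 4 handles it), and a trial with no binocular
pupil sample falls back to the plain mean and is flagged.

The test suite exercises the oracle comparisons on ≥1000 randomised
instances per operation, noise-free end-to-end fidelity on a 2-infant
cohort at the native 600 Hz (latency within one sample period, dilation
within 1e−6 mm), parameter recovery on 100 replicate cohorts of 46 infants
× 56 trials generated at 200 Hz (the inference targets are
rate-independent, and this keeps the suite tractable on one CPU), null
calibration of the LRT on 200 replicates, and inverted-U sign recovery on
60 replicates at the study's 46 × 56 size.

## Known limitations

The generator's effect structure is additive and correctly specified for
the fitted models, so recovery tests cannot detect misspecification bias;
the dynamic-offset reconstruction assumes the left-right offset varies
slowly across a gap; the ±3 SD recoding pass slightly clips genuinely
large peaked responses (a property of the protocol, shared by any
implementation of it); and Laplace-approximate binomial fits carry the
usual small attenuation for few clusters, which `nagq > 1` mitigates at
some cost.
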