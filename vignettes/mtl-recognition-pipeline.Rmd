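---
title: "Models and methods: simulated MTL recognition-memory sessions and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulated MTL recognition-memory sessions and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlmem)
```

This vignette documents the generative models, analysis procedures,
numerical conventions and design decisions behind `mtlmem`. It is the place
to look when a default value or a convention needs a justification.

## The task and the session model

A session of the new/old recognition task has two blocks. In the *encoding*
(learning) block the subject views 100 novel images drawn from 5 visual
categories and answers "is this an animal?" per image. In the *recognition*
block 100 images are shown — 50 repeats ("old", ground-truth label 0) and 50
unseen ("new", label 1) — and the subject answers "have you seen this image
before?" on a 6-point scale from 31 (new, confident) to 36 (old, confident).
The acquisition system emits an integer TTL marker at every behavioral
event, paired one-to-one with an experiment-ID stream labeling the block
(learning 80/83/88, recognition 81/84/89; the pair identifies one of three
task variants). All times in the package are seconds relative to the start
of the experiment; only the serialization layer owns the calendar
`session_start_time`, and it always writes the day as the first of the month
(the patient-privacy convention of human intracranial releases).

The in-memory container (`session_bundle`) mirrors one NWB session file:
trials table, units table with ragged spike times, electrode/device tables,
subject metadata, raw event/tag streams, and the stimuli. `validate_session()`
checks every structural invariant, including the TTL grammar
`55, (1, 2, 3, response, 6) x trials, 66`, and *returns* violations rather
than raising, so defective sessions can be inspected.

### Ragged spike-time storage

Spike times of all units are stored flat, with a cumulative end-index
vector: `index[i]` is the number of spikes belonging to units `1..i`.
Internally slicing is zero-based half-open — unit *i* owns positions
`(index[i-1], index[i]]` — which selects exactly the same elements as the
1-based inclusive `data(index(i-1)+1 : index(i))` idiom used by MATLAB
readers on the same index values. The index is therefore language-neutral,
and the round-trip `slice_ragged(build_ragged(L), i) == L[[i]]` is tested
property-style, including empty units and empty sessions.

## The synthetic-data generator

The generator exists so that every downstream stage — serialization,
parsing, behavior and neuron analysis — can be exercised end-to-end, with
known ground truth, without any external data. Its defaults are the study
conditions: 100 encoding + 100 recognition trials, 5 categories, 50/50
old/new, 6-level confidence. Where the task protocol does not fix a value,
the default is chosen once for realism and documented here.

### Behavior: equal-variance signal detection

On each recognition trial a memory strength is drawn from N(d′, 1) for old
items and N(0, 1) for new items and mapped through 5 strictly increasing
criteria onto the codes 31–36. Defaults:

* `d_prime = 0.9` — yields session AUCs near 0.73, typical of human
  performance on this task.
* `criteria = d′/2 + (-1.2, -0.55, 0, 0.55, 1.2)` — an unbiased observer
  whose criteria spread was chosen, by closed-form calculation over
  criteria placements, to maximize how much of the continuous-ROC area the
  6-level rating ROC retains.
* Encoding responses are correct with probability `p_animal_correct = 0.95`;
  reaction times are log-normal (median ≈ 0.7 s), truncated at `max_rt_s`.

**Quantization bias.** The trapezoid AUC of a 6-point rating ROC is a
Mann–Whitney statistic on the discretized ratings and is strictly below the
AUC of the underlying continuous strengths, `pnorm(d′/sqrt(2))`. At
d′ = 1.5 the continuous value is 0.8556 while the best achievable 6-level
value — attained within 0.0001 by the default criteria — is 0.8466. No
criteria placement can close this gap; tests that compare simulated AUCs to
the continuous closed form must therefore either tolerate a ~0.009 bias or
compare against the exact quantized oracle (`pnorm` over the criteria
bins), which is what the sharper unit tests do.

### Timing

Stimulus pacing is not part of the task specification; the generator uses
1.0 s stimulus, 0.5 s delay to the question screen, 0.5 s from response to
the end-of-trial marker, and a 1.0 s inter-trial interval, all
configurable. Equality of `response_time` and `delay2_time` is treated as
legal by the validator (the protocol does not forbid coincidence; strict
inequality is required only between stimulus onset and offset).

### Category balance and old-image choice

Exact balance — 20 encoding images per category, 10 old + 10 new per
category at recognition — is enforced by default. The task description does
not promise exact balance; it is enforced here because it maximizes the
power of the category ANOVA in tests, and it can be switched off
(`balanced_categories = FALSE`). The old subset is a seeded stratified
sample of the encoding images; recognition order is a seeded shuffle.

### Spike trains

Each unit is a piecewise-constant-rate Poisson process: rate `baseline_hz`
(default 5 Hz) everywhere, multiplied by `category_gain` in the response
window `[onset + 0.2 s, onset + 1.2 s)` of preferred-category trials (VS),
by `memory_gain` in preferred-condition recognition trials (MS), or both
(dual). Simulation is by superposition — a homogeneous baseline train plus
extra window-restricted trains at the excess rate — which is an exact
construction for piecewise-constant intensities. Refractoriness is imposed
by deleting any spike closer than 3 ms to the previously retained spike;
deletion (rather than hazard modulation) is simple, testable, and at 5 Hz
removes ~1.5% of spikes, leaving window-count Fano factors in [0.7, 1.3].
Setting a gain to 1 reproduces the untuned process exactly, seed for seed.

### Waveforms and quality metrics

Mean waveforms are a fixed biphasic template (difference of two Gaussians:
sharp negative deflection, broader positive rebound) scaled to a peak
amplitude drawn per unit from 50–150 µV, plus white noise (SD 3–8 µV), 256
samples at 100 kHz. SNR is defined as peak absolute amplitude over noise
SD. Isolation distance follows the standard Mahalanobis definition: with
cluster feature mean/covariance, the squared distance of the n-th closest
outside spike, n = cluster size; it is undefined (NA with a reason
attribute) when outside spikes are fewer than the cluster or the covariance
is singular. The generator computes it on small synthetic 3-D feature
clouds per unit, which is enough to carry realistic values through the
units table.

### What the generator does not emulate

Real images (stimuli are 16×16 category-patterned integer placeholders),
LFPs, electrode drift, firing-rate nonstationarity, bursting, correlated
noise across units, and behavioral lapses or sequential effects. Passing
tests therefore demonstrate the correctness of the pipeline's bookkeeping
and statistics under the stated models, not robustness of the screens to
every pathology of real recordings.

## Serialization

`write_session_nwb()` lays the session out exactly as the released human
single-neuron NWB files do: `acquisition/events` stores the TTL codes as
integer-parseable text (the MATLAB `num2str` dialect) with timestamps and a
`description` attribute carrying the code table; `intervals/trials` uses the
release column names (`new_old_labels_recog` as text `"0"`/`"1"`/`"NA"` —
learning trials need a placeholder — `stimCategory`, `stim_phase`); `units`
stores the ragged pair plus `waveform_mean_encoding`/`_recognition`
(samples × units, `sampling_rate` attribute 100000), `origClusterID`, `SNR`,
`IsolDist` and 0-based `electrodes` references. The reader is tolerant:
codes and numeric columns may be integer, double, or padded numeric text;
the stimuli group may be absent (stimulus ids become NA). Missing required
groups (`units`, `intervals/trials`, `acquisition/events`) raise a load
error naming the group. Write→read is tested as the identity on the bundle
(times within 1e-6 s) across randomized generator configs. Internal names
differ from file column names deliberately (e.g. `new_old_label` vs
`new_old_labels_recog`); the writer/reader own the mapping.

## Event parsing

`split_blocks()` partitions the streams by experiment ID after stripping
the 55/66 boundary markers (their absence is a validator warning, not a
parse failure — the tolerant-reader principle); mixed variant pairs are an
error. `parse_block_to_trials()` consumes each block in 5-marker chunks and
fails loudly, with the trial ordinal and expected-vs-found code, on any
grammar violation; every event must be consumed. Ground-truth labels are
not encoded in the TTL stream (they live in the trials table), so the
parser takes them as an ordered argument; when reading real files the
parser serves as a cross-check of the stored trials table. Blocks are
assumed contiguous (learning then recognition) — interleaving is an error,
not a supported layout.

## Behavioral analysis

ROC points are cumulative hit/false-alarm rates at thresholds 36 down to
31; the curve is anchored at (0,0) and the threshold-31 point is always
(1,1). The trapezoid AUC is algebraically identical to the tie-corrected
Mann–Whitney statistic, and the test suite asserts this equality to 1e-12
against an independent rank-based oracle.

The task description reports ROC asymmetry without defining its test; the
package's documented choice is the zROC slope: probit-transform the
interior points (both coordinates strictly inside (0,1); boundary points
are excluded because the probit diverges), fit least squares, and bootstrap
the trials (percentile CI, default 95%); "asymmetric" is reported when the
CI excludes 1. Under the equal-variance generator the slope converges to 1;
with old-item SD 1.25 it converges to 1/1.25 = 0.8. Fewer than two usable
interior points yields a flagged undefined result, not an error.

High- vs low-confidence accuracy uses the grouping high = {31, 36}
(the "confident" codes) by default — the split is not defined in the task
description, so it is exposed as a parameter — and reports raw accuracies;
the tests compare them across simulated sessions with a paired t-test.

## Single-neuron analysis

Firing rates are spike counts in the half-open window
`[onset + 0.2 s, onset + 1.2 s)` divided by its length; half-open bins
(≥ left, < right) prevent double counting at edges throughout (PSTH bins
included). The VS screen is a classical one-way F-test across the 5
categories on recognition-trial rates; it refuses to run with fewer than 5
categories or groups smaller than 2 rather than silently testing a reduced
design, and a perfectly flat unit is assigned p = 1 (zero between-group
signal) rather than the 0/0 F statistic. The screen follows the selection
definition in using retrieval (recognition) trials; screening encoding
trials instead is a caller-side change of the trials argument.

The MS screen is a two-tailed bootstrap comparison of means. The null is
built by pooling the new- and old-trial rates and resampling, with
replacement, groups of the original sizes; the p-value uses the +1/(B+1)
correction, which guarantees p > 0 and a valid (slightly conservative)
test. The published description says only "bootstrap comparison of means";
pooled resampling with this correction is this package's documented
instantiation, not a claim about the original authors' code. Calibration is
tested directly: over 400 simulated null units the rejection rate at
α = 0.05 must fall in [0.03, 0.07] (the ~99% binomial band).

Population proportions count dual units in both the VS and MS totals. Note
that labeled proportions estimate `power × true_fraction + α × (1 −
true_fraction)`: with 70% untuned units, α-level false positives add ~3.5
percentage points to each estimate. The population-recovery test (200
units, 20% VS / 10% MS at gain 3, ±5 pp tolerance) passes because power at
these effect sizes is ≈1 and the false-positive inflation (~4–4.5 pp)
remains inside the band — but only barely; the tolerance is dominated by
false positives, not estimation noise.

Unit QC: the ISI-violation fraction is the share of inter-spike intervals
below 3 ms, and the pass rule is *strict* — exactly 3% fails. Trains with
fewer than two spikes pass with fraction 0.

## Problem sizes and determinism

Module tests run on compact sessions (20 + 20 trials, ≤ 6 units); the
end-to-end suite uses full-scale sessions (100 + 100 trials), 400-unit
bootstrap calibration, a 200-unit population recovery, 100-table oracle
sweeps, and behavior simulations of up to 100 × 20,000 trials — sizes at
which Monte-Carlo error is small against every asserted tolerance. Every
stochastic component takes an explicit integer seed; a session is
byte-identical given its seed, and per-unit/per-stage sub-seeds are derived
arithmetically from it, so pipelines are reproducible end to end
(`pipeline_log.txt` records seed, config hash and package versions).

## Known limitations

* The NWB layer targets the single-session human MTL layout described
  above; it is not a general NWB reader, and schema-level validation
  against the official NWB specification is outside its scope.
* The bootstrap MS screen and the zROC asymmetry test are documented
  package choices where the published analysis descriptions are
  underspecified; results on real data may differ in detail from the
  original MATLAB/Python pipelines.
* The generator's placeholder stimuli make image-computable analyses
  (e.g. category decoding from pixels) meaningless; only the category
  labels carry signal.
* Isolation distance values for simulated units are derived from synthetic
  feature clouds, not from real sorting features; they are plausible, not
  faithful.
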