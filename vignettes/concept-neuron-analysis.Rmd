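---
title: "Detecting and characterising relational concept-neuron responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising relational concept-neuron responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(relspike)
```

## The task and the data model

`relspike` analyses single-unit recordings from a three-condition
picture-comparison paradigm. Each session uses a fixed set of four
pictures. In the **main-comparison** condition a trial presents one of five
questions (four semantic, one perceptual — brightness), then two of the
four pictures in sequence with jittered onsets, then a response prompt; all
5 × 12 question × ordered-pair combinations appear equally often (300
trials with the default five repetitions: 60 per question, 25 per ordered
pair, 5 per combination). The **no-comparison** control (60 trials) keeps
the identical event structure but subjects count red fixation crosses, so
no picture comparison is required. The **question-comparison** control
names one of the four concepts in the question text and shows two of the
remaining three pictures; with three question elements this gives 36
combinations, each presented in both picture orders (72 trials).

A session is a list of three tibbles — trials, units, spikes — plus a
manifest, written to and read from a plain-text bundle
(`events.csv`, `units.csv`, `spikes.csv`, `manifest.json`). Spike times
are stored in seconds; every analysis window is given in milliseconds
relative to an alignment event, and all windows are half-open
`[start, end)` so a spike on a shared bin edge is never counted twice.

## The synthetic-session generator

The generator is a first-class module, not a test fixture: it defines the
study conditions under which every downstream guarantee is demonstrated.
Schedule combinatorics are exact by construction and verified by
exhaustive tallies. Where the task description fixes no value we chose
once, on field-typical grounds, and exposed the choice in `sim_config()`:

- picture-onset jitter: uniform 0–200 ms on top of a 500-ms inter-event
  gap (onset jitter of this order is standard in human single-unit work);
- event durations: question 1500 ms, pictures 1000 ms, prompt 2000 ms
  (question and prompt are self-paced in the task and simulated at fixed
  durations), inter-trial interval 1000 ms.

Spike trains are inhomogeneous Poisson processes: a unit's intensity is
its baseline rate plus event-locked components from its tuning
(`tuning_grid()`): a rectangular response bump (gain over
`[latency, latency + duration)`) whenever the preferred picture is shown;
a relational reactivation bump starting `reactivation_onset_delay`
(default 400 ms) after the direct-response latency, in main trials with
the preferred picture first and, for question-comparison trials naming the
preferred concept, after both pictures; a question-period bump when the
question names the preferred concept; a linear anticipation ramp over the
500 ms before the second picture when the preferred picture was not first;
prompt reinstatement when the prompt refers back to the preferred concept;
and a non-specific prompt bump starting 250 ms after the prompt.
Rectangular bumps make onsets sharply testable. Sampling is by
**superposition**: each intensity component is drawn as an independent
Poisson process (ramps via inverse-CDF placement) and the union is the
spike train. For piecewise-defined intensities this is exact — the same
law a thinning sampler would produce — and cheaper.

The generator deliberately omits refractoriness, bursting, rate
non-stationarity, spike-sorting contamination and behavioural errors.
Passing tests therefore demonstrate the *statistical machinery* under
Poisson variability with known ground truth; they do not certify
performance under real-data artefacts such as unit instability or
correlated noise.

## Response detection and the unit taxonomy

Detection compares, per picture, the firing rate in nineteen overlapping
100-ms bins (0–1000 ms after stimulus onset, stepped by 50 ms) against the
per-trial baseline rate (−400 to 100 ms — this window overlaps stimulus
onset by 100 ms and is kept as stated for the paradigm) with a paired
Wilcoxon signed-rank test, and combines the 19 p-values with the Simes
global test at α = 10⁻⁵.

At that α the signed-rank p-value must be exact: at n = 25 pairs even a
uniformly positive sample only reaches ~10⁻⁵ under the normal
approximation. Rate data are also full of ties, which the textbook exact
distribution does not cover. `signed_rank_test()` therefore computes the
exact sign-flip distribution of the midrank statistic by dynamic
convolution over doubled midranks (integers), dropping zero differences;
beyond 25 retained pairs it switches to the normal approximation with
tie-corrected variance and a 0.5 continuity correction. Tests verify the
exact path against an exhaustive 2ⁿ sign-flip oracle (with ties) and
against the classical distribution when ties are absent.

The cascade then labels each unit:

1. **visually selective** — Simes fires for *exactly one* picture (units
   with two or more detected pictures are excluded rather than demoted to
   their best picture), and Hedges' g > 0.3 for the preferred versus every
   other picture within each of the three conditions separately;
2. **concept** — additionally g > 0.3 for question-period firing on
   questions naming the preferred concept versus each other named-concept
   group. We read "versus all other written names" as per-name
   comparisons, parallel to the per-picture structure of the visual gate;
   the pooled alternative passes ~13% of null units (g SD ≈ 0.27 at
   18 vs 54 trials) and would make the gate nearly vacuous;
3. **reactivated** — concept units with higher firing 500–1300 ms after
   the second picture in relational (preferred first) versus
   non-relational (preferred absent) main trials: two-sided Mann–Whitney
   p < 0.05 *and* a positive direction, matching "higher firing" without
   assuming a one-sided test. Other concept units are input-driven;
4. **visual** — visually selective, not concept;
5. **non-visual responder** — no detected picture, mean prompt-aligned
   z > 1 over 0–1500 ms (baseline −400 to 100 ms); otherwise
   **unresponsive**.

Hedges' g uses the pooled-SD standardised mean difference with the
`1 − 3/(4(n₁+n₂) − 9)` small-sample correction; a zero pooled SD yields 0
for equal means and signed infinity otherwise, so degenerate gates fail
loudly rather than silently.

## Population machinery

`zscore_series()` bins spikes at 1 ms, averages across trials, z-scores by
the mean and SD of per-trial baseline rates (−500 to 0 ms before the first
picture), and convolves with a Gaussian kernel (σ = 50 ms). Averaging
before convolution follows the stated order of operations; because z is
linear in rate the two orders agree for the mean series. The kernel is
truncated at ±4σ and renormalised over the available support at the series
edges — no reflection — so endpoints are unbiased averages of observed
mass. Units with zero baseline SD are flagged and excluded from population
averages.

`cluster_permutation()` forms clusters from per-bin paired t tests at
α = 0.01 (two-sided), separately for positive and negative signs, and
refers each cluster's |Σt| to the permutation null of the *maximum*
cluster |Σt| under random per-unit condition-label flips (the paired
design's exchangeability). "Top percentile" is implemented as permutation
p < 0.01; the against-zero variant uses a zero comparator matrix. The
permutation p uses the add-one estimator (1 + #{null ≥ obs})/(n_perm + 1),
so it can never be zero.

On top of these sit the figure-level analyses: cross-condition Pearson
correlations of response (0–1000 ms) and reactivation (500–1300 ms) window
means; semantic-versus-perceptual relational group statistics
("Like better?" counts as semantic; the perceptual question is the
brightness question, configurable); positional effects (Hedges' g of
second- versus first-position responses, per region and condition, tested
against zero); and the prompt-aligned reactivation split by whether the
prompt refers back to the preferred concept. The anticipation window
defaults to the 500 ms before the second picture; its exact bounds are not
fixed by the paradigm and are exposed as arguments.

## Pairwise machinery

`ccg()` counts coincidences by discretising both trains into 1-ms bins
over 0–1500 ms after each alignment event and cross-correlating the count
vectors (FFT-based; identical to pair counting at this resolution), scales
by 1000 and by the geometric mean of the two units' main-condition
baseline rates, smooths each trial's correlogram with a σ = 10 ms Gaussian
and averages over trials. The combining rule for the simultaneous CCG's
normalisation is not uniquely determined by the task description; we adopt
the geometric mean stated for the shift predictor so the two are on the
same scale. The lag convention is fixed and tested: positive lag means the
second-listed unit fires after the first. The shift predictor pairs trial
i with trial i + 1 *cyclically* (last with first) to keep trial counts
equal, is boxcar-smoothed over 100 ms, and is subtracted from the
simultaneous CCG. Condition contrasts of corrected CCGs run the cluster
permutation test over the lag axis at cluster α = 0.05.

`pair_response_reactivation()` partitions main-condition trials per
ordered pair (n1, n2) by comparing the preferred pictures with the
presented sequence (both preferred / only second / only first / neither),
computes per-trial normalised rates (n2: 0–1000 ms response, n1:
500–1300 ms reactivation, both after the second picture), summarises each
pair × category with Spearman's ρ (cells under 4 trials excluded), tests ρ
against zero per category and bundle locality, and pools both-preferred
trials for a trial-level Pearson correlation.

## Verification strategy and problem sizes

Every statistical primitive is tested against an independent oracle
(exhaustive enumeration, hand formulas, or analytic expectations), and the
pipeline against planted ground truth. The package-level checks use:
500 null units for detector calibration (zero Simes rejections at 10⁻⁵;
visually selective fraction ≤ 0.075 at a relaxed α = 0.05); 100 planted
concept and 100 planted visual units for ≥ 90% label recovery, with gains
of roughly three baseline-rate SDs (12 Hz response against a 5-Hz
baseline); 200 exchangeable-null runs at 200 permutations for the cluster
test's family-wise error (≤ 0.05); 100 shared-intensity pairs for
shift-predictor nulling (grand mean corrected CCG within 3 SE of zero) and
50 runs of a planted 300-ms coupling for lag recovery (± 50 ms in ≥ 80%);
and 60 planted units for the reactivation onset lag (half-max onset
difference of 400 ± 60 ms, the smoothing-limited tolerance). These sizes
were chosen to make the binomial/SE margins comfortable at desk scale.

## Limitations

The classifier models a single preferred picture per unit; genuinely
multi-preferred units are conservatively excluded from the selective
classes. Response latency is resolved only to the 50-ms bin grid of the
detector. The population counts reported for the original recordings
(numbers of selective, concept and reactivated units) depend on the real
data and are out of scope here — the package demonstrates calibration and
recovery on synthetic sessions, and exposes the same interfaces for real
session bundles.
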