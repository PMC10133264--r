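---
title: "Methods: time-resolved directed connectivity from trial-aligned intracranial recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved directed connectivity from trial-aligned intracranial recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gcflow)
```

# The problem

Stereo-EEG depth electrodes record local field potentials from small (2 mm)
contacts ("leads") while a patient performs a task. Broadband gamma power
(50–150 Hz) at a lead is a proxy for local neuronal activation; pairwise
Granger causality (GC) between leads, computed in short sliding windows,
traces *directed* functional connections and their time course at
millisecond resolution — something hemodynamic methods cannot do. The
package implements the full chain needed to do this credibly on trial-aligned
data:

1. a multi-criterion artifact-rejection pipeline (single-trial GC is far more
   artifact-sensitive than trial-averaged power);
2. broadband-gamma response characterization and lead classification;
3. sliding-window vector-autoregressive (VAR) GC at two effective delays,
   with surrogate and bootstrap normalization;
4. signed connection strengths, a four-way connection taxonomy, conditioning
   ("via-lead") screens;
5. half-peak onset-latency estimation with bootstrap comparison.

Because the patient recordings this pipeline was designed for are not
redistributable, the package ships a synthetic generator
(`simulate_dataset()`) that reproduces the statistical structure the
analysis assumes — and, critically, records everything it injects, so every
stage can be validated against ground truth.

# Data model

A `trial_tensor` is a `leads × trials × samples` array (µV) at sampling rate
`fs` (1 kHz in the recordings), aligned so that `onset_index` samples precede
the static stimulus onset. Trials carry task labels (`gender` — the task that
drives responses — and `action`, the control), truncation and timing
metadata; leads carry anatomical region tags (`T`, `VL`, `Md`, `Ds` for the
temporal-pole subregions, `outside`, `gray-other`). Invalid data are an
explicit logical mask, not sentinel values: after rejection a `(lead, trial)`
combination is either wholly usable or wholly invalid, which makes the
exclusion contract testable (`valid_combinations()`).

All analysis windows are half-open `[start, end)`; latencies are ms relative
to onset. The on-disk container is a plain-text directory (17-significant-
digit TSV + JSON metadata) that round-trips doubles bit-exactly.

# Artifact rejection

Six criteria, combined conservatively (`reject_artifacts()`). All but the
flatness screen run on linearly detrended traces; flatness runs on raw data
because detrending perturbs exact constancy. Gender and action trials are
pooled.

**Feature-vector outliers** (`feature_vector_outliers()`). Per lead, each
trial is summarized by log high-gamma power (Welch estimate summed over
50–150 Hz) and log SD over time. A minimum-covariance-determinant (MCD)
robust center/covariance is fitted per lead (via `MASS::cov.rob`, followed by
the standard reweighting step and a median-matching consistency correction so
the distance distribution is chi-square calibrated at realistic trial
counts), and trials beyond the bivariate-Gaussian 97.5% Mahalanobis distance
— 2.7162, i.e. `sqrt(qchisq(.975, 2))` — are flagged. The percentile is a
per-dataset parameter (90–99 in practice). Leads with fewer than 10 valid
trials are skipped: robust covariance on two features needs a margin over the
parameter count.

**Wavelet transient blobs** (`wavelet_blob_outliers()`). Each trace is
transformed with an analytic generalized Morse wavelet (symmetry 3,
time-bandwidth product 60, 10 voices/octave; implemented as FFT-domain
filters since no CWT package exists in the supported stack). The magnitude
image (time downsampled ×10, scales above 10 Hz) is binarized at its 95th
percentile, holes filled, 8-connected components labelled, and the
largest-area blob kept per trace. Largest blobs are pooled *globally* across
all traces; a trace is rejected when its blob's centroid frequency exceeds
the low cutoff (default 10 Hz) and its max intensity is strictly above the
pooled 95th percentile (ties at the boundary are kept).

**Coherent (putative interictal) events** (`interictal_trial_detector()`).
Per trial, the maximum absolute lagged cross-correlation (±150 samples,
400-sample windows stepped by 50) is computed per lead pair; its off-diagonal
values are histogrammed (20 bins, common edges), trials are compared by the
1-D earth-mover's distance between histograms, and fuzzy c-means on the rows
of the distance matrix splits the trials in two. The smaller cluster (in
trial count) is the candidate outlier set. Three guards keep exchangeable
data from triggering mass rejection: near-uniform memberships (< 0.6), a
smaller cluster above 40% of trials, or a between/within distance ratio
below 3 (a genuine coherent-event cluster separates by an order of
magnitude; arbitrary splits of exchangeable trials sit near 1) all yield an
empty set with a warning.

**Trial amplitude outliers** (`trial_amplitude_outliers()`): max |value| over
leads and time per trial, median ± 3 scaled-MAD rule. **Glitches**
(`glitch_detector()`): local maxima of the across-lead mean absolute
first difference, pooled over trials; outlier maxima flag their trials. The
MAD multiple defaults to 10 — a glitch is a simultaneous step far above the
diff-noise maxima, and a high multiple keeps smooth data unflagged and lets
single-lead steps (diluted by the across-lead mean) pass; in practice it is a
per-dataset parameter. **Flat segments** (`flatness_detector()`): samples
with successive differences below 1e-10; `(trial, lead)` combinations with
more than `replen` fully-flat windows (`winlen` = 100 samples, step 50) are
rejected.

**Combination** (`combine_rejections()`): the union of the coherent-event and
amplitude candidates is removed *as whole trials* only when the trial also
holds more than `trial_reject_lead_threshold` (default 5, range 5–10)
feature-vector outlier leads — removing a trial costs all of its leads, so
corroboration is required. Glitch trials are removed unconditionally. The
combined mask is the union of removed trials with the three `(trial, lead)`
masks. `rejection_report()` summarizes counts, the union fraction (never
double-counted) and median/min remaining trials per lead.

# Gamma power and lead classification

`gamma_power_timecourse()` measures wavelet power at the ten 10-Hz sub-band
centers (55 … 145 Hz), averages across sub-bands and within non-overlapping
25 ms bins. Both wavelet families that appear in this analysis tradition are
available (`power_wavelet`: Morse, the default, consistent with the
rejection stage; or complex Morlet) — the band average is insensitive to the
choice at the 10-Hz granularity used.

`zscore_vs_baseline()` averages unmasked trials per lead (and task) and
z-scores the average against its 1 s pre-onset baseline bins. A lead is
**responsive** when its gender-task z exceeds 3 in *any* bin of the static
epoch (SEp: 75–275 ms after onset; the "any bin" reading of the threshold
rule is configurable). It is additionally **selective** when the action-task
SEp and the gender-task video epoch never exceed 3. Latency and duration are
threshold crossings of the binned trace with linear interpolation between
bins; the threshold is 3 for classification-style analyses and 2 for
averaged-trace latencies (the caller chooses).

`gc_power_correlation()` computes the Pearson correlation of connection
strengths with source power, target power and their product — the check that
GC is an independent measurement and not a power artifact.

# Granger causality

**Engine.** For an ordered pair, trials valid in both leads are selected
per pair (greedy, not the global intersection; pairs with fewer than 12
common trials are skipped — the worst per-lead trial counts observed in
practice). In every 100-sample window stepped by 10 samples, a VAR with 4
lags is fitted by ordinary least squares over pooled trial rows; the
time-domain statistic is `F = ln(σ²_reduced / σ²_full)` for the target lead,
where the reduced model drops the source's past. `ns_factor` decimates the
window (every 2nd/4th sample, plain decimation — no anti-alias filter,
matching the published "doubled and quadrupled the distance between
samples"), giving maximum modelled delays of 4 ms (NS1), 8 ms (NS2) and
16 ms (NS4) at 4 lags. The normal equations get a ridge
(`1e-8·trace(X'X)/p`) only when the reciprocal condition number drops below
1e-10. `spectral_gc()` provides Geweke's parametric frequency decomposition
(101 points from 0 to the decimated Nyquist — the grid convention for NS1/NS2
follows the NS4 precedent of spanning the setting's own Nyquist) as a
diagnostic; typing always uses the time-domain statistic.

**Normalization.** Three run modes mirror the published procedure: the point
estimate; 20 bootstrap resamples of trials (`bootstrap_gc()`, variability);
and 20 surrogates with the trial order of each lead permuted independently
(`surrogate_normalize()`), whose mean estimates the small-sample bias of F
and whose SD yields `z_surr` — the test against the null of no trial-locked
coupling. Baseline z-scoring (`baseline_zscore_gc()`) isolates the phasic
component: each direction's trace is z-scored against the windows wholly
inside −900…0 ms. It is applied to the raw F by default (configurable): the
published account introduces z-scoring on the GC scores themselves, and a
noisier baseline then correctly shrinks the z.

**Strength and taxonomy.** The signed strength `C` is the extreme of the
baseline-z trace in 0.1–0.4 s after onset: both extremes positive → the
maximum; both negative → the minimum; mixed signs → their mean when the
absolute values differ by less than 3, otherwise the larger-magnitude
extreme with its sign (one signed number even for bimodal profiles). Note
the rule compares the *magnitudes* of the two extremes — with mixed signs
the plain difference `max − min` is their sum, which would almost never take
the mean branch. Combining `C` at the two delays with the strong threshold 5
(strict `>`; ties fall to the weaker class) yields the taxonomy: **D**
(disappear: strong only at 4 ms — consistent with a direct, fast link),
**M** (maintain), **A** (appear: strong only at 16 ms — longer or indirect
routes), **N** (negative: strongly suppressed at the long delay), plus
**opposite** (a strong value flipping sign between delays; excluded
downstream) and **weak**.

**Conditioning.** `conditioned_gc()` fits the three-lead VAR (window length
is the binding constraint: 100 ms windows support at most 3 leads × 4 lags)
and `conditioning_screen()` tries every candidate once, reporting the pair's
peak response-window z before and after; candidates that pull it below 3
(medium threshold) are the influential leads — the strongest common inputs.
An outside lead is a **via-lead** for a pair when both `C(source → lead)` and
`C(lead → target)` exceed 5 (`via_lead_classification()`).
`region_average_gc()` averages traces pointwise across the target-region
leads of a patient.

# Onset latency

`onset_latency_50pct()`: find the peak in a search window (default
50–500 ms, covering the 165–201 ms response latencies observed in this
paradigm with margin; the published "region around the expected response" is
per-patient), normalize, locate the first sample at or above half height,
and interpolate linearly. GC curves must have peak z > 3 to be included.
The estimator is shift-equivariant and scale-invariant.
`onset_difference_bootstrap()` resamples trials 100 times per set, averages,
z-scores, estimates the onset per bootstrap curve, and reports the mean
difference with a pooled-SD significance flag (|Δ| > 2·SD; the published
comparison states significance without naming the test — the 2-SD bootstrap
criterion is this package's choice).

# The synthetic world

`simulate_dataset()` builds datasets with exactly the structure the analysis
assumes:

* background: independent white Gaussian noise per lead (optional 1/f
  fraction; white by default so closed-form GC oracles stay valid);
* responses: 50–150 Hz-filtered noise under a raised-cosine envelope
  (broadband, not narrowband, matching the physiology), default onset 170 ms
  and duration 110 ms — the observed medians; the default amplitude (0.5 ×
  noise SD) gives single-trial z of order 1, as observed, while the
  trial-averaged trace crosses the z = 3 responsiveness threshold decisively;
* couplings: time-varying VAR coefficients (`target[t] += gain ·
  source[t − lag]`) gated by task and time window, so the generator's model
  class matches the GC engine in the ideal case and directionality/delay are
  exactly controlled;
* artifacts: one injectable class per rejection criterion, with the exact
  placements recorded in the returned `ground_truth`.

**What a green test does and does not establish.** The generator's world is
linear, Gaussian, and stationary inside the coupling gate. Green recovery
tests establish that the estimators implement their definitions and recover
planted structure at realistic sizes; they do not establish robustness to
1/f backgrounds, volume conduction, non-Gaussian artifacts beyond the
injected classes, or nonstationarity beyond the gating used. Two boundary
effects are worth knowing:

* a *hard* gain gate violates local stationarity in windows straddling its
  edges, which leaves residual conditional GC there even when conditioning
  on the true driver; conditioning scenarios therefore gate couplings over
  an interval wider than the 0.1–0.4 s measurement window (as in the
  recordings, where GC activation spans the response period). Interior
  windows drop to baseline exactly.
* robust-covariance screens are calibrated for the trial counts of the real
  recordings (≈ 64–256 per lead); far below that the MCD over-flags, which
  is why the clean-data false-positive validation runs at ≥ 128 trials per
  lead.

# Numerical choices and degenerate inputs

* VAR ridge only on near-singular windows (reciprocal condition < 1e-10);
  raw F is non-negative up to ~1e-10.
* Zero surrogate or baseline SD → `NA` z (undefined marker), never an error;
  zero *power* baseline SD is an error (the lead is degenerate).
* Threshold conventions: strict `>` at 5 for "strong"; a magnitude
  difference of exactly 3 in the strength rule takes the larger-magnitude
  branch ("less than 3" takes the mean).
* Seeds: every stochastic step (simulation, injection, surrogates,
  bootstraps, MCD subsampling, fuzzy c-means initialization) derives from an
  explicit seed recorded in the configuration, making whole-pipeline runs
  byte-reproducible.
* Blob intensity ties at the pooled percentile are not flagged; all-equal
  scalograms yield no blobs.

# Known limitations

Nonparametric (spectral-factorization) GC is deliberately out of scope, as
is joint conditioning on more than one lead (window length forbids it),
clinical-format ingestion, re-referencing, and group-level mixed-effects
statistics. The fixed post-onset trial duration simplifies the variable
inter-trial gaps of real sessions. Frequency-domain GC is a diagnostic only.

# Worked example

```{r example}
library(gcflow)

cp <- rbind(
  coupling_spec("L1", "L2", lag_ms = 2,  gain = 0.6, window_s = c(0, 0.6)),
  coupling_spec("L3", "L4", lag_ms = 12, gain = 0.9, window_s = c(0, 0.6))
)
sim <- simulate_dataset(n_leads = 4, n_trials_per_task = 64,
                        tasks = "gender", couplings = cp,
                        bursts = burst_spec("L1"), seed = 42)

res <- run_pipeline(sim$tensor, pipeline_config(ns_factors = c(1, 4)),
                    pairs = rbind(c("L1", "L2"), c("L3", "L4")))
res$connections
#> expected: L1 -> L2 strong at NS1 only (type D), L3 -> L4 type A

autoplot(res$gc_traces, value = "z_base")
plot_connection_types(res$connections)
```
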