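---
title: "Brain-state dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statedyn)
```

## The analysis in one paragraph

`statedyn` treats resting-state fMRI as a sequence of recurrent whole-brain
co-activation patterns ("brain states"). Regional BOLD time series are
postprocessed (detrending, 0.01–0.08 Hz band-pass, nuisance regression,
motion scrubbing, demeaning), concatenated across scans and subjects, and
clustered frame-by-frame with k-means under correlation distance. Each
cluster centroid is a brain state; each kept frame gets a state label. From
the per-scan label sequences the package derives four dynamic metrics —
fractional occupancy, mean dwell time, appearance rate, and the
frame-to-frame transition matrix — and carries them into group inference:
paired pharmacological contrasts (methylphenidate vs placebo) with
Benjamini–Hochberg correction, correlations of metric changes with striatal
dopamine-receptor availability (at ROI and voxel level, the latter with a
cluster-extent filter), and a bootstrap mediation analysis linking D1R
availability to response-time change through FPN+ dwell-time change.

Because the underlying human PET/fMRI data are not redistributable, the
package ships a synthetic-cohort generator with a fully known ground truth.
Every downstream stage is developed and tested against that ground truth.

## The synthetic cohort: what it emulates

The generator reproduces the study geometry: `n_subjects = 37`, two scans
per subject (placebo `PL`, methylphenidate `MP`), `n_frames = 520` at
`tr_seconds = 0.891`, `n_rois = 232` split into seven cortical networks
(200 ROIs) plus one subcortical network (32 ROIs), and `k_true = 6` latent
states.

The latent dynamics are a first-order Markov chain over state centroids.
The paper-level analysis assumes exactly this structure — frame-wise state
membership with persistence — so it is the simplest generative model the
clustering pipeline can be validated against. States come in network ±
pairs (`FPN+`/`FPN-`, `SOM+`/`SOM-`, `VIS+`/`VIS-`), with the
characteristic secondary loadings of the three canonical states: `FPN+`
also elevates DAT and suppresses VIS, while `SOM+` and `VIS+` suppress DMN.
Those secondary loadings are what make the centroid dendrogram split the
six states into an association-dominant group {FPN+, SOM-, VIS-} and a
sensorimotor-dominant group {FPN-, SOM+, VIS+}.

The observation model for frame $t$ is

$$y_t = A\,c_{s_t} + \varepsilon_t + d_t + \text{spikes},$$

with amplitude $A$ (`amplitude = 100` arbitrary BOLD units), per-ROI AR(1)
noise (`ar_coeff = 0.3`, stationary SD `noise_sd = 40`), a shared
sinusoidal drift of period 128 s (`drift_amp = 50`), and motion-spike
artifacts at Bernoulli(`spike_rate = 0.02`) frames. The noise-to-signal
ratio of 0.4 keeps single frames identifiable (≥95% of frames correlate
most with their generating centroid) while leaving clustering non-trivial.
The absolute scale of ~100 units was chosen so that the conventional DVARS
threshold of 150 is meaningful: spike frames produce DVARS in the hundreds,
clean frames tens. Spikes are also written into the emitted motion
regressors as >0.5 mm translation steps, so the FD>0.5 mm rule catches
them independently.

The pharmacological effect is a persistence boost: under MP the
self-transition probability of `FPN+` and `VIS-` rises from
`base_persistence = 0.90` by `sensitivity × mp_persistence_boost`
(`mp_persistence_boost = 0.03`), with the off-diagonal mass of those rows
(including entries into `SOM+`) shrunk proportionally. `base_persistence =
0.90` gives mean dwell times near 9 s — comfortably inside the 0.01–0.08 Hz
passband, so band-pass filtering does not erase the state structure; the
boost roughly scales dwell time by 1/(1−p) and was set so the paired
contrast is detectable but not trivial at n = 37.

The mediation path is planted as: per-subject mean D1R (normal across
subjects, plus per-ROI noise over the 32 subcortical ROIs, which stand in
for the striatal parcellation) → a latent sensitivity scalar
(`mediation_a = 0.6` is the D1R–sensitivity correlation,
`sensitivity_slope = 0.5` its spread around 1) → the subject's persistence
boost → the true MP−PL FPN+ dwell-time gain → a 2-ball response-time
reduction of `mediation_b = 0.02` s per second of dwell gain plus 0.05 s
noise. IQ is drawn independently of the whole path. Ball-track accuracy is
simulated as 15 Bernoulli probes per scan (3 cycles × 5 response
intervals), with probe success probabilities set to the observed group
means (2-ball 0.903 PL / 0.970 MP; 3-ball 0.890 / 0.948), so accuracies lie
on the grid {0, 1/15, …, 1} and ceiling effects are reproducible.

All randomness flows from one root seed (`cohort_config(seed = )`) through
`split_seed()`, a documented splitting scheme; every object the generator
returns is bit-reproducible.

What the generator does **not** emulate: hemodynamic convolution, spatial
autocorrelation between neighbouring ROIs beyond network co-membership,
scanner drift nonstationarity, physiological (cardiac/respiratory)
aliasing, and voxel-level BOLD. Tests passing on this cohort therefore
validate the *pipeline's statistical machinery* — recovery of a known state
structure and planted effects — not the neurobiological claims themselves.

## Postprocessing choices

The chain is detrend → band-pass → nuisance regression → censor → demean,
in that order. Filtering precedes masking so censoring gaps cannot create
filter transients; censored frames are excluded from all analysis rather
than interpolated ("excluded" semantics). Specific conventions:

* **FD** uses the Power convention: sum of absolute frame-to-frame
  differences of the six rigid-body parameters, rotations converted to arc
  length on a 50 mm sphere. `fd[1] = 0`.
* **DVARS** is the RMS over ROIs of the frame-to-frame difference, computed
  on the post-regression, pre-censoring series. `dvars[1] = 0`.
* **Censoring** drops a frame iff FD > 0.5 mm **or** DVARS > 150, with
  strict inequalities at both thresholds.
* **Band-pass** is a second-order Butterworth applied forward–backward
  (`signal::filtfilt`), i.e. zero-phase; the passband is 0.01–0.08 Hz. The
  contract is ≥90% amplitude at mid-band (0.04 Hz) and ≤10% at 0.3 Hz.
* **Nuisance regression** residualizes each ROI on an intercept plus six
  motion and three tissue regressors (CSF, WM, global signal). Global-signal
  regression happens after filtering; only one order is supported, and it is
  this one.

The three projection stages (detrend, regression, demean) are idempotent to
numerical precision. The band-pass stage is *not* exactly idempotent — a
second forward–backward pass squares the frequency response, which is the
expected behaviour of any realizable filter — so the pipeline's stability
test asserts projection idempotence plus near-identity (not bit equality)
of a repeated band-pass.

## Clustering: correlation-distance k-means

The distance is $d(x, c) = 1 - \mathrm{cor}(x, c)$ across ROIs. The
semantics deliberately replicate the common reference implementation as a
compatibility contract, implemented natively: frames are row-standardized;
assignment is to the maximum-correlation centroid (ties to the lowest
index); a centroid is the mean of its member rows re-centered to zero mean;
each restart initializes with k distinct frames drawn uniformly without
replacement; the best of `n_restarts` by total within-cluster distance
wins; an emptied cluster is reseeded with the frame farthest from its
current centroid.

Numerical choices: Lloyd iterations stop when assignments are unchanged or
the total distance improves by less than `tol = 1e-5` relative (cap
`max_iter = 50`). The tolerance is three orders of magnitude below the 0.01
explained-variance resolution that model selection uses, so it cannot
affect the elbow; it exists because the long tail of single-label swaps on
~40,000 frames would otherwise burn iterations for no measurable change.
After the loop a final assignment pass guarantees the returned labels are
an exact argmax fixed point of the returned centroids.

Model selection plots $EV(k) = 1 - \sum_t d(y_t, c_{s_t}) / \sum_t d(y_t,
\bar c)$ for k = 3..22 and picks the smallest k whose gain to k+1 falls
below 0.01 — "<1% variance gain" read as one absolute percentage point of
EV (a relative-gain reading would make the rule depend on the EV level; the
absolute reading is the conventional one). If no gain drops below the
threshold, the scan returns k_max with a warning rather than failing.

Partition robustness: the clustering is replicated (10 replicates by
default), and the replicate with the highest cumulative adjusted mutual
information (AMI) against the others is kept; ties break to lowest inertia,
then lowest replicate index. AMI uses the standard hypergeometric
expectation of mutual information and is implemented in-package.

State naming computes the cosine similarity of each centroid's positive
part and negative part against each network's indicator vector and names
the state after the single largest similarity (`NET+` from the positive
part, `NET-` from the negative). Whole-centroid cosine is available via
`name_states(..., parts = "whole")`. Signed-part naming is the default
because demeaned centroids carry meaningful signed structure and the
whole-centroid variant cannot distinguish `NET+` from the suppression of
everything else. Censored frames are dropped before clustering — an
excluded time point cannot carry a state label.

## Dynamic metrics

For each scan's kept-frame label sequence:

* **Fractional occupancy**: frames in state s / kept frames. Sums to 1.
* **Dwell time**: mean length of maximal runs of s × TR, in seconds; 0 for
  absent states (not missing, so paired tests keep full n).
* **Appearance rate**: number of runs of s per minute of kept time.
* **Transition matrix**: row-normalized counts of adjacent ordered pairs.
  Self-transitions stay on the diagonal (persistence is the phenomenon of
  interest); an exits-only renormalized view is available
  (`offdiagonal = TRUE`). Rows with no departures are flagged, not NaN.

A censoring gap always breaks a run and never contributes a transition —
frames on either side of a gap are not temporally adjacent. Dwell time is
the mean run length (not total time per visit), the convention of the
co-activation literature; on gap-free sequences the identity
FO = rate × dwell / 60 holds exactly and is tested.

## Group inference

Paired two-sided t tests on per-subject MP−PL differences, df = n−1.
Benjamini–Hochberg runs within each metric family (all states × one metric)
by default — matching per-panel correction — with a global option. A
zero-variance nonzero-mean difference vector is reported as the p→0 limit
with a warning instead of NaN. Correlations are Pearson with the exact t
transform; covariate (IQ) adjustment residualizes both variables on the
covariate and uses df = n−3. Missing behavioral data are dropped pairwise
with the per-cell n reported.

The voxelwise stage correlates each in-mask voxel with a target across
subjects, thresholds at uncorrected p < 0.05 separately for positive and
negative correlations (signed maps), labels 26-connected components
(faces + edges + corners; "spatially contiguous" is not further specified,
and 26-connectivity is the permissive standard), and keeps components of
≥30 voxels.

## Mediation

Paths are plain OLS with intercepts: a from m~x, c from y~x, (c′, b) from
y~x+m, so c = c′ + a·b holds identically. Inference on a·b uses the
percentile bootstrap (1,000 subject resamples; BCa was not chosen because
only the iteration count, not the CI type, is part of the compatibility
surface) with the two-sided tail p-value
`2·min(#{ab ≤ 0}, #{ab ≥ 0})/n_boot`, floored at `2/n_boot`. Degenerate
resamples (constant x or m) are redrawn and counted. IQ can be partialled
out of all three variables via `mediate(..., covariate = "iq")`.

## Problem sizes used in validation

The packaged validation suite exercises the full study geometry once — the
default 37 × 2 cohort, 520 frames × 232 ROIs, postprocessed and scanned over
k = 3..22 with 10 restarts per k (restarts are reduced from the
confirmatory 50 because the elbow location is stable across restarts and
the scan is repeated 20 times along the k axis). Simulation studies of the
inference stages use truth-sequence cohorts (no BOLD synthesis): 100
cohorts for contrast power, 200 null cohorts for the false-positive check,
2,500 repeats for bootstrap CI coverage (the percentile CI's true coverage
at n = 37 is ~93.5%, near the edge of its 93–97% calibration band, so the
Monte-Carlo SE must be ~0.5% to resolve it) and 100 repeats for mediation
power. The other sizes give binomial standard errors of 2–4 percentage
points, adequate for their pass bands.

## Known limitations

* The generator's states are exactly Markovian and its centroids exactly
  recurrent; real co-activation patterns drift within state. Elbow recovery
  here does not guarantee elbow detectability on weaker real-data structure.
* DVARS scaling is meaningful only because the synthetic BOLD scale was
  chosen to make it so; on data in other units the threshold must be
  rescaled by the caller.
* The elbow rule with an absolute 0.01 threshold is scale-dependent in k
  only through the EV curve; heavily noise-dominated data can legitimately
  elbow below the true state count.
* Mediation is a single-mediator OLS decomposition with no causal
  identification claims; it quantifies consistency with a mediation
  structure, nothing more.
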