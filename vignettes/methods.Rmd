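---
title: "Decoding anticipatory orientation biases: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding anticipatory orientation biases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(momdecode)
```

`momdecode` reimplements, as a tested package, an analysis chain for EEG
experiments on the neural encoding of predictable visual sequences:
steady-state visual evoked potentials (SSVEPs), inverted encoding models
(IEMs) of orientation, cluster-based permutation inference, jackknife
statistics, and a same/different behavioral analysis. This vignette is the
package's own account of the science: the models and their assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices made where the method left room.

## The experimental design being emulated

Two grating streams flicker at 5 Hz for 5 s (25 gratings of 200 ms each),
one in each hemifield. One stream rotates clockwise in fixed 20° steps
(RTT); the other draws orientations from the same 20° grid with the single
constraint that consecutive gratings never form a ±20° transition (RDM), so
local rotational structure is removed while orientation statistics stay
matched. A cue directs covert attention to one stream; the trial's
condition label is the type of the attended stream. After each trial a
central probe at the last attended orientation ±{0, 4}° is judged
same/different.

Orientation is circular with period 180°; all differences are wrapped to
(−90°, 90°]. "Clockwise" is mapped to +20° per step. The method never
defines the sign convention — only consistency matters, and all decoded
biases are reported in the direction of rotation (positive = forward).

## The encoding model

Eighteen orientation channels with preferred orientations 0°–170° in 10°
steps respond as half-wave rectified cosines raised to the 18th power,
`max(0, cos(πΔ/180))^18`. The argument scaling is a design choice: the
cited family fixes the shape but not the argument; this choice makes each
tuning curve unimodal, equal to 1 at its center, exactly 0 at ±90°, and
180°-periodic — the standard convention for orientation spaces.

The forward model is `EEG = W·C + N`. Weights are ordinary least squares
via the Moore–Penrose pseudoinverse. With stimuli on the 20° grid, `C` has
rank 9 < 18: the model is inherently rank-deficient and the pseudoinverse
returns the minimum-norm solution (a warning is emitted). This
rank-deficiency is a property of the design, not an implementation detail;
the reconstruction lives in the 9-dimensional subspace spanned by the grid
responses, which is sufficient for peak and bias estimation because every
presented orientation lies on the grid.

The inversion filter `V = Σ⁻¹W(WᵀΣ⁻¹W)⁺` accounts for the spatial noise
correlation. Σ is the sample covariance of the training residuals with
analytic (Schäfer–Strimmer) shrinkage toward its diagonal; the exact
estimator in the cited approach is not reproducible from the text, and
analytic shrinkage is the standard self-tuning choice. With white noise the
filter reduces exactly to the transposed pseudoinverse; with zero residuals
(noiseless data) Σ falls back to the identity. The joint-inversion form is
used because the reconstruction applies a single matrix; a per-channel
normalized variant would rescale channels independently and was not needed.

## Sliding-window decoding and cross-validation

Features are per-electrode mean amplitudes in a 40 ms window (10 samples at
250 Hz) centered on each sample; whether the reported time point is the
window's center or trailing edge is unspecified in the method, and the
centered reading was chosen. Decoders are trained on attended-RDM epochs
only, separately per attended side, then collapsed — training on the random
condition avoids the systematic −20° contamination from the previous
grating present in rotational sequences, and equalizes training SNR across
conditions.

The attended-RDM pool is reconstructed with leave-one-out cross-validation.
Two implementation decisions matter:

- **Exact reduced form.** With grid stimuli, the OLS weights equal the
  per-orientation class means times the pseudoinverse of the basis matrix
  (`pinv(B·S) = pinv(S)·pinv(B)` because `B` has full column rank and the
  class-indicator `S` full row rank), and the filter reconstruction
  collapses to `ĉ = B G⁻¹ Mᵀ Σ⁻¹ x` with `G = Mᵀ Σ⁻¹ M`. Leave-one-out then
  reduces to down-dating one class mean, making per-epoch cross-validation
  exact and fast. Tests assert equality with the generic
  weights-then-filter path.
- **Fold-wise noise covariance.** The residual covariance is also
  down-dated for each fold (the held-out epoch's residual outer product is
  removed before shrinkage; the shrinkage intensity is estimated once per
  window). Estimating Σ on the full pool would let each epoch's own noise
  into its filter and measurably inflates leave-one-out decoding scores
  relative to independent test epochs — an effect we observed and removed.
  With the down-date, leave-one-out and independent-pool scores agree in
  expectation. No epoch contributes to its own reconstruction through any
  estimated quantity.

The leave-one-out unit defaults to one epoch, matching the stated
procedure; a leave-one-trial-out option holds out all of a trial's epochs
together, since adjacent epochs within a trial are plausibly dependent in
real data.

Realignment of CTFs to the presented orientation is a pure circular shift
(the 20° stimulus grid is a subset of the 10° channel centers; no
interpolation is ever performed). The decoding score is the OLS slope
(intercept included) of the realigned CTF against the ideal tuning curve
centered at 0°: it is invariant to additive constants and linear in gain.
The decoded bias is the center of a Gaussian `a·exp(−(x−µ)²/2σ²)+b` fitted
by Levenberg–Marquardt over the offsets −90°…+80°, with µ ∈ [−45°, 45°],
σ ∈ [5°, 90°], initialized at the argmax (lowest offset on ties). Flat
inputs and non-convergence are flagged and excluded rather than fitted.

## Statistical inference

**Channel-shift cluster permutation.** The CTF surrogate distribution
randomly shifts each epoch's CTF center before realignment. Because
realignment is itself a circular shift, this is implemented as an extra
uniform channel shift of the realigned per-epoch CTF — an exact
equivalence. The shift is drawn per epoch (realignment is per-epoch); a
per-subject variant is available. Pixels above the pixelwise 95th
percentile of the surrogate maps (one-tailed, matching the stated
procedure) are clustered with time adjacency and circular channel
adjacency, and cluster mass is compared to the permutation null of maximum
surrogate cluster masses. p-values use the (1 + #{null ≥ obs})/(n_perm + 1)
convention, so they are floored at 1/(n_perm+1) and monotone in mass.

**Time-resolved RM-ANOVA.** Decoding scores in the four cells (attention ×
sequence type) are analyzed pointwise with a 2×2 repeated-measures ANOVA
(each effect tested against its subject-by-effect interaction; no
sphericity correction, matching the uncorrected degrees of freedom
convention). Suprathreshold runs (uncorrected p < 0.05) are clustered in
time; the null stores, per effect, the maximum summed F under independent
within-subject relabelings of the four cells. Under joint relabeling the
interaction family is exactly calibrated and main-effect families are
mildly conservative; the package's null simulations measure the
interaction family.

**Electrode-time maps.** Paired SSVEP power maps are compared with
pixelwise paired t tests, two-tailed thresholding at α = 0.05, clustering
via electrode adjacency × time contiguity (positive and negative clusters
separately), and a sign-flip max-cluster-mass null. Negating the data
leaves all cluster p-values unchanged.

**Jackknife.** Group-level statistics that are functions of the whole
sample (the Gaussian center of the group-mean CTF) get leave-one-subject-out
standard errors, `SE_D = √((N−1)/N · Σ(D₋ᵢ − J̄)²)`, `t_j = D/SE_D` with
N−1 degrees of freedom. For linear statistics this equals the classical
plug-in SE exactly (tested).

**Effect size.** Paired contrasts report Cohen's d_z = t/√N, the convention
consistent with printed values in this literature.

## The synthetic generator

The generator is the package's testbed: a forward model with known ground
truth emulating the study's structure. Per subject it draws a random mixing
matrix `W_true` (orientation-tuned, concentrated at posterior electrodes),
an untuned evoked topography, and a random spatial noise correlation. Each
epoch's signal is a gamma-shaped response kernel (onset 50 ms, peak 120 ms,
width 50 ms — chosen so decodable signal falls in the early post-stimulus
range where visual responses live) times the channel response to the
*encoded* orientation, which for rotational streams is the true orientation
shifted forward by `bias_rtt` (default 5°). Attention multiplies the evoked
response by `gain_attended` (default 1.3). A 5 Hz sinusoid (with a 10 Hz
harmonic in the trial-level data) is added at posterior electrodes
contralateral to the attended side. Noise is spatially correlated Gaussian
(`noise_spatial_corr` controls off-diagonal mass) with AR(1) temporal
structure — correlated noise is required for the optimal filter to be
distinguishable from the plain pseudoinverse, which is tested.

**What `gain_rtt` scales.** The study's empirical pattern is *reduced
response amplitude with preserved decodable information* for predictable
sequences. The generator realizes this by splitting the evoked response
into an orientation-tuned component and an untuned component: `gain_rtt`
(default 0.8) scales the untuned evoked component and the rotational
stream's SSVEP drive, while the tuned component is scaled by a separate
`gain_rtt_tuned` (default 1). With the defaults, global field power and
lateralized 5 Hz power drop for rotational sequences while decoding scores
are statistically indistinguishable — the dissociation the analyses are
designed to detect. Setting `gain_rtt_tuned < 1` instead produces amplitude
loss *with* information loss. Note that with the default 5° bias, decoding
scores for the rotational condition are very slightly lower purely because
the shifted tuning curve is misaligned with the ideal template — a real
property of slope-based scoring; the amplitude-dissociation validation
therefore zeroes the bias to isolate the gain manipulation.

**Deliberate simplifications.** Each epoch carries only its labeled
stream's evoked signal: the two concurrent streams are not mixed into one
sensor array, and responses of adjacent gratings do not superpose. This
keeps the noiseless forward model exactly invertible (a round-trip test
requires 100% of epochs to realign at 0°) at the cost of not emulating
cross-stream interference or the −20° carry-over the training scheme
guards against. There is no head model, no eye movements or blinks, no
alpha rhythm, and behavioral responses are independent across trials.
Passing tests therefore validate the *analysis machinery* — estimator
correctness, calibration of error rates, recovery of known parameters —
not robustness to every property of real recordings.

**Behavior.** Same/different responses follow
`P(same|o) = lapse + (1−2·lapse)·exp(−(o−µ)²/2σ_b²)` with µ = 4° after
attended rotational sequences and 0° otherwise, σ_b = 6°, lapse = 0.1. The
±4° probe grid only samples three points of this curve, which is why the
behavioral analysis is a 2×3 ANOVA with planned contrasts rather than a
psychometric fit. The 4° default reflects that the probe grid probes ±4°;
σ_b and the lapse are generic psychophysical values.

**Scale defaults.** 19 subjects, 45 trials per (attended side × sequence)
cell — about 1125 attended epochs per condition and side, matching the
recorded study's scale — 32 electrodes (128 available), 250 Hz, epochs
−200…+500 ms (175 samples). The simulation is a pure function of the
config including its seed; per-subject streams are derived from the master
seed, so any subject can be regenerated bit-identically in isolation
(the pipeline exploits this to avoid holding all subjects in memory).

## Electrode selection and spectral choices

Decoding uses the electrodes with the strongest SSVEP response: the
**union** of the sets exceeding the 75th percentile of trial-averaged power
at 5 Hz and at 10 Hz. With 128 electrodes each set has 32 members, so the
union has 32–64 members; a reported subset of 39 is arithmetically possible
only under the union reading (the intersection can never exceed 32), which
settles an ambiguity in the method's wording. Selection is applied to
trial-averaged spectra (whether averaging preceded thresholding is not
stated) and is scale-invariant.

Spectra are raw 5 s periodograms (0.2 Hz resolution): the tagging frequency
and harmonic fall on exact bins, so no taper is needed for leakage control
at those bins. The time-frequency estimate at 5 Hz uses a 1 s Hann-tapered
complex sinusoid (the method's description mixes two taper families; the
stated 1 s window with a Hann taper was implemented, a Gaussian-taper
variant is one flag away), normalized so a stationary unit-amplitude
sinusoid yields power 1, restricted to 0.5–5 s to avoid onset transients
and edge effects. Global field power is the sample (n−1) standard deviation
across electrodes — the denominator is unspecified in the method and the
sample convention was chosen.

## Problem sizes in the test suite

The validation experiments run at reduced scale, chosen to keep the
properties they measure intact: bias-recovery and dissociation replicates
use 19 subjects with 2 trials per cell and 16 electrodes (100 replicates
for bias recovery; the jackknife t at this scale is far from the
significance boundary, so the replicate rate is a stable property);
family-wise error simulations use 500 outer replicates of small null
datasets with 500 permutations each, against the binomial 95% band around
0.05. The pipeline's end-to-end test uses 8 subjects with 6 trials per
cell on a 64-electrode montage; the acceptance script runs 19 subjects
with 8 trials per cell on the full 128-electrode montage. The full-scale
defaults remain the package defaults.

**A conditioning caveat.** With 9 distinct stimulus orientations, the
class-mean system that the reduced inversion solves has 9 columns; if the
selected electrode set is about the same size, that matrix is nearly
square and — like any square random matrix — can be arbitrarily close to
singular at windows with no evoked signal, producing exploding
reconstructions. The recorded-study regime (a 128-electrode montage whose
quartile-union selection returns roughly 30–60 electrodes for 9 classes)
is comfortably rectangular and does not suffer from this.
`sliding_window_decode()` warns when the electrode count comes within 3 of
the class count; pipeline-scale analyses in this package use montages of
64 or 128 electrodes for exactly this reason.

## Known limitations

- The IEM subspace is 9-dimensional by design; tuning *width* comparisons
  between conditions are constrained by the training-on-RDM scheme (a
  limitation the method itself notes).
- The generator's noise is Gaussian and stationary; real EEG artifacts,
  oscillatory structure, and cross-stream interference are out of scope.
- Real-data ingestion expects the package's epoch container
  (`epoch_array`, serialized via `save_epochs()`); converters from
  acquisition formats are out of scope.
- The channel-shift surrogate is drawn per epoch; whether the original
  procedure shifted per epoch, trial, or subject is not stated (a
  per-subject option is provided).
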