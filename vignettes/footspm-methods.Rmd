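---
title: "Methods: stance-phase foot kinematics, discrete risk factors, and 1D-SPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stance-phase foot kinematics, discrete risk factors, and 1D-SPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footspm)
```

# Scope and design

`footspm` implements the full secondary-outcome analysis chain of a two-arm
pre/post running study: stance-phase recordings are filtered, segmented by
the 30 N rule, decomposed into multi-segment foot angles, reduced to six
discrete injury-risk parameters, and analyzed with per-outcome mixed models
and one-dimensional statistical parametric mapping (1D-SPM) over 101 stance
nodes. Because trial-level raw data of this kind are rarely shareable, the
package treats the *synthetic cohort generator* as a first-class module:
cohorts carry planted per-trial ground truth, so the correctness of every
later stage is a testable property rather than an assumption.

# The synthetic cohort generator

## What it emulates

A cohort is `2 × n_per_group` subjects (defaults 41 intervention / 46
control), each recorded at two assessments. Per subject and assessment the
generator draws the six discrete outcomes from a group × time cell table of
means and standard deviations (defaults follow the discrete-outcome table
of the trial design the package targets: MLA ROM 6.16/0.17 vs 3.59/2.88
degrees, rearfoot peaks, impact peak ≈ 1.1 BW, VALR ≈ 75 BW/s, braking
≈ −0.24 BW), decomposed as

* a between-subject random intercept per outcome (default: half of the
  smallest cell variance, i.e. an intraclass correlation of about 0.5 in
  the most precise cell — a typical test–retest figure for discrete gait
  parameters), and
* an independent residual making up the remaining cell variance.

Body mass is normal(70.5, 13.1) kg truncated at ±3 sd; stance duration is
0.25 s with 0.015 s jitter (clamped to 0.18–0.35 s and snapped to the
200 Hz kinematic grid so the 1,000 Hz force grid aligns exactly). Sampling
rates, assessment labels, and every noise scale are configuration fields;
`sd_scale = 0` collapses the cohort to the fully deterministic degenerate
case and `null_effects = TRUE` equalizes all four cells per outcome.

## How planted values survive extraction exactly

The design goal is that the *measurement definitions themselves* recover
the planted numbers:

* **Vertical GRF**: a linear rise at exactly the planted loading rate up to
  the impact peak, a plateau of ~2.5 samples at exactly the planted peak
  force, a smooth dip, a half-cosine rise to the active peak (default
  2.4 BW at 45 % of stance), and a half-cosine decay to zero. Because the
  rise is linear, the 20–80 % secant slope equals the planted VALR no
  matter where in the rise the contact and peak samples fall; because the
  peak is a plateau, the sampled maximum equals the planted value at any
  sampling rate. The anterior-posterior channel is a braking bump with the
  same plateau construction at its minimum, followed by a propulsive bump.
* **Angle channels with planted extrema** (rearfoot frontal angle, MLA):
  piecewise-linear "trapezoid" programs whose extreme values sit on
  plateaus near 0–10 %, 42–58 % and 90–100 % of stance. Linear
  re-interpolation (sampling, then 101-node normalization) cannot move a
  plateau value, so max/min extraction is exact; ramps between plateaus
  only ever take intermediate values.
* **Poses**: segment rotations are composed in the exact inverse order of
  the Joint Coordinate System decomposition, so decomposition recovers the
  programs to machine precision; markers are rigidly attached to segments.
  The arch triad (heel, apex, first-metatarsal head) is driven directly by
  the MLA program through the apex-angle identity
  `h = (L/2) / tan(θ/2)`, making the arch angle exact by construction.
  The calcaneus–metatarsus joint is *not* independently plantable — it is
  the composition of the two chain joints between them — and is computed
  downstream like in real data.

Channels with no planted discrete outcome (the other joint planes, the
metatarsal inclinations and divergences) use fixed smooth base shapes of
realistic magnitude plus a per-subject offset (sd 2°) and a per-trial
low-order Fourier perturbation (sd 0.5°, first three harmonics). The
Fourier family was chosen because 1D random-field inference assumes smooth
residual fields; white node-wise noise would violate the smoothness model
the SPM stage relies on. No claim is made that these shapes reproduce any
specific population's mean curves — they exist to give the trajectory
statistics realistic smoothness and variance structure.

## Planted vs. realized truth

Normal cell summaries are not perfectly compatible with the outcome
definitions: a normal draw for MLA ROM can be negative although
`max − min ≥ 0`, the eversion draw can fall below the inversion draw, and
kinetic draws can be physically unrealizable (e.g. a negative loading
rate). The truth table therefore stores two columns: `planted` (the raw
statistical draw; cohort-level means match the configured cells exactly in
expectation) and `realized` (what the waveforms actually encode: the
folded ROM magnitude, the ordered peak pair, and kinetic values truncated
to realizable ranges — VALR to `[max(1, peak/(0.27·T)), peak·rate/5.5]`
BW/s, impact to `[0.2, active − 0.2]` BW, braking to `[−2, −0.005]` BW).
Under the default configuration truncation is rare; at `sd_scale = 0` the
two columns coincide with the cell means. A consequence worth knowing: the
near-zero post-intervention MLA ROM cell mean (0.17, sd 6.86) folds
heavily, so the *waveform-level* cohort attenuates that planted
interaction — the mixed-model recovery properties are therefore stated
(and tested) on the planted draws, which is also how the test suite's
simulation studies are run.

# Preprocessing

* **Filter**: "fourth-order, zero-lag Butterworth" is implemented in the
  dominant biomechanics reading — a 2nd-order design applied forward and
  backward (effective 4th order); `order = 4` selects the stricter
  dual-pass variant. The dual pass squares the magnitude response, so the
  gain at the cutoff is exactly 1/2. Edges are padded by odd reflection
  (`max(3·order, 8 cutoff periods)` samples, capped at the series length)
  and each pass starts at the DC steady state of its first sample, so
  constants pass through unchanged and endpoint transients on short
  stances are negligible. Defaults: 10 Hz for kinematic channels, 80 Hz
  for GRF. Filtering is applied to the derived angle series (equivalent in
  practice to filtering marker trajectories, and it keeps the pose
  interface clean).
* **Events**: heel strike is the first sample at/above 30 N after a
  below-threshold run, toe off the last at/above before the next one.
  The threshold is applied to the filtered vertical GRF by default (raw
  selectable); a hysteresis (minimum 10 ms stance, minimum 50 ms flight,
  boundary gaps always count as flight) rejects force-plate chatter.
* **Normalization**: linear interpolation onto 101 nodes between the
  events; windows can be expressed in seconds so an event found on the
  1,000 Hz force clock maps onto the 200 Hz kinematic clock without
  resampling either signal first.

# Discrete outcomes

Definitions follow the conventional forms: MLA ROM = max − min over
stance; inversion/eversion peaks = min/max of the shank–calcaneus frontal
angle; vertical impact peak = first local maximum of the vertical GRF
within the first 30 % of stance (plateau-aware, so an exactly flat sampled
peak is found at its first sample), in body weights with
`BW = mass × 9.80665` N; VALR = the secant slope between the 20 % and 80 %
points of the contact-to-peak interval (a least-squares variant is
selectable, both readings exist in the literature); peak braking = the
in-stance minimum of the anterior-posterior force (posterior negative; a
convention flag handles posterior-positive data). A missing impact
transient (forefoot-striker pattern) propagates as `NA` with a `missing`
attribute and is excluded listwise from that outcome's model. A
contact-to-peak interval under 5 samples is treated as a resolution error
rather than silently producing a meaningless slope.

With filtering enabled, extracted kinetics are *not* numerically identical
to the planted values: an 80 Hz low-pass rounds the impact plateau and
shallows the rise, attenuating VALR by roughly a quarter under the default
waveform. This mirrors what filtering does to real force data. The exact
planted-recovery contract is defined — and tested — on the unfiltered
path (`filter = FALSE`, `detect_on = "raw"`), where there is no noise to
remove.

# Mixed-model inference

Each outcome is fitted with `value ~ group * time + (1 | subject)` by REML
(lmerTest), i.e. fixed group, time and group × time plus a random
participant intercept — the standard pre/post RCT model. A
"participants and time as random effects" formulation cannot carry the
fixed interaction that is the primary comparison, so time is fixed; a
random time-slope option exists for sensitivity analysis. The interaction
Wald test uses Satterthwaite degrees of freedom (the covariance structure
and df method of the original closed-source implementation are not
recoverable, so the most widely accepted default was chosen and
documented). Estimated marginal means come from emmeans with Bonferroni
adjustment of the pairwise family. A singular random-intercept fit falls
back to ordinary least squares with a note — in that case the estimates
coincide with the two-way fixed-effects ANOVA. Cohen's d is computed
between groups at the post assessment from the raw summaries with the
n-weighted pooled sd (a change-score d is a selectable alternative
computation path via the raw summaries), and labelled negligible/small/
medium/large at 0.2/0.5/0.8.

# 1D statistical parametric mapping

Scalar channels are compared with node-wise t fields (pooled-variance or
paired) and one-way ANOVA F fields; the three-plane joint rotations with
node-wise Hotelling T² vector fields (pooled within-group covariance, or
the one-sample form on paired differences; a singular node covariance is
ridge-stabilized with a warning). Family-wise inference uses random field
theory:

* **Smoothness**: `FWHM = sqrt(4 log 2) / RMS gradient` of unit-variance
  residuals, gradient pooled over the node intervals with the adjacent
  node variances averaged in the denominator; zero-variance nodes are
  excluded with a warning.
* **Threshold**: the smallest `u` with
  `EC0(u) + resels · EC1(u) = α` (α/2 per tail for two-sided t — the
  default, since group differences in either direction are of interest),
  `resels = (nodes − 1)/FWHM`, using the standard 1D
  expected-Euler-characteristic densities for Gaussian, t and F fields;
  T² is thresholded through its exact monotone F transform
  (`F = (ν − p + 1)/(ν p) · T²` with `(p, ν − p + 1)` df). The root is
  bracketed and solved to 1e-6. As FWHM → ∞ the threshold approaches the
  pointwise quantile, as it must. At FWHM near one node the continuum
  threshold slightly *exceeds* the discrete Bonferroni bound — that is a
  property of the continuum approximation, not a bug, and irrelevant at
  the smoothness of filtered gait trajectories (FWHM ≳ 15 nodes).
* **Clusters**: maximal suprathreshold runs, reported as stance-percent
  intervals with cluster-extent p-values from the classic 1D Gaussian
  cluster approximation (secondary descriptive output; set-level
  inference is deliberately omitted).
* **Post hoc**: after a significant T² field, component t fields are run
  at a Šidák-adjusted level with k = 3 components (the number of planes of
  that joint — the defensible reading; k is an argument where another
  family is wanted).
* **Permutation oracle**: `permutation_threshold()` computes the
  `(1 − α)` quantile of the max-statistic distribution over label
  permutations (independent designs) or sign flips (paired), deterministic
  under its seed. It exists both as a user-facing nonparametric option
  (`method = "perm"`) and as the in-suite validation of the parametric
  threshold.

## Validation as run by the test suite

The suite validates the statistical machinery at these problem sizes
(chosen to give Monte-Carlo standard errors comfortably below the margins
being asserted): node-wise field oracles on 50 random datasets; FWHM
recovery on kernel-smoothed noise (120 replicates of 10 × 101 fields,
kernel FWHM 20); family-wise error of the RFT threshold on 2,000 null
two-sample problems (10 + 10 subjects, 101 nodes, FWHM 20) asserted inside
[0.035, 0.065]; RFT vs 5,000-permutation threshold agreement within 5 %;
mixed-model recovery of the planted −5.28° difference-in-differences over
500 simulated cohorts (mean estimate within 0.5°, 95 % CI coverage in
[92 %, 98 %]); and a 20-seed null pipeline with per-outcome significance
counts held to the binomial(20, 0.05) envelope.

# Known limitations

* The generator emulates statistical structure (cell means, between-subject
  correlation, smooth trajectory variability), not biophysics: no
  soft-tissue artifact, no muscle–tendon dynamics, no marker-placement
  error model, no C3D ingestion (the pose/marker interface is the
  adapter point for real data). Passing tests demonstrate correctness of
  the *analysis*, not realism of any particular waveform shape.
* Normal cell summaries for sign-constrained outcomes (ROM) are
  internally inconsistent at small means; see "Planted vs. realized
  truth" above.
* Filtered-path kinetic extraction is attenuated relative to planted
  values by design of the filter itself; exactness claims hold on the
  unfiltered path.
* RFT thresholds assume stationary smoothness; non-stationary corrections
  and 2D/3D SPM are out of scope. The permutation path is the recommended
  fallback when stationarity is doubtful.
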