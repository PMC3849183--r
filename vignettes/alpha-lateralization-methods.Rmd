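---
title: "Methods: simulating and analysing posterior alpha lateralization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing posterior alpha lateralization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During covert visual spatial attention — attending to a peripheral
location while fixating centrally — posterior alpha oscillations
(8–14 Hz) desynchronize in the hemisphere contralateral to the attended
hemifield and synchronize ipsilaterally. Two derived quantities
summarise this pattern. The per-sensor **alpha modulation**

$$AM = \frac{P_{\mathrm{left}} - P_{\mathrm{right}}}
            {P_{\mathrm{left}} + P_{\mathrm{right}}}$$

contrasts the mean alpha power during attend-left versus attend-right
trials, normalizing away between-subject power scale. The scalar
**alpha lateralization**

$$AL = \overline{AM}_{\mathrm{left\ ROI}} - \overline{AM}_{\mathrm{right\ ROI}}$$

averages the modulation over a data-defined region of interest (ROI) in
each hemisphere and takes their difference. `alphalat` implements the
complete analysis chain around these statistics — trial rejection,
synthetic planar gradients, sliding-window Hanning-taper spectral
estimation, within-subject cluster-based sign-flip permutation
inference over sensors and time, repeated-measures ANOVA, and
single-trial left/right decoding — together with a synthetic-data
generator that emulates the experimental design (a 2 × 2 within-subject
design, task difficulty × target eccentricity, with balanced left/right
attended hemifields), so every stage can be verified against known
ground truth without access to the original recordings.

## The synthetic-data generator

`generate_dataset()` produces per-subject trials of multichannel data
(sensors × samples) on a mirror-symmetric 2-D sensor layout
(`make_sensor_array()`), spanning a 1 s pre-cue baseline, a 0.5 s cue
period, a variable pre-target period, and 1 s after target onset, at
300 Hz.

**Pre-target periods** follow a 90/10 mixture of range-limited
exponentials: 90% on [2, 3] s and 10% on [0.5, 2) s with mean 0.8 s.
A strictly decaying density on [2, 3] cannot have mean 2.5 s (its
truncated mean is below the midpoint), so the long component's decay
rate is a configuration parameter whose default 0 is the uniform limit,
giving mean exactly 2.5 s; the short component's rate is solved
numerically so its truncated mean equals the 0.8 s target.

**The planted effect.** Posterior-band sensors (the lower third of the
layout, per hemisphere) carry a 10 Hz oscillation with random phase per
sensor and trial and lognormal trial-to-trial amplitude jitter. From
0.2 s after cue onset the oscillation's envelope ramps linearly,
reaching its plateau at `onset_ramp` (default 0.6 s; the attention
literature reports lateralization "shortly after cue onset", so the
exact waveform is a modelling choice): the amplitude drops by a
fractional `contra_decrease` contralateral to the attended hemifield
and rises by `ipsi_increase` ipsilaterally, each with separate easy and
difficult levels. A `hemisphere_asymmetry` factor (default 1.3) boosts
the left-hemisphere effect during right-hemifield attention, emulating
the left-hemisphere dominance of attention shifts to the right. 1/f
background noise (spectral exponent 1) plus white sensor noise is added
on all sensors. `eccentricity_effect` defaults to 0 — the study design
this emulates found no eccentricity effect, and the generator's null
must reproduce that.

**Calibration.** Only derived lateralization values are reported for
the original recordings, never sensor-level effect amplitudes, so the
generator's amplitudes are calibrated, not copied: with
`contra_decrease = (0.055, 0.085)`, `ipsi_increase = (0.028, 0.043)`,
`alpha_amplitude = 1`, `pink_sd = 2`, `white_sd = 0.5`, the full
pipeline recovers grand-average AL of roughly 0.11 (easy) and 0.18
(difficult) and single-subject decoding accuracy near 64% — the same
order, ordering and decodability regime as the empirical values — while
keeping the difficulty effect detectable at the reduced trial counts
used in the test suite. A variant scaled to 70% of these effects
reproduced AL ≈ 0.10/0.13 but left the within-subject difficulty
contrast underpowered at desk scale, and was rejected for that reason.

**Behaviour.** Correctness is drawn from a two-alternative forced-choice
Weibull psychometric function with guessing floor 0.5 and base 2, so
accuracy is exactly 0.75 at threshold contrast; the easy condition uses
the contrast at which the function reaches 0.96 (matching observed
easy-condition accuracy; the nominal full-contrast intent is ~100%).
Reaction times are shifted lognormal (shift 0.2 s, log-SD 0.35) with
means 0.571 s (easy) and 0.763 s (difficult); `rt_sigma = 0` collapses
the distribution onto its mean, which the tests exploit.

**What the generator does not emulate.** Effects are planted at sensor
level — there is no dipole forward model, no head geometry, no
physiological alpha waveform beyond a stationary sinusoid with an
envelope, no eye-movement-related fields, no sensor dropout, and
between-subject effect heterogeneity is limited to sampling noise.
Passing tests therefore demonstrate the correctness and calibration of
the *analysis*, not the realism of MEG physics; conclusions about real
recordings still require real recordings.

## Preprocessing

The rejection cascade applies, in order: minimum pre-target filtering
(inclusive at 2.0 s) with per-channel demeaning; reaction-time
rejection with strict bounds (<0.3 s, >2 s — values exactly at a bound
survive); gaze rejection (radial deviation from the pre-cue mean
position exceeding 2° continuously for more than 0.05 s inside the
1–2.5 s post-cue window; the pre-cue re-referencing makes the rule
insensitive to constant drift); and broadband power-outlier rejection
(per-trial mean squared amplitude in the same window, beyond 3 SD of
the subject's trial distribution; zero variance removes nothing, since
no trial "deviates"). Broadband rather than band-limited power is used
for the outlier rule. Each rule reports per-subject counts and
fractions relative to the trials entering it, so the cascade conserves
totals.

Anti-alias filtering for `downsample()` uses a Blackman windowed-sinc
FIR with cutoff at 0.85 and transition width 0.10 of the target Nyquist
frequency, applied zero-phase via its symmetric kernel with
anti-symmetric edge reflection: components up to 0.8 of the target
Nyquist survive within 1%, and out-of-band components are attenuated
far beyond 40 dB.

The **synthetic planar gradient** estimates, per sensor, the field's
spatial derivative along the two layout axes by a weighted
least-squares plane fit to the differences with neighbouring sensors
(weights inverse to layout distance). The fit is exact for spatially
linear fields, maps uniform fields to zero, and is linear in the data,
which the tests verify directly. No specific algorithm is canonical for
this step; inverse-distance-weighted neighbour differences are the
simplest estimator with those guarantees.

## Spectral estimation

`sliding_alpha_power()` slides a 0.5 s Hanning-tapered window in 0.05 s
steps and evaluates the DFT at the band's bin centres. A 0.5 s window
has exactly 2 Hz native resolution, so "8–14 Hz in 2 Hz bins" is
realized as the four native centres {8, 10, 12, 14} Hz (centres
{9, 11, 13} would not be native bins of this window), averaged with
equal weights. Power is normalized by the squared sum of the taper, so
a unit tone at a bin centre contributes power 1/2 there regardless of
the window length. Time stamps are window *centres* (not starts), which
aligns power symmetrically with the attention epoch. The two planar
components are combined by summing their powers — the field-standard
convention — which is exactly invariant under rotations of the gradient
axes. Baseline z-normalization for timecourse analyses pools the
−0.75 … −0.25 s pre-cue window over both hemisphere series and all
trials of a subject into one affine transform, making standardized
series invariant to subject-specific power scale.

## Inference

The **cluster-based sign-flip permutation test** forms per-element
(sensor or time-step) one-sample t statistics, thresholds them
two-sided at the t quantile for `cluster_alpha = 0.05` with N−1 df (the
threshold is a tunable, not part of the controlled error rate), groups
suprathreshold elements of equal sign into connected clusters (sensor
neighbour graph, or temporal contiguity), and scores each cluster by
the sum of its t values. The null distribution records the maximum
absolute cluster mass under random whole-map sign flips per subject.
With `2^N ≤ 4096` all flips are enumerated exactly; otherwise `n_perm`
random flips including the identity are used, so p ≥ 1/`n_perm` and
p-granularity is 1/`n_perm`. Zero-variance elements receive t = 0.
ROIs are the significant clusters' sensors split by hemisphere, with
midline sensors excluded; condition means enter the ROI-defining map
unweighted by trial counts.

The 2 × 2 repeated-measures ANOVA is computed from per-subject contrast
scores, giving F = t² with (1, N−1) df per effect — the exact
decomposition for a balanced two-level within-subject design. N−1 is
the correct within-subject error df; published F statistics from
N = 14 subjects quoted with 14 denominator df follow a different df
convention that this package deliberately does not chase. The Wilcoxon
signed-rank companion uses the exact distribution up to 25 untied
non-zero differences and the continuity-corrected normal approximation
otherwise; binomial intervals are Clopper–Pearson.

## Decoding

Features are the natural logs of the window-averaged (1–2.5 s) combined
planar alpha power, on sensors selected per subject by a
leave-subject-out ROI definition (the held-out subject's data never
influences their own selection; if the reduced cohort yields no
significant cluster, all non-midline sensors are used and the fallback
is flagged). Classification is a linear maximum-margin classifier
(C-SVM, hinge loss) evaluated by ten sequential contiguous outer folds
— the generator interleaves hemifield labels, so sequential folds
always contain both classes — with an inner sequential cross-validation
(5 folds; the inner fold count is not canonical and is configurable)
selecting the cost from a 7-point logarithmic grid spanning
10⁻³ … 10³, ties resolved toward stronger regularization. The SVM is
solved by dual coordinate descent (the liblinear algorithm) compiled
via Rcpp with a deterministic internal shuffle; SMO-based solvers need
orders of magnitude longer at weak regularization on non-separable
standardized features, which makes replicate studies impractical, and
the test suite cross-checks predictions against an independent libsvm
implementation.

## Numerical choices and degenerate inputs

* Window centres are anchored to the step grid at cue onset; closed
  intervals use a 10⁻⁹ tolerance at their endpoints.
* The modulation index refuses sensors where both powers are zero and
  rejects negative powers.
* Lateralization refuses empty ROIs rather than silently returning NA.
* `svm_linear` standardizes features with training-set statistics only.
* Pipeline stages abort with stage-tagged errors
  (`[simulate] …`, `[stats] …`), and a single global seed is fanned out
  to fixed per-stage child seeds.

## Simulation sizes

The validation studies run at sizes chosen to make their Monte-Carlo
error explicit and their runtime reasonable on a single CPU:
calibration of the permutation test uses 200 null datasets of
14 subjects × 30 sensors with 500 randomizations; chance-level decoding
uses 50 null replicates of 160 trials; effect-size recovery uses a
4-point effect grid × 20 seeds of 4-subject datasets with the ROI fixed
to the planted posterior band (ROI selection cannot run at zero
effect); design sensitivity uses 20 replicates of the full 14-subject
design at 12 trials per condition. The generator's own defaults remain
the full study conditions (14 subjects, 110 trials per condition).

## Known limitations

* Sensor-level effect planting means source-space claims are out of
  scope by construction.
* The mirror-symmetric layouts are idealized; real axial-gradiometer
  layouts are only approximately symmetric, and dropped-out sensors are
  not modelled.
* The permutation p-value floor (1/`n_perm`, or 2/2^N under exhaustive
  enumeration with its sign-symmetric null) means cohorts below
  6 subjects can never reach p < 0.05.
* The decoder's sequential folds follow presentation order; datasets
  whose labels are not interleaved would need stratified folds instead.
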