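---
title: "Detecting helmeted head impacts from instrumented-mouthguard kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting helmeted head impacts from instrumented-mouthguard kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactkit)
```

## The problem

Instrumented mouthguards trigger a recording whenever linear acceleration
exceeds 10 g, capturing a 100 ms window (10 ms pre-trigger, 90 ms
post-trigger) of triaxial linear acceleration and angular velocity at
1000 Hz, together with an infrared (IR) proximity reading that indicates
whether the tray sits on the upper dentition. On a football field most
triggers are *not* head impacts: device handling, chewing, biting and
sensor noise all clear 10 g. Simple peak-acceleration thresholds cannot
separate these from true helmet contacts because the peak-amplitude
distributions of the two classes overlap almost completely. impactkit
implements a detection pipeline that works instead from the *structure* of
the signal: 411 engineered features spanning the time domain, the
frequency domain, a time-frequency decomposition, and a mechanistic
head-neck model, feeding a radial-basis-function support vector machine
(RBF-SVM) trained under leave-one-out cross-validation (LOOCV) with
sequential forward feature selection.

## Data model and preprocessing

A `recording` holds one triggered window: 3 x 100 linear acceleration (g),
3 x 100 angular velocity (rad/s), one IR reading, and a trigger timestamp
with 1 s resolution. `preprocess_recording()` converts it to the
anatomical frame (AP = +anterior, LR = +left, IS = +superior,
right-handed; angular channels are rotations about AP/LR/IS, i.e. the
coronal, sagittal and horizontal planes):

1. **Rotation** by the per-subject calibration matrix (orthonormality
   checked to 1e-8).
2. **Zero-phase low-pass filtering** at each sensor's bandwidth: 4th-order
   Butterworth applied forward-backward, with odd-reflection padding and
   steady-state initial conditions so a 100-sample record has no edge
   transients. Phaseless filtering follows impact-biomechanics practice
   (SAE J211-style) and doubles the effective order; this is documented
   because the causal/zero-phase choice is otherwise open. The 500 Hz
   accelerometer cutoff equals Nyquist at 1000 Hz, where a Butterworth
   design is degenerate; cutoffs at or above 0.99 x Nyquist pass the
   series through unchanged. The 184 Hz gyroscope cutoff is applied
   normally.
3. **Integration** of linear acceleration (g converted at 9.80665 m/s^2)
   by the cumulative trapezoid rule with zero initial velocity. Gravity is
   not subtracted: a 10 g-triggered 100 ms window does not resolve the
   gravity vector, and all derived quantities treat the window as
   gravity-unresolved.
4. **Differentiation** of angular velocity by the five-point central
   stencil (exact through degree-4 polynomials). The outermost two samples
   on each side use one-sided 4-point and 2-point differences so the
   series keeps its 100-sample length without padding artifacts.
5. **Vector magnitudes** of all four quantities.

Linear acceleration is deliberately *not* transformed to the head centre
of gravity at this stage, so linear and angular feature blocks stay
uncoupled; only the head-neck model applies the rigid-body transform.

## The 411-feature registry

The registry (`feature_registry()`) is ordered and versioned; selection
tie-breaks and serialized tables depend on that order.

* **Time domain (24).** Peaks of linear acceleration, linear-velocity
  change, angular acceleration and angular-velocity change per anatomical
  component and magnitude (directional peaks use |x|; directional "change"
  is max - min; the magnitude change is the maximum of the magnitude
  series, which starts at zero for integrated velocity), plus
  full-width-at-half-maximum impulse durations of linear and angular
  acceleration (sub-sample linear interpolation of the half-max crossings,
  clamped at window edges; an all-zero series is a flagged 0).
* **PSD (152).** One-sided rectangular-window periodogram without
  detrending: with 100 samples at 1000 Hz the DFT bins land exactly on the
  10 Hz grid, so "PSD at 10-200 Hz (linear) and 10-180 Hz (angular) in
  10 Hz intervals" needs no interpolation. The one-sided density scaling
  satisfies Parseval (sum x bin width = mean square); power density was
  chosen over amplitude spectrum as the unit. The 180 Hz angular ceiling
  reflects the gyroscope bandwidth; 200 Hz keeps about six samples per
  period for the accelerometer.
* **Wavelet (152 + 32).** Continuous Morlet transform (analytic Morlet,
  centre frequency omega0 = 6, L2-normalized, moduli as amplitudes, no
  cone-of-influence masking on a 100 ms window) on the same channel and
  frequency grids. Per-frequency features are maxima over time; the four
  per-channel descriptors are the global peak amplitude, its frequency,
  its timing relative to the channel's time-domain peak, and the 10%
  bandwidth — the ascending distance from the peak frequency to the first
  grid point whose time-maximal amplitude falls below 10% of the global
  maximum, capped at the grid ceiling. Zero channels yield flagged
  degenerate descriptors (0, lowest frequency, 0, 0).
* **Head-neck model (51).** See below.

## The head-neck linkage model

The model is a two-link chain: a head rigid body joined to a neck link of
length 10.8 cm by a universal joint — rotation about LR (atlanto-occipital
flexion/extension) then about IS (atlanto-axial axial rotation) — with the
head centre of gravity 5 cm above the joint. Head pose over the window is
integrated from the signals (exponential-map orientation updates with
midpoint angular velocity; double trapezoid integration of world-frame CoG
acceleration after the rigid-body lever-arm transform
`a_cog = a + alpha x r + omega x (omega x r)`). The mouthguard-to-CoG
lever arm is a calibration input; the default places the bite plate 7 cm
anterior and 7 cm inferior of the CoG.

Given the head pose, the universal angles determine the neck orientation
(`R_neck = R_head Rz(-theta_IS) Ry(-theta_LR)`), leaving a two-parameter
family; the solver picks the member minimizing the distance between the
torso-base point and its t = 0 position — the massive-torso assumption —
by bounded quasi-Newton minimization per sample, warm-started from the
previous sample, with both angles restricted to (-pi/2, pi/2). The
neutral anchor (base directly below the initial joint along the initial
head IS axis) makes the solution covariant under global rigid rotations.
Note one geometric consequence of the constraint: a pure head translation
is explained by *tilting* the joint toward the displaced position, giving
a base offset of sqrt(shift^2 + L^2) - L rather than the full shift.

Features: sign-match percentages between each head-neck angle and the
same-plane neck angle (|angle| < 1e-3 rad counts as matching either sign,
so a stationary window scores 100%), peak absolute angles/velocities/
accelerations of the five angle series, peak displacement/velocity/
acceleration of the torso-base, head-base and head-CoG points, per-axis
CoG displacement and velocity peaks, peak base offset, and 18
coupling-ratio statistics: angular acceleration about each axis divided
per-sample by linear acceleration along each normal axis (six series;
mean, SD, peak |ratio| each), excluding samples whose denominator is
below a 0.5 g deadband (all-excluded series give flagged zeros). The
pairing of sign-match angles and the exact enumeration of this block are
the least-constrained part of the published description; the registry
documents one consistent realization totalling 51.

## IR placement thresholding

Per subject-event, a two-component 1-D Gaussian mixture is fitted to the
IR readings by EM with deterministic initialization (means at the
25th/75th percentiles, equal weights), and the on/off-teeth threshold is
the weighted-density crossing between the component means; classification
is inclusive at the boundary (reading >= threshold is on-teeth). The fit
is flagged degenerate — with a midpoint-of-means fallback — when the means
are closer than the pooled SD *or* when the fitted mixture has no
meaningful valley between the means (crossing density at least half the
smaller mode density). The second test matters in practice: EM will
happily carve a narrow, low-weight component out of unimodal data, which
the separation rule alone cannot catch.

## Ground-truth construction

Video review yields labeled intervals (helmet contact with a direction,
body contact, no contact, idle, obstructed, no view). Because the
mouthguard clock has 1 s resolution and synchronization adds error, a
recording matches an interval if the interval dilated by +-2 s contains
its trigger time. The selection rules are conjunctive:

* **Impacts**: on-teeth, matched to a helmet-contact interval, kinematics
  consistent with the video direction, and not dominated by
  high-frequency noise.
* **Nonimpacts**: on-teeth, strictly inside an *undilated* no-contact or
  idle interval (dilation exists only to catch clock skew on impacts),
  and matching no contact/obstructed/no-view interval under dilation.
* Everything else is excluded from both classes.

Direction consistency maps each video direction to a 90-degree cone about
an anatomical axis, on the convention that the head accelerates away from
the impacted surface (frontal -> -AP, rear -> +AP, left -> -LR,
right -> +LR, top -> -IS); the recording passes if either the
acceleration vector at the magnitude peak or the end-of-window velocity
change lies in the cone. The 45-degree half-angle and the sector map are
configurable because video conventions vary. The noise check compares
linear-acceleration periodogram power above vs at-or-below 200 Hz, summed
over the three components: content above 200 Hz is undersampled at
1000 Hz and indicates electronics noise. The component sum is used
rather than the magnitude series because rectification folds oscillation
power into DC and would mask exactly the high-frequency content the rule
exists to catch.

## Classifier protocol

The RBF-SVM (soft margin C = 1, gamma = 1/d on standardized features —
the published work does not state its hyperparameters, so common defaults
are exposed as configuration and recorded in the serialized model)
classifies at decision value 0. Standardization statistics always come
from the training rows of the fold at hand, so LOOCV values never touch
the held-out sample. Sequential forward selection scores every candidate
feature set by the LOOCV cost (1 - ROC area, or 1 - F-measure at the zero
threshold), accepts the best strictly improving candidate, breaks ties
toward the lowest registry index, and stops at no strict improvement or
10 features. Degenerate folds (single-class training sets) score 0 and
are flagged rather than dropped, conserving n. ROC and precision-recall
curves sweep the unique scores with ties grouped; areas are trapezoidal,
with the PR curve's recall-0 endpoint extended at the first precision
value (one of several conventions; documented). Reported percentages
round half-away-from-zero to one decimal. The baseline comparator
thresholds the peak linear-acceleration magnitude over its observed range
— the conventional impact-registration rule.

## Feature screening statistics

Two-sided unpaired Wilcoxon rank-sum per feature (exact null when the
smaller sample has at most 8 tie-free observations, normal approximation
with tie and continuity corrections otherwise — the regime switch is an
implementation choice), Bonferroni-corrected over the full 411-feature
family (threshold 0.05/411, about 1.2e-4; strict inequality; degenerate
features enter with p = 1), PCA of the standardized feature matrix
(zero-variance columns dropped with a warning; top contributors ranked by
absolute loading), and Pearson correlation matrices (undefined
correlations reported as flagged zeros).

## The synthetic cohort generator

`generate_cohort()` is the package's study-conditions module: every
pipeline stage is testable without access to field data. It emulates:
10 g-triggered 100 ms windows; **impacts** as direction-consistent
half-sine pulses (amplitudes 10-65 g around a 22 g mean via a truncated
shifted exponential, durations 8-30 ms, hence fundamentals roughly
17-60 Hz) with coherent same-plane angular-velocity pulses (changes
1.6-26 rad/s) and, in half of draws, 100-200 Hz damped ringing on both
sensors standing in for helmet-shell and mandible dynamics;
**nonimpacts** as multi-axis 120-350 Hz damped oscillation bursts
(decays 2-25 ms, amplitudes 10-104 g around an 18.5 g mean) mixed with
brief bite/clack spikes and a low-amplitude handling swipe (0.3-2.5 g,
30-80 ms), with angular content band-limited to the gyroscope's range;
**off-teeth** recordings reusing the nonimpact signal model with low-mode
IR draws; bimodal IR readings six pooled SDs apart; and +-1 s clock skew
at 1 s timestamp resolution. Additive white noise is 0.5 g and
0.2 rad/s RMS per axis — small against the 10 g trigger. Impact direction
jitter (<= 20 degrees) plus bounded off-axis pulse content (<= 0.35 of
the pulse) guarantees planted impacts pass their own direction check, so
ground-truth recovery on synthetic cohorts is exact up to IR draws, which
the truth table records.

What the generator does *not* emulate: genuine helmet-contact mechanics
(it is phenomenological, not physical), body-contact confounders,
correlated multi-recording events, sensor bias drift, or the real
cohort's exact class geometry. Passing tests on synthetic cohorts
therefore demonstrate the pipeline's internal consistency and the
recoverability of planted structure, not field performance.

One property of the published analysis deliberately does **not** emerge
under these conditions, and the acceptance outputs report it honestly
(`first_feature_low_freq`): on synthetic cohorts the single most
discriminative features are the integrated-displacement model features
and wavelet bandwidth descriptors rather than the 10-30 Hz spectral
features (whose class medians do separate in the expected direction).
The mechanism is structural. Over a 100 ms window the 10 Hz DFT bin is
nearly the net velocity change (X(0) = delta-v), so any nonimpact
population with realistic velocity changes blunts low-frequency PSD
exactly as much as the delta-v features; the rectified magnitude channel
folds the nonimpact oscillation envelope into the 0-30 Hz range; and
uniformly sampled impact directions dilute every directional channel.
Making the spectral features dominate would have required implausible
surgery on the nonimpact class (removing its velocity changes entirely),
which was rejected in favor of reporting the ordering as it falls out.
The published cohort's ordering plausibly reflects structure — directional
concentration of impacts, activity-specific artifact spectra — that a
phenomenological generator does not claim to reproduce.

## Numerical choices and degenerate inputs

Tolerances: rotation orthonormality 1e-8; linkage solver convergence
factr = 10 (about 1e-15 relative) with warm starts; link-length
conservation is exact by construction. FWHM of an all-zero series, PSD of
a zero signal, wavelet descriptors of a zero channel, coupling ratios
with all-deadband denominators, correlations of constant columns, and
single-class LOOCV folds all return flagged zeros/defaults rather than
NaN, so feature vectors are always finite. Determinism: preprocessing and
feature extraction are bitwise deterministic; EM initialization is
quantile-based; libsvm's SMO solver is deterministic for a fixed row
order and order-invariant to its working tolerance (1e-3).

## Problem sizes in the test suite

The default cohort used by the end-to-end tests and the acceptance script
is 60 impacts + 60 nonimpacts + 100 off-teeth recordings with 3 no-view
confounders, comparable to the published cohort after IR filtering; unit
tests use 3-45 recordings. IR-recovery checks use 100 replicates of
8000 readings (tests) and 20 (acceptance script). These sizes were chosen
to exercise every rule at meaningful sample sizes while keeping the full
suite runnable on a laptop in well under half an hour.

## Limitations

The registry's model-block enumeration realizes a block structure the
published supplement describes only in outline; other enumerations of the
same 51 slots are possible. SVM hyperparameters, Morlet normalization,
PR-curve endpoint convention, and the rank-sum regime switch are
documented choices, not published facts. The linkage model is kinematic
only (no muscle forces, no gravity) and its lever arm must come from
device calibration. Serialized models are tied to the registry version;
tables and models from other registry versions are refused rather than
coerced.
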