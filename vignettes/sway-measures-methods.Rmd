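---
title: "Assessing working postural stability from wearable accelerometers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing working postural stability from wearable accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaylab)
```

## The problem

Quiet-stance body sway is the classical window onto postural control.
Force-plate center-of-pressure (COP) trajectories are the traditional
measurement, but wearable inertial sensors (IMUs) make acceleration-based
sway quantification cheap and field-deployable, which matters for
occupational settings — construction and masonry work impose non-erect
postures, inclined surfaces and load carriage, all of which stress balance.
`swaylab` implements the full analysis chain for evaluating how well
accelerometer-based sway measures capture working postural stability:

1. a **synthetic-study generator** that emulates a within-subject
   6 postures x 2 surfaces x 2 loads factorial experiment with coupled
   accelerometer, COP and subjective-rating outputs,
2. **preprocessing** (zero-phase Butterworth low-pass, gravity removal,
   directional decomposition),
3. a registry of **43 sway measures** per sensor and trial,
4. a **factor-effect detection battery** (three-way repeated-measures
   ANOVA with sphericity handling, paired t-tests, detection counts), and
5. a **stable/unstable classification grid** over sensor configurations,
   feature sets and a roster of eleven classifiers, scored by stratified
   5-fold cross-validation.

## The sway-measure registry

All measures operate on the filtered, per-axis mean-centered tri-axial
acceleration of one sensor over one 10-s trial, decomposed into
anterior-posterior (AP), medial-lateral (ML) and inferior-superior (IS)
axes plus the planar (2DR) and spatial (3DR) resultant magnitudes. The 43
measures span twelve families: mean absolute amplitude (AVG, 5
directions), range (RNG, 5), root-mean-square (RMS, 5), sway areas
(ARE_SW, ARE_CC, ARE_CE), fractal dimensions (FD_CC, FD_CE), trajectory
length (LEN, 4), mean distance (MD, 4), spectral mean frequency (MF, 4),
mean velocity (MV, 4), planar deviation (PD_P, PD_V), the phase-plane
parameter (PP) and RMS distance (RMSD, 4).

Key formulas, following the classical COP-measure definitions transplanted
to acceleration signals:

* the 95% confidence circle area is
  $\pi\,(MD_{2DR} + z_{.05}\, s_{RD})^2$ with $z_{.05} = 1.645$ and
  $s_{RD}$ the SD of the planar resultant distances;
* the 95% confidence ellipse area is
  $2\pi F_{.05}[2, n-2]\sqrt{s_{AP}^2 s_{ML}^2 - s_{APML}^2}$, using the
  exact F quantile (which tends to 3.0 for long records);
* the fractal dimension is $\ln N / \ln(N d / L)$ for an $N$-point planar
  trajectory of length $L$, with the characteristic diameter $d$ taken
  from the confidence circle (FD_CC) or from the circle of area equal to
  the confidence ellipse (FD_CE);
* the spectral mean frequency is the power-weighted mean of the one-sided
  periodogram with the DC bin excluded.

Decisions taken where the family definitions leave latitude:

* **AVG on axis directions** is the mean *absolute* signal: after gravity
  removal the raw mean is ~0 and would carry no information. The flag
  `avg_raw` in `measure_opts()` restores literal raw means. On 2DR/3DR the
  resultant is nonnegative and the plain mean is used.
* **"Per unit of time"** for the three areas is honored by dividing by the
  trial duration; a flag disables the normalization (the classical
  definitions are not time-normalized).
* **Second moments** about the trajectory center are population moments
  (divide by $n$), so that the identity
  $RMSD_{2DR}^2 = RMS_{AP}^2 + RMS_{ML}^2$ holds exactly on centered axes.
* **Integration** for the MV/PD/PP families is cumulative trapezoidal,
  followed by linear detrending to suppress drift — deterministic,
  parameter-free and testable against closed forms, unlike a high-pass
  alternative. Displacement integrates the detrended velocity the same
  way. PP is computed on the sagittal (AP) direction.
* **Degenerate inputs** (zero-variance trajectories) yield `NA` for
  FD/MF rather than silent zeros; the detection stage counts exclusions
  explicitly.

The single COP-based reference measure, `copv_ap()`, is the total AP path
length of the filtered COP trajectory divided by the trial duration
(mm/s).

## Preprocessing

The paper-level specification of "fourth-order zero-phase low-pass
Butterworth" is read as *effective* order 4: an order-2 design applied
forward and backward (`literal_order = TRUE` gives the other reading).
Ends are protected by odd-reflection padding of length `3 * order`, and
each pass starts from the filter's steady state for the first padded
sample, so constants are reproduced exactly. The cutoff is not fixed by
the source description; the default is 10 Hz for both the 240 Hz
accelerometer stream and the 40 Hz COP stream, comfortably above the
< 3 Hz band where quiet-stance sway energy lives, and configurable.
Gravity is handled by per-axis mean removal over the trial — trials are
static postures, so gravity is a constant per-axis offset.

## The synthetic-study generator

No raw data accompany the source study, so the generator is the package's
test bed. It emulates the *structure* of the experiment, not its
physiology. Each trial draws a latent instability
$I = \exp(\eta)$ from a log-linear model

$$\eta = \mu + \beta_{WP}[p] + \beta_{SS}\,\mathbb{1}\{\text{inclined}\} +
\beta_{LC}\,\mathbb{1}\{10\,kg\} + \text{interactions} + b_s +
u^{WP}_s[p] + u^{SS}_s[\text{srf}] + u^{LC}_s[\text{load}] + c_{s,cond}
+ \epsilon,$$

with a subject random effect $b_s$, factor-specific subject
susceptibilities $u^{WP}_s, u^{SS}_s, u^{LC}_s$ (each subject responds
differently to postures, slopes and loads — stable across repetitions),
an unstructured subject-by-cell effect $c_{s,cond}$, and trial noise
$\epsilon$. The susceptibilities are the error terms of the corresponding
within-subject F tests, so their SDs control detection power factor by
factor. The latent drives every output coherently:

* each accelerometer channel is band-limited Gaussian noise (zero-phase
  band-pass filtered white noise, default 0.1–3 Hz) whose sample SD is
  `sensor_gain * I` — the pelvis carries the largest gain;
* the passband's upper edge scales as
  $\exp(\texttt{freq\_coupling} \cdot (\eta - \mu))$, so unstable
  conditions sway *faster* as well as *larger*. Without this coupling the
  scale-invariant measures (FD, MF) could detect nothing, contradicting
  the finding that every measure detects the posture effect;
* the COP trajectory is its own band-limited process sharing $I$
  (not a double-integrated acceleration, which would add drift);
* the 0–10 perceived-stability rating is
  $\mathrm{clip}(\texttt{intercept} + \texttt{slope}\cdot\eta +
  \text{noise},\, 0, 10)$, continuous by default with an option to round
  to the 11-point scale.

Default effect sizes follow the published pattern: `beta_lc = 0.6` (large
load effect), `beta_ss = 0.1` (small surface effect), posture offsets
spread over 0–0.8, posture-by-load interactions up to 0.25 and
surface interactions near zero. The susceptibility SDs (0.25 for posture,
0.3 for surface and load, 0.25 unstructured) are sized by paired-t power
arithmetic so that at the default 30-subject design the posture and load
effects are detected by essentially every measure (per-measure power ~1)
while the surface effect is only marginally detectable (study-level power
~0.4) — the qualitative signature reported for the real study. One
consequence of the single shared latent: all sensors and measures move
together, so per-study detection counts are closer to all-or-nothing than
the graded per-sensor counts real data produce. Gravity,
sensor noise and orientation drift are *not* simulated; the inclined
surface enters only as an effect size, not as geometry. Consequently,
passing tests demonstrate that the pipeline recovers injected structure —
they say nothing about, e.g., robustness to sensor misalignment on real
hardware.

Every trial draws from an RNG substream derived deterministically from
`(seed, subject, condition, repetition)`, so studies are reproducible
trial-by-trial and package internals never perturb the caller's RNG
state.

## Factor-effect detection

Repetitions are averaged within subject and condition (the design treats
repetition as replication, not a factor), and each of the seven effects
(3 main, 3 two-way, 1 three-way) is tested against its effect-by-subject
interaction in the classical fully-within decomposition. For effects
involving the six-level posture factor, Mauchly's sphericity test is
evaluated on the effect's orthonormal contrast covariance; when violated
at 0.05 the Greenhouse-Geisser epsilon (clamped to [0.2, 1]) multiplies
both degrees of freedom. Two-level effects carry a single contrast and
are exempt. Shapiro-Wilk normality screening is reported per design cell
as a diagnostic only — the analysis path never switches, since the source
procedure names the test but no nonparametric alternative. Detection
counts tally measures with p < 0.05 per sensor and effect without
multiplicity correction (a Holm option exists for the pairwise t-tests
but is off by default, matching the reported procedure).

The implementation computes sums of squares from orthonormal
within-subject contrasts; the test suite cross-checks F statistics
against `aov()` error strata and Mauchly/epsilon against
`stats::mauchly.test()` and `anova.mlm`. Note one nuance the test suite
encodes: the folk rule "the GG correction never increases significance"
is only true in the right tail (F well above 1); near F = 1 the adjusted
p can dip below the unadjusted one by O(1e-3) while both remain far from
significance.

## Stable/unstable classification

Features are computed per sensor and axis on the **raw** acceleration
(the classification stage of the source procedure works on raw data,
unlike the measure pipeline): FS1 = mean, range, variance, SD, RMS,
skewness, kurtosis; FS2 = magnitudes of the five lowest nonzero-frequency
FFT coefficients (DC is excluded because it duplicates the mean feature);
FS3 = both. Sensor configurations: SC1 = all 8 placements, SC2 = pelvis +
sternum + shoulders, SC3 = pelvis + sternum, plus a pelvis-only variant.
Labels come from the subjective rating (stable iff rating < 5, the
boundary rating 5.0 is unstable) or from the COPV_AP median split (the
trial at the median is unstable). Features are z-scored column-wise
(population SD) on the full dataset *before* cross-validation, matching
the stated extract-then-standardize order; this leaks fold statistics,
and a `fold_safe` option refits the standardization inside training
folds for users who prefer the conservative protocol.

Cross-validation is stratified by class; the source does not mention
subject-wise grouping, so trials are treated i.i.d. by default and a
`group_by_subject` option assigns whole subjects to folds for users who
want subject-independent estimates. Per-trial rather than per-task
instances are the default reading of the ambiguous "data set" unit.
Accuracy is (TP + TN)/(P + N) x 100 per fold, averaged.

The roster maps point-and-click classifier names onto open equivalents:
KNN (city-block and Euclidean, k = 5, hand-rolled distance voting since
no installed KNN supports the city-block metric), Gaussian naive Bayes
(`e1071`), kernel-density naive Bayes (per-feature `stats::density`),
logistic regression (`glm`), linear discriminant analysis (`MASS`),
linear and cubic-polynomial SVMs (`e1071`), a decision tree (`rpart`),
bagged trees (`randomForest` with `mtry = p`, 100 trees) and an
"optimized ensemble" that selects `mtry`/`nodesize` for a 100-tree forest
by inner 5-fold cross-validation — a deliberately small fixed grid, since
hyperparameter optimization is out of scope. Exact hyperparameters of the
original toolbox models are unrecoverable; accuracies are comparable in
pattern, not cell-by-cell.

## Problem sizes used by the test suite

The acceptance-level checks run the detection pattern at the full default
design (30 subjects x 24 conditions x 2 repetitions, all 8 sensors), the
ANOVA calibration on 500 replicate latent-level studies of 10 subjects
(the calibration concerns the F machinery, so waveform synthesis is
skipped via `simulate_study(..., signals = FALSE)`), and the
classification grid on a 12-subject pelvis-only study — sizes chosen so
the full suite completes in minutes while keeping every qualitative
conclusion stable under the fixed seeds.

## Known limitations

* The generator's stationary Gaussian sway has no biomechanical content
  (no inverted-pendulum dynamics, no intermittent control, no
  nonstationarity); measures sensitive to such structure (FD, MF) are
  exercised only through the amplitude/frequency coupling.
* Generator magnitudes are order-of-magnitude plausible, not calibrated
  to any real cohort — per-condition means of the real measures were
  never published.
* The classification default reproduces a leakage-prone standardization
  order for fidelity; use `fold_safe = TRUE` for honest generalization
  estimates on real data.
* MV is reported as mean |velocity|; a velocity-path-per-second variant
  coincides up to the sampling-interval factor, and the displacement
  stage of PD/PP rests on a documented double-integration choice rather
  than an authoritative definition.
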