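---
title: "Methods: gait feature extraction, filter feature selection and faller-classification evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait feature extraction, filter feature selection and faller-classification evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfall)
```

# The problem and the pipeline

`gaitfall` classifies older adults as fallers (at least one fall reported
in the six months before assessment — the positive class) or non-fallers
from one short instrumented walk: 7.62 m with pressure-sensing insoles
sampled at 120 Hz (total plantar force, CoP coordinates per foot) and
tri-axial accelerometers at the head, pelvis and both shanks sampled at
50 Hz. The pipeline is: feature extraction per sensor → filter feature
selection per sensor combination (31 non-empty subsets of the five
sensors) → classifier grid on a 75:25 stratified holdout → seven-metric
evaluation with Wilson intervals and summed-rank ranking → repeated-
random-sampling (RRS) stability analysis of the top models.

Feature selection deliberately uses *filter* methods (CFS, FCBF,
Relief-F): they are classifier-independent, so one selected subset can be
compared across the whole classifier bank, and they avoid the
computational cost and overfitting risk of wrapper methods. By default
selection runs once on the full dataset and the resulting subsets are
reused across every holdout iteration; `selection$on_full_dataset = FALSE`
restricts selection to the training rows instead, for users who want
leakage-free subsets at the price of losing a single cohort-level subset.

# The synthetic-data generator

No public dataset accompanies this class of study, so the generator is a
first-class module: it emulates the *statistical structure the features
assume*, not biomechanics. Per foot, each stance phase gets

* a bimodal vertical force curve: two smooth Gaussian bumps (≈1.10 and
  ≈1.05 body weight, centred at 28% and 72% of stance, width 0.22) with a
  mid-stance minimum of ≈0.79 BW, linearly tapered to zero over the first
  and last 8% of stance. This guarantees the first-peak / minimum /
  second-peak landmarks the impulse features I1–I7 require;
* a CoP track advancing monotonically 0 → 200 mm posterior→anterior, with
  a configurable number of injected posterior deviations (5 frames of
  negative AP velocity) and square ML deviations (±5 mm for 5 frames,
  short enough that an 11-frame running median keeps tracking baseline,
  so injected counts are exactly recoverable from noiseless signals).

Accelerations are sums of the stride-frequency fundamental and harmonics
2–6 with decaying amplitudes and uniformly random phases, plus white
noise; the step frequency (second harmonic) dominates the vertical axis.
This makes the REOH and FFT-quartile features non-degenerate and gives the
step-peak detector a realistic target.

Faller effects are *multiplicative scalings of generator parameters*,
never of extracted features: `late_stance_impulse_scale` scales the force
curve in the second half of stance through a smooth logistic transition at
mid-stance (values < 1 reduce I3, I4, I6, I7), and
`posterior_accel_scale` scales the posterior half-axis of the head AP
acceleration. Extraction is therefore tested end-to-end: an injected
effect must survive signal synthesis, event detection and integration to
show up in the feature table.

Default conditions: stride time 1.0 ± 0.05 s (inter-participant SD),
within-trial stride jitter 0.01 s, gait speed 1.27 m/s (typical for
community-dwelling older adults and consistent with six-minute-walk
distances around 450 m), body mass 72 kg, stance fraction 0.6,
accelerometer noise SD 0.02 g, force noise 0.5% BW, CoP noise 0.3 mm, one
posterior and one ML deviation per stance. The cohort default is 24
fallers / 76 non-fallers. The generator does *not* emulate: pressure-cell
images, turning or gait initiation/termination transients, sensor
misalignment, or the subtlety of real faller/non-faller differences —
passing tests show the pipeline recovers what was injected, not that real
fallers are separable.

# Feature definitions and conventions

## Insole bank (30 features)

Stance events come from threshold crossings of total force (default 10 N,
a conventional small fraction of body weight); incomplete first/last
stances are discarded, and stance + swing = stride holds per stride by
construction. Impulses integrate force by the trapezoid rule at the
native 120 Hz (no resampling) over landmark-delimited intervals and divide
by body mass (N·s/kg); because the trapezoid rule is additive at shared
nodes, I5 = I1+I2, I6 = I3+I4 and I7 = I5+I6 hold to floating-point
precision on every stance. If a stance is not bimodal, the landmarks fall
back to the maxima of the two stance halves with the minimum between them
and a warning is raised.

Conventions the field leaves open, fixed here and configurable:

* *Posterior deviation*: maximal run of frames with negative AP CoP
  velocity; "length" is 2-D CoP path length over the run (axis
  displacement is the obvious alternative; path length was chosen as the
  more complete measure of excursion).
* *ML deviation*: maximal run where |ML − running median(11 frames)|
  exceeds a 2 mm band; lateral and medial excursion magnitudes are summed
  separately. The band is a convention — nothing in the literature pins
  down "ML deviation" — and is a parameter (`ml_band`).
* *CoP CoV*: SD/|mean|·100 of the stance coordinate series (AP and ML).
* CoP ML coordinates are foot-local with positive = lateral, which makes
  the pooled feature vector exactly invariant to left/right relabelling.
* The enumerable insole bank yields 26 unambiguous features; the canonical
  registry carries 30 by adding four across-stride SD slots (defaults: SD
  of I3, I6, I7 and stride time — the variables most implicated in faller
  gait). The composition of the four extra slots is configurable
  (`insole_feature_names(extra_sd = ...)`).

## Accelerometer bank (29 features per site)

Descriptive statistics and the Lyapunov exponent consume the signal after
a fifth-order zero-phase (forward–backward) Butterworth low-pass at
12.5 Hz; FFT-quartile and REOH use the raw signal. Zero-phase filtering is
a choice (phase handling is rarely reported); it avoids lagging landmarks.
The forward–backward pass is applied with odd-reflection end padding,
which suppresses the large edge transients `signal::filtfilt` otherwise
produces.

* *Directional statistics*: each signed anatomical axis is split into its
  two half-axes (superior/inferior, anterior/posterior, right/left);
  max/mean/SD of the sample magnitudes on each side. "Maximum" is the
  whole-trial maximum (a per-stride-max-averaged variant would be the
  alternative; whole-trial is simpler and monotone in it).
* *Cadence / stride time*: step peaks on the filtered vertical axis with a
  0.35 s minimum inter-peak distance. Stride time is the median interval
  between every *second* peak — with random harmonic phases the two step
  peaks inside one stride are asymmetrically spaced, so twice the median
  step interval is biased while the two-step interval is exact for
  periodic signals. Cadence = 120/stride time, preserving the two-steps-
  per-stride identity exactly.
* *FFT first quartile*: percentage of DC-excluded spectral magnitude at or
  below one quarter of the analysable band (6.25 Hz at 50 Hz sampling).
* *REOH*: harmonic amplitudes are read as the maximum spectral magnitude
  within ±0.1 Hz of each of the first 20 stride-frequency harmonics
  (robust to small stride-frequency error; harmonics above Nyquist are
  truncated). Reported as the *proportion* even/(even+odd) ∈ [0, 1]; the
  plain even/odd ratio is available via `proportion = FALSE`.
* *MLE*: Rosenstein-style — delay embedding with dimension 5 and delay at
  the first minimum of the average mutual information (16 equal-width
  bins), nearest neighbours outside a temporal exclusion window, mean
  log-divergence tracked over 0–0.5 stride and fitted by least squares,
  in 1/s. Hyper-parameters follow the gait local-dynamic-stability
  literature and are all arguments.

Three numerical decisions make the MLE well-behaved on short walks:
0.5 s is trimmed from each end of the series before embedding (keeps any
residual filter edge effects out of the neighbour search); the exclusion
window spans one stride *minus one sample*, so the natural one-period
recurrence of a periodic signal remains an admissible neighbour; and
divergence distances are floored at 10⁻⁴ of the signal SD, so exactly
periodic signals produce a flat curve (slope ≈ 0) instead of
numerical-level drift driving the log. Genuine neighbour distances in
noisy data sit orders of magnitude above the floor. A 7.62 m walk yields
only ~6 strides; MLE estimates from fewer than ~35 strides are
low-reliability and should be read comparatively, not absolutely.

# Feature selection

Symmetrical uncertainty SU = 2·I(X;Y)/(H(X)+H(Y)) is computed after
equal-frequency discretization (10 bins; variables with ≤10 distinct
values pass through unbinned). MDL-style supervised discretization was
considered and rejected for the first release: equal-frequency binning is
parameter-free, deterministic and adequate for ranking.

* **CFS** maximises merit(S) = k·r̄_cf / √(k + k(k−1)·r̄_ff) by best-first
  forward search, stopping after five consecutive non-improving
  expansions. Exhaustive enumeration on ≤6-feature tables is used as a
  test oracle for the search.
* **FCBF** ranks by SU with the label, drops features at or below δ
  (default 0) and removes any feature dominated by an earlier-ranked
  retained feature (SU(F,G) ≥ SU(F,label)).
* **Relief-F** uses k = 10 neighbours and exhaustive sampling (m = n) by
  default — literature conventions, both configurable — on range-
  normalised features, with class-prior-weighted miss contributions.
  Subset sizing evaluates the top 5, 10, 15, … features (by weight) with
  a quadratic naive Bayes and a degree-1 SVM on one fixed 75:25 stratified
  holdout and returns the smallest size within 5 *percentage points* of
  the full-set accuracy ("5%" is read as points, not relative, because
  the accuracies being compared are themselves stated in percent).

All ties — feature ranking, search expansion, neighbour selection — break
lexicographically by feature name or by index, making every method
deterministic and row-order invariant (Relief-F under exhaustive
sampling). The three methods intentionally disagree about redundancy:
CFS and FCBF eliminate exact duplicates, Relief-F weights them equally;
the test suite asserts this contrast.

# Classifiers

NN: `nnet` single hidden layer (5–25 logistic units), entropy loss, up to
2000 epochs, seed-controlled initialisation — the unstated training
details are fixed defaults, all configurable. NB: Gaussian
class-conditionals per feature; the "linear" variant pools variances
across classes, the "quadratic" variant (NB-Q) fits per-class variances;
variances are floored at 10⁻⁹ to guard constant features. SVM:
`e1071` polynomial kernel (γ = 1/p, coef0 = 1) at cost 1 — the
regularisation constant is unstated in this protocol family, so the
library default is kept and exposed. Features are standardised by
training-set mean/SD (flag on by default), which makes predictions
invariant to affine rescaling of any input.

# Evaluation

Seven metrics from the confusion matrix (faller positive): accuracy,
sensitivity, specificity, PPV, NPV, F1 = 2·PPV·sens/(PPV+sens), MCC with
the 0-when-degenerate convention. The Wilson interval is evaluated in
closed form; at p = 0.96, N = 25 its lower bound is 0.80455, which prints
as 80.5 at one decimal — one-decimal tables in circulation print 80.4 for
this entry, a rounding discrepancy this implementation documents rather
than reproduces. Stratified holdouts round the per-class training count
to the nearest integer (24/76 at 75:25 → 18/57 train, 6/19 test). Model
ranking assigns rank 1 to the best value of each metric with mean-rank
ties (the tie policy of historical tables is unknowable from summed ranks
alone, so the standard order-independent policy is used) and sums the
seven ranks; RRS derives per-iteration seeds from the master seed by
iteration index, so summaries are independent of execution order, and
failed training iterations are counted and excluded rather than silently
dropped.

# Problem sizes used by the tests

The test suite and examples run at desk scale by choice: cohorts of 20–100
synthetic participants, RRS at 500–10,000 iterations, effect-recovery
checks on ~20 trials, and the Lorenz cross-check of the Lyapunov estimator
on 2,000 samples. The pipeline accepts the full study scale (100
participants, 31 combinations, 30-model grid, 10,000 RRS iterations)
through the same configuration object.

# Known limitations

* Generator realism is statistical, not biomechanical; transfer of any
  performance number to real cohorts is explicitly out of scope.
* Short-walk MLE is low-reliability (above).
* The insole registry's four SD slots are a documented convention, not a
  community standard.
* Holdout-based evaluation (with RRS) is implemented as specified;
  cross-validation and prospective-fall criteria are out of scope.
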