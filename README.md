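# gaitfall

Classifying older adults as fallers or non-fallers from one short
instrumented walk is a standard screening problem in clinical biomechanics:
a participant walks 7.62 m (25 ft) wearing pressure-sensing insoles (120 Hz;
total plantar force and centre-of-pressure coordinates per foot) and
tri-axial accelerometers at four body sites (head, pelvis, left and right
shank, 50 Hz), and the question is which of the ~146 gait features derivable
from those streams actually carry fall-risk information, and how stable any
resulting classifier is. `gaitfall` implements that whole workflow as a
tested R package, for researchers in wearable-sensor gait analysis:

* **Synthetic trial generation** — cohorts of multi-sensor recordings with
  the statistical structure the analysis assumes (bimodal stance-phase
  force curves, posterior-to-anterior CoP progression with injected
  deviations, stride-harmonic accelerations) and configurable faller
  effects applied at the signal level, so the complete pipeline is testable
  without any participant data.
* **Feature banks** — the 30-feature insole bank (CoP-path deviations and
  variability, temporal gait parameters, mass-normalised stance impulses
  I1–I7) and the 29-feature-per-site accelerometer bank (directional
  half-axis statistics, cadence and stride time, FFT first-quartile
  percentage, ratio of even to odd stride harmonics, maximum Lyapunov
  exponent).
* **Filter feature selection** — correlation-based feature selection (CFS,
  best-first search on the merit
  k·r̄_cf / √(k + k(k−1)·r̄_ff)), the fast correlation-based
  filter (FCBF, symmetrical-uncertainty ranking with predominance-based
  redundancy removal), and Relief-F with incremental five-feature subset
  sizing — over any of the 31 sensor combinations.
* **Classifier bank** — single-hidden-layer perceptrons (5–25 nodes),
  Gaussian naive Bayes with pooled ("linear") or per-class ("quadratic")
  variances, polynomial-kernel SVMs (degree 1–7), plus a majority-class
  baseline.
* **Evaluation protocol** — accuracy, sensitivity, specificity, PPV, NPV,
  F1 and MCC; Wilson score intervals on accuracy,

  CI = (p + z²/2N ± z·√(p/N − p²/N + z²/4N²)) / (1 + z²/N);

  summed-rank model ranking; stratified 75:25 holdouts; and
  repeated-random-sampling (RRS) stability analysis over thousands of
  re-randomised holdouts.

## Worked example

Generate a small synthetic cohort (8 fallers with reduced late-stance
impulse and altered head AP acceleration, 16 non-fallers), extract
features, select insole features with Relief-F, and evaluate an SVM:

```r
library(gaitfall)

cohort   <- generate_cohort(n_fallers = 8, n_nonfallers = 16, seed = 7)
features <- extract_features(cohort)
features
#> <feature_table> 24 participants x 146 features (faller=8, non_faller=16)

insole <- subset_combination(features, "I")
w      <- relieff_rank(insole, k_neighbors = 5)
subset <- relieff_subset_size(insole, w, seed = 7)
subset
#> <feature_subset> ReliefF: 5 feature(s)
#>   insole.i3, insole.i6, insole.i4, insole.i7, insole.i2
```

Relief-F recovers precisely the late-stance impulse features (I3, I6, I7)
that the faller effect scales down in the generator. A single stratified
holdout and a 500-iteration RRS run:

```r
tab   <- feature_table(insole$features[, subset$names], insole$labels,
                       insole$participant_id)
split <- stratified_holdout(tab$labels, 0.75, seed = 7)
fit   <- train(tab, model_spec("SVM", 2), rows = split$train)
pred  <- predict(fit, tab$features[split$test, ])
confusion_metrics(confusion_counts(tab$labels[split$test], pred))
#> accuracy 100.0% [61.0: 100.0], sens 100.0%, spec 100.0%, PPV 100.0%,
#> NPV 100.0%, F1 1.000, MCC 1.000 (n=6)

rrs(tab, model_spec("SVM", 2), n_iter = 500, seed = 7)
#> <rrs_summary> 500 iterations, seed 7
#>   SVM-2      accuracy 100.0 +/- 0.0%, sens 100.0%, spec 100.0%
```

The default synthetic effect (late-stance impulse scaled by 0.85) is a
strong, clean signal, so the classifier separates the classes perfectly;
real faller/non-faller differences are far subtler. The wide Wilson
interval (61–100% at n = 25 test participants would be narrower; here
n = 6) is the point of reporting it.

The full study protocol — all sensor combinations, three selection methods,
the complete classifier grid, ranking and RRS — runs through one call:

```r
res <- run_pipeline(default_config(n_fallers = 24, n_nonfallers = 76,
                                   n_iter = 10000, seed = 1))
res$holdout_report   # single-holdout table: metrics, Wilson CI, summed rank
res$rrs_report       # RRS table: mean ± SD per metric, summed rank
```

## Scope

The package analyses total-force and CoP insole streams (no pressure-cell
images), does not model musculoskeletal dynamics, and performs no
orientation estimation or sensor fusion. Wrapper/embedded feature
selection and cross-validation are intentionally out of scope; the
evaluation protocol is holdout-based with RRS stability analysis. See the
methods vignette (`vignettes/gaitfall-methods.Rmd`) for the model details,
parameter conventions and limitations.
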