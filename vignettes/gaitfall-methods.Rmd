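---
title: "Methods: temporal gait analysis and fall-risk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal gait analysis and fall-risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `gaitfall`, the
assumptions they rest on, the numerical choices made where the design was
genuinely open, and what the synthetic test bed does and does not show
about real video data.

## The measurement model

The input is markerless pose-estimation output for a Timed-Up-and-Go (TUG)
trial: per frame, 26 named keypoints of the Halpe full-body skeleton, each
an (x, y, confidence) triplet in image coordinates. Only four keypoints
drive the gait analysis — the two heels and the two big toes — and only
their y (vertical) coordinate: walking is a cycle of lifting and lowering
the feet, and in image coordinates (y growing downward) a foot on the
ground sits at a local *maximum* of its y trajectory. Heel strikes are
maxima of the heel signal; toe-offs are maxima of the big-toe signal. For
data delivered in an upward-positive convention, `y_up = TRUE` negates the
signal so the same maximum rule applies.

Assumptions: a single subject per recording (multiple detections on one
frame are collapsed to the highest summed confidence), one camera view per
run (the side view, where vertical foot motion is visible), and a single
turn per trial. Samples with detection confidence below 0.1 are treated as
missing and linearly interpolated between valid neighbours; leading and
trailing gaps are held at the nearest valid value rather than extrapolated,
because extrapolated foot positions could fabricate spurious contacts at
the recording edges.

## Smoothing

Raw keypoint trajectories carry frame-to-frame jitter. Each signal is
smoothed with a Savitzky–Golay filter: a polynomial of order 3 is
least-squares-fitted to the 11 samples centred on each point and the point
is replaced by the fitted value, ŷᵢ = Σⱼ cⱼ·yᵢ₊ⱼ. Window 11 / order 3 (the
defaults of `smoothing_params()`) generalise well across age groups' heel
and toe signals at 30 fps: the window spans a third of a second, long
enough to suppress jitter, short enough not to merge adjacent contacts.

At the signal boundaries the window is truncated to the available samples
and the polynomial refitted, instead of padding the signal. Padding
fabricates samples exactly where a TUG walk's first and last contacts
live; a truncated fit uses only observed data. In the interior the filter
is a fixed convolution; the two are identical away from the first and last
five samples.

## Event detection

Events are constrained local maxima of the smoothed signal
(`find_local_maxima()`):

* a sample strictly greater than both neighbours is a candidate; a run of
  equal values flanked by lower ones counts once, at its first sample
  (deterministic and reproducible under ties);
* candidates are then pruned greedily by decreasing height (earlier frame
  first on ties), keeping a candidate only if every already-kept peak is at
  least `min_distance` frames away — so the higher peak wins any conflict.

`min_distance` defaults to 15 frames (0.5 s at 30 fps), below the shortest
plausible stride interval, so two genuine same-foot contacts can never
conflict. The event detector (`detect_events()`) additionally requires
10 px of prominence by default: genuine foot lifts in side-view video span
tens of pixels, while smoothing ripple near flat signal stretches and
residual jitter stay in the low single digits. Both parameters are exposed
because camera distance and resolution change the pixel scale.

## Turning detection and exclusion

During the turn the subject pauses and shuffles both feet without full
swings, so the heel-strike maxima inside the turn are the lowest-valued of
the recording. The detector pools both feet's heel-strike peaks, takes the
lowest (deepest) and second-lowest values, locates the pooled heel strike
immediately before the second-deepest and immediately after the deepest,
and sets

```
start_turning = floor(median(index_before_deepest, deepest_index2))
end_turning   = floor(median(index_after_deepest,  deepest_index))
```

The median of two frames is their midpoint; non-integer midpoints are
floored to a frame index. Value ties are broken toward the earlier frame.
Every event inside `[start_turning, end_turning]` (inclusive) is excluded
from feature extraction, because contacts made while manoeuvring are not
normal-pace gait. If no event precedes the second-deepest peak the start
falls back to that peak's own frame (flagged); if the computed bounds come
out reversed — possible when the deepest peak precedes the second-deepest
with no event between — they are swapped and flagged rather than returned
inverted. Both feet's strikes are pooled when locating the bracketing
events; toe-off peaks do not enter the deepest-point search, since the
turn signature is defined on heel strikes.

## Temporal features

With fps the frame rate and frames as indices:

* stance time = (toe-off − heel strike) / fps, the foot's ground time in a
  cycle, paired within the same walking segment and before the next
  same-foot heel strike;
* stride time = (next same-foot heel strike − heel strike) / fps;
* step time = (following opposite-foot toe-off − heel strike) / fps. This
  is the protocol's printed definition and the package default; note the
  conventional definition uses the opposite foot's *heel strike* and is
  available as `step_time_convention = "contralateral_hs"`. Under the
  paper convention a symmetric 60 %-stance gait yields step times around
  (stance − half-stride)/fps, much shorter than half a stride — users
  comparing against normative step-time tables should use the
  contralateral convention;
* cadence = steps per minute, computed as the number of step intervals
  (consecutive pooled heel strikes within one contiguous walking segment)
  divided by the summed duration of those segments. Counting intervals
  rather than strikes, and summing segment durations rather than spanning
  the excluded turn, keeps cadence exact for periodic gait
  (cadence = 60 / step interval; 120 / stride time for symmetric walks):
  counting strikes over the full first-to-last span would bias cadence by
  a factor n/(n−1) and dilute it by the turning pause, which the exclusion
  step explicitly removes from the analysis.

Features are averaged over all valid cycles of each foot into one row per
subject — the tabular layouts used by the two experiments: per-foot
(`left_/right_stride_time`, `_step_time`, `_stance_time`, `cadence`,
`label`) and averaged (`average_*`, the pairwise left/right means).
External gait tables in the elderly-cohort dialect are aligned onto the
per-foot layout by `map_external_attributes()`: `*_Single_Support` maps to
stance time, cadence is the mean of the two per-side cadences, and spatial
columns are dropped — single-view markerless video supports only the
temporal features, so merged tables keep the common temporal core.

## Classification protocol

The protocol mirrors a small-cohort clinical study: 65 subjects, 44
fallers and 21 non-fallers.

* **SMOTE** balances the classes by synthesising minority samples: pick a
  minority vector, one of its k = 5 nearest minority neighbours
  (Euclidean), and a point uniformly at random on the segment between
  them, until parity (44/44, i.e. 23 synthetic rows). Original rows are
  preserved bit-exactly; synthetic rows carry `provenance = "smote"`.
* **Scaling** standardises each feature, z = (x − μ)/s, with μ and s
  fitted on the training set only and reused on the test set.
* **Split**: stratified 70:30 after shuffling; the test set takes
  ⌈0.3 n⌉ rows, allocated per class by floor plus largest remainder with
  ties resolved in label sort order — on the 88-row balanced table this
  yields 61 train / 27 test with 14 fallers and 13 non-fallers, matching
  the protocol's stated composition.
* **Models**: twelve classifiers behind one registry — SVM (RBF), decision
  tree, random forest, three gradient-boosted variants, AdaBoost, KNN,
  naive Bayes, MLP, bagging, and a hard-voting ensemble of SVM, random
  forest and naive Bayes. The three boosted entries share the xgboost
  backend under different growth policies: `lightgbm` grows leaf-wise on
  feature histograms, `xgboost` depth-wise with exact splits, `catboost`
  depth-wise on histograms with stronger L2 regularisation. AdaBoost
  (SAMME stumps) and bagging are small hand-rolled ensembles over rpart
  trees. Grid search is exhaustive over small per-model grids, scored by
  stratified 5-fold cross-validated accuracy on the training set; the best
  configuration is refitted on the full training set. Grids and
  cross-validation folds are package choices — the protocol prescribes
  tuning but not its contents — and are fully overridable.
* **Ablations** (`run_experiment()`): full, without SMOTE, without
  scaling, and without both ("without enhancement"), reported as an
  accuracy matrix with confusion matrices and (for tree models)
  per-feature importances.

One deliberate fidelity choice: SMOTE is applied to the **whole table
before the split** by default, because that is what reproduces the
protocol's counts (88 rows split 61/27, synthetic rows reaching the test
set). This is statistically leakage-prone — synthetic test points
interpolate training-set neighbours — so the sound variant is one switch
away (`smote_after_split = TRUE`), which balances the training set only.
The chance-level control below quantifies that the leakage does not
manufacture signal out of nothing under the null.

Label semantics: `faller` is the positive, high-risk class throughout.

## The synthetic test bed

Two generators make every stage testable without video.

`simulate_tug()` builds keypoint trajectories for an out-and-back walk:
per foot, ground contacts are raised-cosine peaks reaching `baseline_y`
(default 500 px), separated by swing dips of `foot_lift_amplitude`
(default 60 px); bump half-widths are half the gap to the neighbouring
contact, so each peak is a strict, locally symmetric maximum that survives
symmetric smoothing at exactly its true frame. Defaults encode the study
conditions: 30 fps, 1.2 s strides (4 per direction, about a 3 m walkway),
60 % stance, half-stride phase lag between feet, and a 2 s mid-walk pause
containing one adjustment contact per foot whose peaks sit `turn_depth`
(20 px) and 1.5 × `turn_depth` below baseline — the deepest-maxima premise
holds by construction, and the two distinct depths keep the
deepest/second-deepest ordering untied so the computed window brackets the
whole pause. Gaussian pixel noise of configurable σ is added everywhere.
The returned ground truth records every true event frame, the true pause
interval, and the realised stride/stance frame counts;
`ground_truth_features()` pushes the true frames through the same pairing
and formulas as the pipeline, giving exact recovery targets.

What the simulator does **not** emulate: pose-estimation failure modes
(identity switches, occlusion dropouts, confidence collapse during the
turn), perspective scaling as the subject approaches the camera, double
support asymmetries, or out-of-plane motion. Passing recovery tests
therefore validates the algorithmic chain — smoothing, peak logic, turning
arithmetic, feature formulas — not robustness to real-world pose noise.

`simulate_feature_table()` draws per-subject feature vectors from
class-conditional truncated normals. Defaults encode the faller contrasts
the analysis assumes — longer stance (0.72 ± 0.05 vs 0.62 ± 0.08 s),
longer and more variable stride (1.12 ± 0.15 vs 1.05 ± 0.08 s), shorter
step (0.46 ± 0.05 vs 0.55 ± 0.07 s), higher and more variable cadence
(116 ± 12 vs 105 ± 8 steps/min) — at roughly one standard deviation of
separation with substantial overlap, which a movement-analysis reader
would recognise as a realistic, imperfectly separable cohort. Left/right
columns perturb a shared latent value by 2 % relative noise. Class sizes
default to the protocol's 44/21.

## Numerical choices and degenerate inputs

* SG boundary handling: truncated-window refit (no padding); polynomial
  order capped at window length − 1 on very short truncated windows.
* Plateau peaks resolve to the plateau's first sample; all value ties
  break toward the earlier frame.
* Midpoints of frame pairs are floored; exclusion bounds are inclusive.
* Signals shorter than the window, empty trajectories, fewer than two
  heel strikes, zero-variance features, a minority class smaller than
  k + 1, and single-row classes all raise typed errors naming the
  offending input rather than returning partial results.
* A no-turn simulation (`turn_pause = 0`) carries no turning ground truth;
  turning detection on such data is meaningless and the simulator flags it
  by omission. Multiple-turn protocols are out of scope.
* All stochastic operations (SMOTE, splits, stochastic fits, simulators)
  take explicit integer seeds and are bit-reproducible under them.

## Test problem sizes

The suite exercises: oracle equivalence of the smoother against per-window
least squares on 150–200-sample signals; peak detection against an
exhaustive O(n²) oracle on 100 random signals; turning and feature
recovery on 20 seeded simulated walks (exact recovery without noise,
≤ 2 frame periods under σ = 2 px); the protocol counts 65 → 88 → 61/27;
and a chance-level control — zero-separation balanced tables of 60
subjects, 50 seeds, all twelve models — whose pooled accuracy must sit
inside the 95 % binomial band around 0.5. The band treats each seed's
model-averaged accuracy as one binomial sample of the test size; since
models are correlated this is approximate, but it guards against the
failure mode that matters: systematic accuracy inflation through
preprocessing leakage.

## Known limitations

* The step-time definition follows the protocol's printed formula; see
  above for the conventional alternative before comparing to normative
  data.
* Temporal features only; spatial parameters need calibrated distances.
* One view, one subject, one turn per recording.
* The twelve-model suite approximates three distinct gradient-boosting
  libraries with one backend under different growth policies; absolute
  accuracies of those entries are not interchangeable with the original
  implementations, though their roles in the protocol are.
* Small-cohort accuracies carry wide confidence intervals: on a 27-row
  test set one flipped prediction moves accuracy by 3.7 points, which is
  why the package reports confusion matrices alongside.
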