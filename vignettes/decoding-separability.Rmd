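---
title: "Testing encoding and decoding separability in population codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing encoding and decoding separability in population codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddsep)
```

## The problem

When a stimulus varies along two dimensions — say face identity and
emotional expression — a natural question is whether the neural
representation of one dimension is *separable* from the other: does the
population response to "identity 1" stay the same when the expression
changes?  `ddsep` formalizes this within a signal-detection-theoretic view
of population codes and provides the statistical machinery to test it from
trial-level data.

Three layers of description are involved:

* **Encoding.**  N tuned channels respond to stimulus $A_iB_j$ with a
  multivariate Gaussian $r \sim N(f(A_iB_j), \Sigma(A_iB_j))$.  *Encoding
  separability* of A from B holds when both the tuning vector and the
  noise covariance of every A-level are invariant across B-levels
  (tuning separability plus noise invariance).
* **Decoding.**  A linear decoder $\hat A = \beta + b^\top r$ turns the
  population response into a scalar.  *Decoding separability* holds when
  the distribution of $\hat A$ for every A-level is invariant across
  B-levels.
* **Measurement.**  Indirect measures (voxels, electrodes) are modelled as
  $a = Br + e$ with stimulus-independent Gaussian error, which convolves
  every decoding distribution with a fixed Gaussian kernel — so
  differences between decoding distributions survive measurement, up to
  smoothing.

The logical relations are asymmetric and drive everything else in the
package: encoding separability *implies* decoding separability for any
fixed decoder, but a failure of encoding separability may be either
*hidden* (a tuning deviation $\delta$ with $b^\top\delta = 0$ leaves the
decoding distributions untouched) or *exposed*
($b^\top\delta = d \neq 0$ shifts them by exactly $d$).  A decoding
violation is therefore valid evidence of an encoding violation, while
decoding separability proves nothing about encoding.

## The DDS statistic

The core test statistic sums, over the two target levels $i$ and 1,000
grid points, the absolute differences between kernel density estimates of
decoded values at the two irrelevant levels:

$$DDS = \sum_{i=1}^{2}\sum_{k=1}^{1000} |\hat p_{i1}(\hat A_k) - \hat p_{i2}(\hat A_k)|.$$

Implementation choices that matter:

* **Grid.**  1,000 evenly spaced points from the pooled minimum minus half
  the pooled range to the pooled maximum plus half the range.  The grid is
  built once from all four conditions pooled and reused across
  permutations, which guarantees a common support.
* **Bandwidth.**  Gaussian kernel with Scott's rule,
  $h = \mathrm{sd}(x)\, n^{-1/5}$, computed per condition subsample and
  *recomputed inside every permutation* so that the observed split and the
  shuffled splits are treated identically (exchangeability).
* **Scale.**  The raw DDS sums density values with no grid-spacing factor,
  exactly as defined above; `l1_distance()` supplies the properly scaled
  L1 norm separately.  Since the permutation standardization is rank-based,
  the raw scale is irrelevant to inference.
* **Standardization.**  The irrelevant-dimension labels are shuffled 200
  times within each target level; the observed DDS is located in the
  resulting EDF.  Ties use the mid-rank convention, and the observed value
  is not pooled into its own EDF by default (`include_observed` exposes
  the alternative).  Two equivalent reporting scales are returned: the
  percentile minus 50 (maps, null 0) and the raw proportion (ROIs, null
  0.5).  Under exchangeability the proportion has expectation exactly 0.5.

KDE estimation error inflates the raw DDS additively (the statistic is
positive even under the null), which is precisely why the permutation
standardization, not the raw value, carries the inference.

## Competing operational tests

For comparison with common practice the package also implements:

* `orthogonality_index()` — cosine/correlation between two classifier
  weight vectors.  Only rigid transformations preserve angles, so
  measurement-space orthogonality says little about encoding-space
  orthogonality; the searchlight variant reports the weight correlation.
* `accuracy_table()` + `accuracy_invariance()` — classification-accuracy
  invariance and generalization.  Decoding separability implies
  invariance, which implies generalization; each arrow is one-way.  The
  randomized-model test in the suite confirms the chain never reverses.
* `pattern_difference_test()` — the interaction contrast
  $[\bar a(A_1B_1)-\bar a(A_2B_1)]-[\bar a(A_1B_2)-\bar a(A_2B_2)]$, its
  Euclidean norm, and a within-target-level permutation p-value.

## Synthetic worlds

`make_world()` pins down the study conditions used throughout the test
suite; the defaults are the conditions everything else assumes, not
tuning knobs:

* 2 x 2 stimulus grid (two levels per dimension, as in a two-identity by
  two-expression design); 4 Gaussian channels with unit width and gain,
  centers at 1..4, and A-values straddling the bank center; unit channel
  noise, independent across channels.
* `separable` uses the unit-norm discriminant direction between the two
  A-levels as decoder.
* `hidden_violation` draws a seeded random unit deviation $\delta$
  (norm `effect_size * noise_sd`) on condition (1,1) and constructs the
  decoder in the null space of $\delta$ (minimum-norm particular solution
  plus seeded null-space component, unit-normalized).
* `exposed_violation` places the deviation along the discriminant
  direction, pointing away from the other target level, with the decoder
  aligned to it.  This makes the decoding means differ by exactly
  `effect_size` decoding SDs *and* keeps the violation visible to a
  classifier trained on the data itself — the canonical exposed case.  A
  deviation in a random direction can instead be nearly invisible to a
  freshly fitted decoder, which is the hidden case shading continuously
  into view.
* `orthogonal_weights` / `oblique_weights` modulate the mean response
  along two unit directions at 90 or 45 degrees for the
  weight-correlation analyses.

`generate_volume_dataset()` plants the world inside a sphere of an
otherwise pure-noise volume: signal voxels receive a seeded random linear
mixture of the channel responses with coefficient SD `snr` times the
voxel noise SD.  It emulates the geometry of a focal representation, not
fMRI physics: there is no hemodynamics, no spatial autocorrelation, no
run structure.  Passing searchlight tests on these volumes validates the
statistical machinery, not robustness to realistic nuisance structure.

## Searchlight and group inference

`searchlight_dds()` repeats at every in-mask voxel: extract the in-mask
voxels within a 3-voxel-radius sphere (Euclidean distance in voxel units,
inclusive), standardize each voxel across trials, fit a soft-margin
linear SVM (cost 1) on the target dimension pooling all trials, project
onto the unit hyperplane normal to get signed-distance decoded values,
and run the standardized DDS.  Centers with fewer than two usable voxels
are left missing.  Because the rank-based index saturates at its ceiling,
the map also carries a continuous EDF z-score
$(DDS_{obs} - \mathrm{mean}(EDF))/\mathrm{sd}(EDF)$ used by `map_peak()`
to break ties at the maximum.

`group_sign_flip_test()` provides voxelwise one-sample inference over
subject maps by randomly flipping the sign of whole maps, with
family-wise control via the maximum-statistic distribution and exhaustive
enumeration whenever $2^S$ does not exceed the permutation budget.  This
is a deliberately simple, fully verifiable nonparametric scheme;
cluster-mass correction and variance smoothing are out of scope.

## Numerical choices and problem sizes

* Analytic separability checks use an absolute tolerance of `1e-10`:
  models are exact objects, not estimates.
* The KDE/DDS inner loop is compiled (Rcpp); each sample's kernel is
  accumulated only within 8.5 bandwidths, which is below double precision
  relative to the kernel peak and therefore exact in double arithmetic.
* The replicate suites in the package's tests use 500 replicates of
  50 trials per condition for null calibration (and 100 per condition for
  the exposed-violation power check), with the full 200-shuffle
  standardization — matching the simulation sizes the package documents.
  The planted-signal searchlight check runs a 20^3 volume with a
  radius-4 signal sphere and 40 trials per condition at 50 shuffles per
  center; peak localization needs spatial contrast, not fine percentile
  resolution, so fewer shuffles suffice there.
* Seeds are explicit everywhere; (parameters, seed) fully determine every
  output, including whole searchlight maps.

## Known limitations

* Channel noise is Gaussian only; Poisson or multiplicative noise is a
  documented non-goal, as is fitting encoding models to real recordings.
* Decoders are linear; optimal or nonlinear decoding is out of scope, and
  designs beyond 2 x 2 are supported by the definitions but not by the
  DDS permutation test, which is written for the 2 x 2 case.
* The searchlight decodes with the all-data classifier (no per-fold
  cross-validation for the projection); the standardization of voxel
  columns spans all trials.  Both alternatives would be easy to add but
  are not what the default analysis does.
* The rank-based standardized DDS is known to run conservative in noisy
  real data; the package exposes both reporting scales and the
  differential contrast of two standardized maps (subtracting one map
  from another) is left to the user, since its calibration is exploratory.
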