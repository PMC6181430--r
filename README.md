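# ddsep

Tests of encoding and decoding separability for neural population codes.

## The problem

Many questions about neural representation come down to *separability*:
when a stimulus varies along two dimensions (face identity and emotional
expression, orientation and spatial frequency, ...), is the neural code
for one dimension invariant to changes in the other?  `ddsep` is for
researchers analysing multivariate neural data (fMRI voxel patterns,
electrode arrays, simulated population codes) who want a theoretically
grounded test of that invariance rather than the looser operational
criteria common in the literature.

The framework has three layers.  An **encoding model** describes N tuned
channels responding to stimulus A_iB_j with a multivariate Gaussian,
r ~ N(f(A_iB_j), Sigma(A_iB_j)); *encoding separability* of A from B
means both f and Sigma for every A-level are invariant across B-levels.
A **linear decoder** A_hat = beta + b'r reduces the population response to
a scalar; *decoding separability* means the distribution of A_hat is
invariant across B-levels.  A **measurement model** a = Br + e links
channels to indirect measures with additive Gaussian error, which only
convolves each decoding distribution with a fixed kernel — so decoding
separability remains testable from imaging-style data.

The key logical fact: encoding separability implies decoding separability
for any fixed decoder, but not conversely (a tuning deviation delta with
b'delta = 0 is invisible to the decoder).  So an observed *violation* of
decoding separability is valid evidence of an encoding violation, while a
null result is not evidence of encoding separability.

The central statistic is the **DDS** (deviations from decoding
separability):

    DDS = sum_i sum_k | p_hat_i1(A_k) - p_hat_i2(A_k) |

— the sum over both target levels and 1,000 evenly spaced grid points of
absolute differences between Gaussian kernel density estimates of decoded
values at the two irrelevant-dimension levels.  Because KDE error
inflates the raw value, inference uses a permutation standardization:
irrelevant-dimension labels are shuffled 200 times within each target
level, and the observed DDS is located in the resulting EDF (reported
both as percentile − 50, null 0, and as a proportion, null 0.5).

The package also provides the competing operational tests
(classifier-weight orthogonality, classification-accuracy
invariance/generalization, pattern-difference invariance), a spherical
searchlight driver with NIfTI I/O, group-level sign-flip permutation
inference, and a synthetic-world generator that reproduces the regimes of
interest (separable, hidden violation, exposed violation, noise
violation) so every claim is testable without external data.

## Worked example

Simulate a world in which encoding separability fails but the decoder is
aligned with the deviation (the "exposed" case), then test it:

```r
library(ddsep)

world  <- make_world("exposed_violation", effect_size = 2, seed = 4)
check_encoding_separability(world$encoding)$encoding_separable
#> [1] FALSE

decoding_distribution(world$encoding, world$decoder)
#> # A tibble: 4 x 4
#>   level_A level_B   mean   var
#>     <int>   <int>  <dbl> <dbl>
#> 1       1       1  2.43      1
#> 2       1       2  0.434     1
#> 3       2       1 -0.434     1
#> 4       2       2 -0.434     1

trials <- generate_trials(world, n_per_condition = 100, seed = 5)
fit    <- dds_test(trials, target = "A", n_shuffles = 200, seed = 6)
fit
#> <dds_test> target dimension A, 400 trials
#>   raw DDS: 96.8411  (EDF of 200 shuffles: median 22.0385)
#>   standardized: proportion 1.000 (null 0.5), percentile - 50 = 50.0
```

The decoding means at target level 1 differ by exactly 2 decoding SDs
across the irrelevant dimension (2.43 vs 0.43), and the permutation test
puts the observed DDS above all 200 shuffles (proportion 1.0): a clear
violation of decoding separability, hence of encoding separability.  In a
separable world the proportion hovers around its null value of 0.5.  The
hidden-violation world (`make_world("hidden_violation", ...)`) shows the
converse: encoding separability fails, yet the test correctly stays at
the null, because its decoder satisfies b'delta = 0.

`autoplot(fit)` draws the permutation EDF with the observed statistic;
`glance(fit)` and `tidy(fit)` return one-row and long-format summaries.
For volumetric data, `generate_volume_dataset()`, `searchlight_dds()`,
`map_peak()` and `group_sign_flip_test()` carry the same test across a
voxel lattice and over subjects.

A thin command-line front-end (`inst/cli/ddsep.R`) exposes the same
functionality as reproducible JSON-configured runs (`simulate`,
`dds-test`, `searchlight`, `group-test`, `power-study`, ...).

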