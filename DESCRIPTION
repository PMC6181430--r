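Package: ddsep
Title: Tests of Encoding and Decoding Separability for Neural Population Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates multichannel encoding of two-dimensional stimuli,
    decodes population activity with linear decoders, and tests for
    violations of decoding separability -- the invariance of the
    distribution of decoded values for a target stimulus dimension across
    levels of an irrelevant dimension.  The central statistic (DDS,
    deviations from decoding separability) sums absolute differences
    between kernel density estimates of decoded values and is standardized
    against a label-shuffling permutation distribution.  The package also
    implements the competing operational tests used in multivariate
    neuroimaging (weight-vector orthogonality, classification-accuracy
    invariance and generalization, pattern-difference invariance), a
    spherical searchlight driver with group-level sign-flip inference, and
    a synthetic-world generator covering separable, hidden-violation and
    exposed-violation encoding regimes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
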