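Package: dsim
Title: Differential Association Testing Between Two Sample Groups for
    Integrated Omics Profiles
Version: 0.1.0
Authors@R:
    person("dsim", "maintainers", email = "dsim@example.org", role = c("aut", "cre"))
Description: Tests whether the association between a dependent omics
    profile (for example copy number) and a window of covariate probes
    (for example gene expression) differs between two groups of samples.
    The baseline association shared by both groups is removed per
    dependent probe by ridge regression with leave-one-out
    cross-validation; the cross-validated residuals are then tested for a
    group-by-covariate interaction with a variance-component (global)
    score test. Inference is permutation based, with false discovery
    proportion control via Meinshausen's permutation procedure. Includes
    the classical per-group association analysis with Benjamini-Hochberg
    correction for comparison, and a synthetic-data suite with known
    ground truth for validating operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
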