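Package: gmimpute
Title: Multilevel Multiple Imputation with Group Means and Adjusted Group
    Means
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully conditional specification (FCS) multiple imputation for
    two-level (clustered) data using single-level imputation models with
    group means (GM) or adjusted, leave-one-out group means (AGM) in place
    of random effects, together with a conventional random-intercept
    two-level imputation method for comparison.  Includes a two-level
    normal data generator for balanced and unbalanced designs, a
    latent-response amputation model for MCAR/MAR missingness, maximum
    likelihood analysis models for clustered data (empty model, latent and
    manifest covariate models, cluster-robust single-level regression),
    Rubin's rules for pooling, closed-form asymptotic bias expressions for
    non-iterative GM/AGM imputation with a Monte Carlo oracle, and a
    simulation harness that evaluates bias and coverage over replications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    sandwich,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
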