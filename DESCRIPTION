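Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    and two-step multivariable-MR mediation analysis from GWAS summary
    statistics. Provides summary-statistic input/output with allele
    harmonization and LD-aware clumping, instrument selection with explained
    variance and F-statistic filters, a battery of univariable MR estimators
    (inverse-variance weighted with robust and penalized variants, MR-Egger,
    maximum likelihood, debiased IVW, contamination mixture, MR-Lasso, BWMR,
    constrained maximum likelihood, MR-PRESSO), multivariable IVW, mediation
    decomposition of total effects into direct and mediated components, a
    synthetic GWAS summary-statistic generator with known causal structure,
    and screening pipelines for many-exposure and many-mediator designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
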