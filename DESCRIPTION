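Package: tates
Title: Trait-Based Association Testing with an Extended Simes Procedure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combines per-phenotype univariate genome-wide association
    p-values into a single trait-based p-value per genetic variant while
    correcting for phenotypic correlation through an eigenvalue-based
    effective number of tests (the TATES procedure), together with the
    classical p-value combiners (Simes, Fisher, Lancaster, Stouffer),
    composite-score and multivariate comparator tests (sum score, Thompson
    factor scores, canonical-correlation MANOVA), mixed-level phenotype
    correlation estimation (Pearson, polyserial, polychoric), factor-model
    and stationary-network genotype-phenotype simulators with missing-data
    schemes, and a replication engine for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
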