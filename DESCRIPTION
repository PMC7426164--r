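Package: ltspRecovery
Title: Recovery Dynamics of Bacteria Adapted to Long-Term Stationary Phase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how bacterial populations adapted to
    long-term stationary phase (LTSP) recover their growth once fresh
    resources become available. Implements sliding-window exponential
    growth-rate estimation from plate-reader OD600 curves, clone genotype
    catalogues with detection of newly acquired mutations, classification
    of antagonistically pleiotropic RNA polymerase core-enzyme (RNAPC)
    alleles and of reversion versus compensatory recovery outcomes,
    fractional-site dN/dS with a chi-squared enrichment test, and a
    serial-dilution evolution simulator (growth-rate selection,
    bottleneck drift, reversion/compensation mutation) that generates
    synthetic growth curves and clone mutation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
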