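Package: chirank
Title: Ranked Chi-Square Association Testing for Alternative Poly(A) Site Usage
Version: 0.1.0
Authors@R:
    person("chirank", "maintainers", email = "chirank@example.org", role = c("aut", "cre"))
Description: Detects condition-associated usage changes of transcript 3'-end
    isoforms (poly(A)-site "tags") from replicated sequencing count tables.
    For every tag the package builds replicate 2x2 tables (tag versus
    rest-of-gene by condition), computes a treatment chi-square from
    replicate-mean counts and an empirical null chi-square from
    within-condition replicate pairs, compares the two profiles rank by rank
    over a grid of thresholds, and estimates a nonparametric false discovery
    rate curve from the ranked null profile. Includes library-size
    normalization, tag filters, a negative-binomial simulator with injected
    association effects for FDR calibration, reference association tests
    (Pearson, Fisher, Cochran-Mantel-Haenszel with Benjamini-Hochberg
    adjustment), switch/accordance pattern classification of declared genes,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
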