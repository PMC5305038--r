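Package: lickstat
Title: Lick Microstructure Analysis for Rodent Ingestive Behaviour
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for lickometry: segmentation of timestamped lick-event
    streams into drinking clusters, computation of the standard seven
    microstructure measures (consumption, total licks, lick volume per 1000
    licks, licks per cluster, cluster count, mean inter-lick interval and its
    coefficient of variation), a two-group statistical battery (pooled-variance
    t, exact Mann-Whitney U, one-way ANOVA with post-hoc contrasts, Pearson
    correlation, Bonferroni family-wise control, and JZS default Bayes factors
    computed by adaptive quadrature), a noncentral-t sample-size calculator for
    two-arm treatment studies, and a generative model of clustered licking for
    validating the whole pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
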