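Package: efieldstats
Title: Group-Level Statistics for TMS and tES Electric-Field Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for group-level transcranial magnetic
    stimulation (TMS) and transcranial electrical stimulation (tES)
    electric-field dosimetry studies. Implements one-way ANOVA computed
    from group sufficient statistics (supporting singleton template-head
    groups), Tukey-Kramer post-hoc comparisons, template-versus-group
    percent differences, an outlier audit, spherical region-of-interest
    field averaging, and a permutation point-of-stability estimator with
    a configurable corridor of stability. A synthetic cohort generator
    reproduces the moment structure of a transdiagnostic stimulation
    cohort so the full pipeline is testable without imaging data or a
    field solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
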