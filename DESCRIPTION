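Package: myelotrace
Title: Quantification and Modelling of Myelination Patterns Along Cortical Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying myelin coverage along traced axons and
    modelling what determines which axons get myelinated. Reads SWC axon
    traces with companion arc-length internode annotations and computes
    percent length myelinated (PLM), internode-length and unmyelinated-gap
    spectra with nodal classification, and regional scaled myelination
    prevalence. Estimates axon diameters from transverse intensity profiles
    by full width at half maximum, fits a binomial generalized linear model
    of myelination probability on diameter and neuronal subtype with
    separation detection, and derives per-subtype 50 percent-probability
    diameters with delta-method intervals. Includes longitudinal
    baseline-versus-recovery remyelination analysis (delta-PLM, linear
    models, identity-line crossings, tracing-error bands, sheath-fraction
    summaries), the group-comparison statistics common in this literature
    (Kruskal-Wallis with Dunn-Sidak post hoc, Kolmogorov-Smirnov, paired t),
    and seedable synthetic-data generators so the whole pipeline is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
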