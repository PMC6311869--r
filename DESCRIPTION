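Package: immunoBarometer
Title: Splenic Immune Barometer: Simulated Flow Cytometry, Hierarchical
    Gating and Bonferroni-Corrected Group Comparison
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org",
           role = c("aut", "cre"))
Description: Tools for treating the spleen as a systemic immune barometer in
    preclinical tumor models.  Simulates per-animal single-cell flow
    cytometry event tables with a known population structure, classifies
    events through hierarchical boolean marker gates (lymphoid and myeloid
    antibody panels, including PD-1/Tim-3 exhaustion and M1/M2 macrophage
    polarization markers), computes the T-cell exhaustion status (TCES)
    ratio statistic, and runs two-group pooled-variance Student's t-tests
    with Bonferroni family-wise correction to produce publication-style
    comparison tables from either event-level data or printed summary
    statistics (mean, SD, n).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
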