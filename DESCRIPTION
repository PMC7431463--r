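Package: obseq
Title: Sequential, Polar Coordinate, and T-Pattern Analysis of Coded
    Observational Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of systematically coded
    behavioral interaction sequences, such as turn-by-turn transcripts of
    group therapy sessions coded with a field-format observation
    instrument.  Implements lag sequential analysis with Allison-Liker
    adjusted residuals and behavior-pattern construction, polar coordinate
    analysis (Cochran Zsum reduction, vector length/angle/quadrant maps,
    classic and genuine retrospectivity), and T-pattern detection with
    critical-interval significance testing and hierarchical pattern
    assembly.  Includes readers and writers for the GSEQ-style multi-event
    dialect and the THEME .vvt/.rdt dialect, interobserver reliability via
    Cohen's kappa with Landis-Koch interpretation bands, and a seeded
    generator of synthetic multi-event sessions with plantable lag
    dependencies and recurring temporal patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
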