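Package: lipotyper
Title: Quantitative Shotgun Lipidomics: Blank Filtering, Class Composition,
    Saturation Profiles and Differential Lipotypes
Version: 0.1.0
Authors@R:
    person("lipotyper", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for species-level shotgun lipidomics
    concentration tables (Lipidyzer/SLA-style output). Parses LipidMaps
    shorthand species names into a fixed 16-class registry, removes species
    indistinguishable from process-blank background (2x blank in >=80% of
    samples, with group-wise reintroduction at >=60%), aggregates species to
    class totals and percent-of-total compositions, computes double-bond
    saturation profiles for triacylglycerols, cholesterol esters and the
    glycerophospholipid pool, and performs differential lipotype statistics
    (two-sided t or Mann-Whitney U tests with Benjamini-Hochberg correction,
    paired variants, PCA). Includes a synthetic lipidome generator with
    cell-type lipotype templates, log-normal noise, blank background and
    injectable genotype/treatment effects so every stage is testable without
    instrument data.
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
    optparse,
    withr
Config/testthat/edition: 3
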