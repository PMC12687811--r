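Package: nadflux
Title: Stable-Isotope Tracing Analysis of NAD+ Metabolism in Murine Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo stable-isotope tracing of NAD+
    metabolism: a kynurenine/salvage/Preiss-Handler pathway atlas with atom
    mapping of expected isotopologue shifts, natural-abundance and
    tracer-purity correction of mass-isotopomer distributions by
    non-negative least squares, fractional-labeling and serum-enrichment
    summaries, precursor-contribution estimates partitioning tissue and
    luminal NAD+ pools between nicotinamide salvage and de novo synthesis
    from tryptophan, a compartmental constant-infusion simulator for
    synthetic ground-truth data, disease-activity-index scoring for DSS
    colitis, and the group-comparison statistics used throughout
    (Mann-Whitney, Kruskal-Wallis with Dunn post hoc, Benjamini-Hochberg
    adjustment, and qPCR fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
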