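Package: stemdrift
Title: Genetic Drift in Long-Term Pluripotent Stem-Cell Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the genomic drift of human pluripotent
    stem-cell lines under serial passaging: copy-number calling from shallow
    (~0.1x) whole-genome sequencing binned at 50 kb (GC correction, robust
    per-bin scores, run-based segmentation, annotation against recurrent
    hPSC abnormalities), a cancer-panel SNV retention cascade, germline
    versus de novo classification across ordered passage series, an
    expected-allele-fraction model joining variant allele fractions with
    copy number and clonal fraction, and the accompanying statistical layer
    (exact two-sided Fisher tests, Poisson log-linear mutational-load and
    binary logistic acquisition-rate regressions). A serial-passage
    clonal-evolution simulator (selection, bottleneck drift, mutation)
    generates ground-truth culture histories and renders them into binned
    coverage and panel variant calls so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
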