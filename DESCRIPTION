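Package: substrainr
Title: Variant Classification and Marker Selection for Inbred Substrain Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing joint variant calls from two closely related
    inbred substrains: quality filtering of small-variant and structural-variant
    VCFs, classification of variants into shared and strain-unique categories,
    per-chromosome coverage and homozygosity summaries, functional-impact triage
    of SnpEff ANN annotations, and selection of an evenly spaced marker panel
    for reduced-complexity crosses. Includes a fully truth-labelled synthetic
    data generator so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    vcfR,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
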