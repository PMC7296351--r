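Package: chromaprime
Title: Differential DNase-Seq Analysis of Primed and Inducible Chromatin
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for defining condition-specific and inducible
    DNase I hypersensitive sites (DHSs) from cut-count data: summit-centered
    tag counting, correction-factor normalization from the median of the
    strongest peaks, replicate-consistent fold-change classification of DHSs,
    expression-based gene grouping, DHS-to-TSS proximity analyses with a
    permutation null, tag-density profiles, IUPAC consensus motif scanning,
    and a simplified strand-aware binomial footprint caller. Includes a
    seeded synthetic-data generator with planted ground truth so every stage
    is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
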