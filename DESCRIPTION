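Package: mobilome
Title: Comparative Annotation of Transposable Element Mobilomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for comparative mobilome analysis:
    curation of transposable-element (TE) libraries from genomic copies,
    homology-based repeat masking with per-hit divergence, Jukes-Cantor
    corrected divergence landscapes, classification of autonomous LINE and
    LTR elements into families by amino-acid identity, hierarchical coverage
    tables, and bootstrapped neighbor-joining phylogenies of conserved
    domains. Includes a synthetic-genome simulator that plants TE copies at
    configured copy numbers, divergences and truncation levels together with
    ground-truth annotation, so every stage of the pipeline can be validated
    without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils,
    tools,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
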