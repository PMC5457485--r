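Package: chromcompare
Title: Comparative Analysis of Chromatin Accessibility Landscapes and
    Transcription Factor Cistromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting the open-chromatin landscapes and
    transcription factor binding repertoires of two cell states, as used in
    comparative leukemia epigenomics: peak-set algebra and overlap analysis,
    tag-count correlation clustering, position-weight-matrix and IUPAC motif
    scanning, unique-versus-union hypergeometric motif enrichment with
    clustered score heatmaps, digital DNase I footprinting with a
    strand-aware binomial protection score, a bootstrap statistic for the
    co-clustering of occupied motifs around anchor binding sites, ranked
    fold-change signal and motif-density matrices, and classification of
    accessibility changes and expression responses after a knockdown time
    course. A fully parameterised synthetic-data generator with recorded
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
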