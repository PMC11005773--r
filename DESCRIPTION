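Package: subgenome
Title: Subgenome Composition and Homoeologous Exchange Detection from
    Alignment Statistics and Read Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers subgenome composition (AA, AAB, ABB, ...) of hybrid and
    allopolyploid accessions from competitive alignment statistics against
    multiple reference genomes (the Relative Averaged Alignment metric), and
    detects homoeologous chromosomal exchanges and introgressions from
    windowed read-depth ratios between concatenated subgenome references
    (Relative Coverage), including cross-mapping background estimation,
    per-window dosage classification and segmentation. Ships a full
    simulator for clustered alignment-statistic panels and hybrid dosage
    mosaics so every analysis step can be exercised and validated without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    withr,
    Rsamtools,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
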