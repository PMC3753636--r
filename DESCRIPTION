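Package: prostar
Title: Promoter and TSS Prediction from DNA Physical Deformability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts transcription start sites (TSSs) from the physical
    deformability of DNA rather than its sequence motifs. Six diagonal
    dinucleotide stiffness constants (twist, tilt, roll, shift, slide,
    rise) annotate a genome at single-step resolution; 500-bp window
    averages of the resulting profiles are classified by comparative
    Mahalanobis distance against promoter and background reference
    profiles trained on known TSSs. The package also implements the
    orthogonal validation analytics used to assess such predictions:
    strand-aware percent-distance-bin profiling of CAGE/RNA-seq tag
    5'-ends over candidate regions, transcription-factor-binding-site
    enrichment by Fisher's exact test with Bonferroni control, and
    region-level chromatin/conservation signal summarisation. Seeded
    synthetic-data generators produce every input with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
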