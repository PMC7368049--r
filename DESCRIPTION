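Package: hetinsul
Title: Insulator-Protein Occupancy at Heterochromatic Gene Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for classifying Drosophila genes as active heterochromatic
    genes from chromatin marks (H3K9me3, HP1a), quantifying insulator-protein
    occupancy (BEAF-32, GAF, dCTCF, Dref) in promoter windows with direct versus
    indirect binding calls from consensus-motif scans, relating occupancy to
    differential expression under BEAF-32 disruption, and comparative promoter
    and selection analyses (ortholog hit chaining, TSS inference, Tamura-Nei 93
    distances, Nei-Gojobori 86 dN/dS). Includes a seeded synthetic-genome
    generator with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
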