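Package: crossbind
Title: Comparative Analysis of Transcription Factor ChIP-Seq Binding Across Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the chromatin binding of one transcription
    factor between two tissues or conditions from called ChIP-seq peaks.
    Provides peak-to-gene association with a promoter/distal-enhancer/intron/
    intergenic location scheme, cross-tissue gene categorization and
    binding-frequency classes, subdivision of peaks into tissue-specific and
    shared (within 2 kb) regulatory elements, position weight matrix scanning
    with Fisher-exact motif enrichment, k-mer seeded de novo motif discovery,
    relative binding-affinity scoring under a position-specific affinity
    matrix with rank-sum comparisons, and a four-way cross-tissue histone-mark
    (H3K27ac/H3K27me3) classification. Includes a synthetic-data generator
    with a machine-readable truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
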