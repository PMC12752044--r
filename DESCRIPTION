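Package: fuseval
Title: Validation and Annotation of Fusion Transcripts with Matched WGS Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validates predicted fusion transcripts at the DNA level using
    matched whole-genome sequencing alignments. Parses Arriba and STAR-Fusion
    call tables, applies pre-validation filters, constructs strand-aware
    search regions around fusion junctions, detects discordant read pairs
    and soft-clip supported genomic breakpoints, and annotates validated
    fusions with alternative-splicing identifiers, promoter-swap status,
    kinases, miRNA host genes, known-fusion database matches and cancer gene
    membership. Includes summary and enrichment statistics, a drug-screen
    association analysis (Welch tests with Benjamini-Hochberg correction),
    and a fully self-contained synthetic data generator (genome, gene
    models, planted fusion events, simulated paired-end WGS reads) with
    ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Transcriptomics, StructuralVariation, Annotation, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
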