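Package: NeuropeptideMiner
Title: Mining and Comparative Annotation of Neuropeptide Precursors from
    Transcriptome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates neuropeptide and protein-hormone precursor proteins
    from transcript or protein sequences: six-frame translation and ORF
    extraction with sequencing-artifact flagging, heuristic signal-peptide
    prediction, prohormone-convertase cleavage-site assignment following
    classical dibasic/monobasic rules, excision of mature peptides with
    C-terminal amidation and pyroglutamate calls, motif-based assignment to
    39 neuropeptide/protein-hormone families, paracopy-count statistics with
    the uncorrected standard deviation, splice-variant grouping, capa/pk
    gene-architecture classification (patterns A to C3), and sequence-logo
    conservation matrices. Includes a synthetic-precursor generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
biocViews: Annotation, SequenceMatching, Transcriptomics, Proteomics
RoxygenNote: 7.3.3
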