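Package: cfFrag
Title: Fragment-Size and End-Motif Profiling of Cell-Free DNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for fragmentomic analysis of circulating cell-free DNA
    (cfDNA) from shallow whole-genome sequencing. Reads aligned fragments
    from BAM or BED with pair-level quality filters, computes per-base-pair
    fragment-size histograms, detects the nucleosomal ladder peaks
    (mono- to tetra-nucleosome) and the 10-bp periodic sub-nucleosomal
    subpeaks, quantifies peak amplitudes with a +/-1 bp read-fraction proxy,
    extracts 8-mer 5' end motifs against a reference genome with per-position
    base content and C-end fractions stratified by fragment size, and
    compares healthy and cancer cohorts with rank-sum and paired t
    statistics. Includes a synthetic cfDNA fragment simulator with built-in
    presets (healthy human plasma, healthy dog plasma, apoptotic HL60 cell
    pellet and supernatant, and a cancer-like profile) so every stage of the
    pipeline can be validated by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, Epigenetics, WholeGenome, Coverage, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cfFrag-package.R'
    'reference.R'
    'endmotif.R'
    'sizeprofile.R'
    'cohort.R'
    'fragio.R'
    'presets.R'
    'simulate.R'
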