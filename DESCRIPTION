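Package: tbseq
Title: Terbium Cleavage Sequencing Analysis of RNA Tertiary Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of terbium(III) chemical-probing sequencing
    experiments, in which lanthanide-catalysed backbone cleavage of folded
    RNA is read out as reverse-transcription termination. Converts aligned
    truncated-cDNA reads into per-nucleotide stop and read-through counts,
    computes stop probabilities, background-subtracted and top-decile
    normalized reactivities, calls reproducible concentration-dependent
    strong cleavage sites, quantifies protein-dependent reactivity changes
    between native and deproteinized lysate probing, and relates called
    sites to local backbone compression (phosphate n to n+2 distances) in
    3-D structures. Includes a simulator of gene-specific-primed
    RT-truncation libraries with known cleavage ground truth so the whole
    pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    bio3d,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
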