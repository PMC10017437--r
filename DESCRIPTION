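Package: ISMobilome
Title: Insertion Sequence Cataloging, Integration Calling and Transposition Statistics for Bacterial Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the insertion-sequence (IS) mobilome of an
    annotated bacterial genome and for detecting active transposition events in
    phenotypically selected mutants. Around each annotated transposase the
    package searches flanking windows for terminal inverted repeats (TIR) and
    flanking target-site duplications (direct repeats, DR), defines full-length
    IS elements, clusters transposases into subtypes by global amino-acid
    identity and assigns IS families against an exemplar set. Given wild-type
    and mutant gene sequences it locates the integration junction, infers the
    target-site duplication, orientation and donor element, predicts PCR
    amplicon enlargement, and classifies the transposition mode (replicative
    versus conservative). A seeded transposition simulator generates genomes
    with planted IS elements and ground-truth events, binomially sampled
    phenotypic selection counts and replicated qPCR Ct tables, so that every
    stage of the pipeline is testable end to end. Selection frequencies are
    reported with Wilson score intervals and relative expression by the
    2^-deltadeltaCt method with per-comparison t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Genetics, SequenceMatching, Annotation, MobileElements
Config/testthat/edition: 3
RoxygenNote: 7.3.3
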