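Package: amplindel
Title: InDel Analysis in Multi-Copy Gene Families from CRISPR Amplicon
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes CRISPR/Cas9-induced insertions and
    deletions (InDels) in multi-copy, high-homology gene families (such as
    the wheat alpha-gliadins at the Gli-2 loci) from paired-end amplicon
    sequencing, without a single fixed reference sequence.  Implements the
    full read-processing chain (pair merging, expected-error filtering,
    dereplication, UNOISE-style denoising into unique denoised amplicons,
    identity search), Bayesian optimization of the five pipeline
    parameters, TMM normalization with per-line frequencies and a presence
    threshold, classification of amplicons into wild-type and CRISPR
    classes across generations, neighbor-joining dendrograms used to pick
    the closest wild-type reference for each edited amplicon, cut-site
    anchored InDel calling, qPCR relative copy-number estimation, and a
    synthetic fixture generator emulating a subgenome-structured gene
    family with edited copies and sequencing errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    methods,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
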