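Package: helscan
Title: Structural Annotation of Helitron Transposons and Genome-Scale
    Helitron Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate Helitron rolling-circle transposons in
    nucleotide sequences from their conserved structural signature: a GC-rich
    palindromic hairpin 2-10 nt upstream of a CTRR-family (mostly CTAG) 3'
    terminus, with candidate 5' TC ends searched upstream, on both strands of
    whole-genome FASTA input. Writes terminal-end and full-length FASTA plus
    GFF3 annotation. Companion analytics treat Helitron density (3' termini
    per Mb) as a genome characteristic: dispersion statistics, bootstrap
    Pearson correlation, 1 Mb / 500 kb sliding-window densities, linear
    discriminant species classification, median-linkage clustering,
    insertion-site typing against gene annotation, composition-matched
    random-genome false-positive estimation, and association-rule mining of
    Helitron presence/absence against a categorical phenotype.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    boot,
    parallel,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
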