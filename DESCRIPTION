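Package: mitoprofile
Title: Descriptive Analytics for Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the descriptive stage of insect mitochondrial genome
    studies: gene-organization geometry on circular coordinates (intergenic
    spacers, overlaps, strand tallies), nucleotide composition and AT/GC skew
    statistics by feature class, strand and codon position, codon usage under
    the invertebrate mitochondrial genetic code (relative synonymous codon
    usage and amino-acid composition), template-constrained tRNA clover-leaf
    folding with a mismatch census, and control-region motif scanners for
    poly-T stretches, (TA)n repeats and G(A)nT elements.  A synthetic
    mitogenome generator with a planted-truth record makes the whole pipeline
    testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
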