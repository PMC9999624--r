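Package: pseudohet
Title: Mapping Cryptic Gene Duplications from Pseudo-Heterozygosity in
    Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects cryptic copy-number variation in highly selfing
    (inbred) populations from the spurious heterozygous SNP calls that
    arise when short reads from a diverged duplicate copy mis-map onto
    the original locus of a reference genome. Provides a forward
    simulator of selfed founder-mosaic populations with segregating
    duplications, run-of-heterozygosity scanning, pseudo-SNP filtering,
    an accelerated (EMMAX-style) linear mixed-model association scan
    using heterozygosity as a binary phenotype, FFT-smoothed peak
    calling with cis/trans classification, alignment-based confirmation
    of duplicate copies in assembled genomes, read-pair insertion
    presence calls, and quantification of the methylation-call
    artifacts caused by reference-collapsed bisulfite mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
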