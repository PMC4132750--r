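Package: periodscan
Title: Dinucleotide Periodicity Analysis of Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spectral quantification and localization of ~11 bp dinucleotide
    sequence periodicity in bacterial genomes. Computes motif autocorrelation
    functions and normalized power spectra of AT-tract motifs, scans genomes in
    200 bp windows with dinucleotide-preserving permutation tests, concatenates
    significantly periodic windows into genome segments, tests their overlap
    with annotation by Jaccard interval-permutation tests, dissects how the
    periodic signal is embedded in protein-coding sequence via codon
    permutation schemes, and clusters coding sequences by their periodicity
    spectra. Includes a synthetic-genome generator with implanted phased
    AT-tracts for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
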