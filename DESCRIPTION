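Package: mgpipe
Title: Metagenomic Read Processing, Abundance Profiling and Assembly Revision
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A self-contained toolkit for shotgun metagenomic sequencing data:
    quality trimming and filtering of raw Illumina-style reads (longest-segment
    and 3'-threshold trimming, 5' base-composition-bias trimming), a built-in
    seed-and-extend read mapper with screening and filtering against reference
    databases, genome-size-normalized base/read/insert coverage and relative
    abundance estimation, run-time assembly parameter estimation (k-mer size,
    insert size), scaftig extraction and assembly statistics, pileup-based
    assembly revision (consensus base/indel correction and chimera splitting),
    a synthetic community simulator with ground-truth logs, and a light
    per-sample pipeline layer with TSV/SQLite summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RSQLite,
    DBI,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
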