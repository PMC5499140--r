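Package: erscan
Title: Selection Scans for Evolve-and-Resequence Pool-Seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects selected loci in evolve-and-resequence (E&R) experiments
    from replicated pooled-sequencing allele counts. Reads and writes
    PoPoolation2-style sync files, applies the standard SNP-calling and
    coverage filters, tests for consistent allele-frequency change across
    replicates with the Cochran-Mantel-Haenszel test, estimates temporal
    effective population size in SNP windows from the Fc statistic with
    two-stage pool-seq sampling corrections, calibrates an empirical
    significance cutoff at a nominal false-positive rate against matched
    neutral Wright-Fisher simulations, and delimits selected genomic regions
    by sliding-window averaging and merging. Includes a synthetic-data
    generator with planted selected loci and linked blocks for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
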