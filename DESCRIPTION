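Package: methylKL
Title: Depth-Matched Binomial Null and Relative-Entropy Analysis of CpG
    Methylation Bimodality
Version: 0.1.0
Authors@R:
    person("methylKL", "Maintainers", email = "methylkl@example.org",
           role = c("aut", "cre"))
Description: Quantifies how strongly the bimodality of per-CpG methylation
    levels (beta values) from whole-genome bisulfite sequencing deviates from
    what heterogeneous sequencing depth alone would produce.  Builds the
    observed beta-value distribution over exact reduced fractions, constructs
    an analytic depth-matched binomial null, and measures the deviation with
    relative-entropy statistics at the unmethylated and fully methylated
    endpoints (KL(0), KL(1)) as well as the full Kullback-Leibler divergence
    and direct endpoint differences.  Analyses can be stratified by
    strand-aware flanking-sequence context (N5CGN3 tetranucleotides and N5CG
    trinucleotides), by sequencing depth, and by genomic region sets.
    Includes readers for Bismark-style cytosine reports, bedGraph coverage
    files, FASTA references and BED region sets, a seeded synthetic methylome
    generator for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    optparse,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
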