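Package: kmerbatch
Title: Batch-Effect Diagnostics from DNA k-mer Spectra of FASTQ Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free quality control for high-throughput
    sequencing experiments. Counts DNA k-mers from FASTQ files (plain or
    gzip, Phred+33) into dense profiles, scales profiles to a common
    sequencing depth, compares samples under the Canberra distance and
    clusters them hierarchically. Trees annotated with preparation
    groups (flowcells, batches) are summarised into diagnostics: the
    Contralaterality Score, a semi-quantitative batch-effect class, the
    largest pure-group subtree, and per-motif spectrum comparisons. A
    seeded simulation framework with controlled motif contamination
    provides the null distribution, significance threshold and power
    curves of the method.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
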