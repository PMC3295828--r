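Package: syserr
Title: Detection, Characterization and Correction of Systematic
    Base-Call Errors in Short-Read Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistics and tools for genomic positions at which base-call
    errors from many independent short reads accumulate far beyond the
    background error rate ("systematic errors").  Builds per-site pileups
    from SAM alignments, classifies base-call pairs from overlapping
    paired-end mates (reference-, SNP- and error-pairs), annotates sites
    with exact binomial and quality-conditioned Poisson-binomial p-values
    under Bonferroni control, screens single-end data with a strand
    directionality chi-square test, characterizes error sites by sequence
    motif and substitution spectrum, and trains a coverage-stratified
    logistic-regression classifier that separates true heterozygous sites
    from systematic errors.  A read simulator with planted heterozygous
    and systematic-error sites makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
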