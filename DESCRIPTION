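Package: spikecal
Title: Spike-In Based Systematic Sequencing Error Analysis and Base
    Quality Score Recalibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying systematic sequencing errors (SSEs) with
    synthetic spike-in standards. Generates ERCC-style plasmid reference
    sets and concentration pools, simulates aligned reads with a known
    covariate-dependent error process (reported-quality miscalibration by
    machine cycle, dinucleotide context and per-site effects), certifies
    high-purity reference bases with a beta-binomial posterior, performs
    GATK-style base quality score recalibration (BQSR) trained on the
    spike-in reads, and provides the evaluation machinery for comparing
    recalibration tables: split-half weighted mean absolute differences,
    read and reference downsampling, nucleotide-change error rates with
    transition/transversion ratios, and per-cell significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
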