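Package: edscan
Title: Euclidean-Distance Association Mapping for Two-Pool
    Bulked-Segregant Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome scans for trait-associated regions from pooled
    whole-genome re-sequencing of two phenotypically contrasting bulks,
    as used to map the multi-silique trait in rapeseed near-isogenic
    lines.  Computes the per-site Euclidean Distance (ED) statistic from
    pooled allele depths, applies a power transform to suppress
    background noise, fits a distance-weighted (tricube kernel) profile
    along each chromosome, and calls associated regions above a
    center + k x spread threshold.  SNP and InDel marker classes are
    scanned independently and their region sets intersected; regions are
    annotated with gene models and overlapped with differential-expression
    results.  Includes a seeded synthetic near-isogenic-line pool
    generator (binomial allele depths at configurable coverage, localized
    allele-frequency divergence with linear linkage decay) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
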