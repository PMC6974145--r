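Package: splicedose
Title: Multi-Resolution Splicing QTL Analysis for Cassette Exons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the effect of genetic variants on alternative
    splicing of a cassette exon at five resolution levels: transcript,
    exonic part, exon-exon junction, splice site and intron. Provides a
    gene-model layer that flattens transcript annotations into
    non-overlapping exonic parts, pseudo-transcript introns and junctions;
    quantification of aligned spliced reads with junction overhang
    filtering, RPKM/RPM normalisation, percent-spliced-in estimation and an
    EM estimator of isoform proportions from junction compatibility
    classes; additive linear-model cis-eQTL fitting with covariates and
    conditional two-SNP analysis; a genotype-to-band association analysis
    with a from-first-principles exact test; and a synthetic-data generator
    that simulates two SNPs in linkage disequilibrium driving logit-linear
    exon inclusion with Poisson read counts, for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    IRanges
Config/testthat/edition: 3
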