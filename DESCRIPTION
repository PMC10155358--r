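Package: oxDMR
Title: Paired Bisulfite/Oxidative-Bisulfite Methylome Analysis: 5hmC
    Estimation, DMR Calling and Biomarker Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for base-resolution analysis of paired reduced-representation
    bisulfite (RRBS) and oxidative RRBS (oxRRBS) sequencing data.  Estimates
    per-CpG 5-hydroxymethylcytosine (5hmC) levels by subtraction of the oxidised
    from the plain bisulfite methylation ratio (with clamped and constrained
    maximum-likelihood variants), calls differentially methylated regions (DMRs)
    between sample groups with mark-specific effect-size gates and
    Benjamini-Hochberg false-discovery control, annotates DMRs to genomic
    categories (promoter, exon, TTS, intron, intergenic), and screens DMRs as
    univariate rank-based AUC biomarkers.  Includes a seeded synthetic-cohort
    generator for paired BS/oxBS binomial counts with planted region-level
    effects and conversion-chemistry error rates, used to demonstrate that
    mixed 5mC+5hmC bisulfite signal attenuates biomarker performance when the
    two marks are anti-correlated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
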