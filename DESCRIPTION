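Package: msyscan
Title: Delineation of the Male-Specific Region of a Y Chromosome from
    X-Y Divergence, Sex-Linked Markers and Repeat Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to delineate the male-specific region (MSY) and the
    pseudoautosomal region (PAR) of a Y chromosome from a haplotype-resolved
    assembly. Implements trio-binning read classification with parent-unique
    k-mers (hap-mers), orthologous X-Y pairwise alignment by k-mer seeding,
    co-linear chaining, gap filling and single-coverage netting, a windowed
    SNP-plus-indel divergence statistic with changepoint detection of the
    PAR/MSY boundary, RAD-tag catalog construction with male-only marker
    calling and ungapped tag mapping under a Karlin-Altschul E-value cutoff,
    a pooled-sequencing sex-specific SNP window scan, evidence-based gene
    model merging with terminal-exon rescue, Kimura two-parameter repeat age
    contrasts, and an integrated consensus MSY report. A seeded synthetic
    sex-chromosome generator with planted ground truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
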