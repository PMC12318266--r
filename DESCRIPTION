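Package: hepzone
Title: Hepatic Lobule Zonation Analysis for Single-Nucleus RNA-Seq and smFISH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying spatial organization of gene expression
    across the liver lobule. Implements diffusion-map pseudodistance ordering
    of hepatocyte nuclei, spline-based zonation testing of binned expression
    profiles with parametric ANOVA, discovery of zonated gene-expression
    modules by hierarchical clustering, hypergeometric gene-set overlap with
    Benjamini-Hochberg adjustment, within-cluster genotype differential
    expression and ratio-slope attenuation statistics, radial (10-bin)
    quantification of smFISH transcript spots relative to central and portal
    vein outlines, and genotype-dosage association statistics for aggregate
    and individual-level cohorts. Includes synthetic-data generators with
    known ground truth for zonated count matrices, smFISH spot fields, and
    Hardy-Weinberg cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    mgcv,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
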