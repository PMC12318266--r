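# hepzone

Quantifying the spatial organization of gene expression across the liver
lobule — and what happens to it when a zonation-controlling transcription
factor is lost.

Hepatocytes are not interchangeable: cells near the central vein
(pericentral) and near the portal triad (periportal) run different
metabolic programs, and many genes express along smooth gradients in
between. `hepzone` is an R package for analysts working with
single-nucleus RNA-seq, smFISH imaging, or human genotype data who need
to measure that organization:

- **Lobular coordinate reconstruction.** A diffusion map on the top 30
  principal components of log-normalized expression, diffusion pseudotime
  from a marker-anchored root, rescaled and oriented into a *diffusion
  pseudodistance* (DPD) in [0, 1], with DPD = 0 at the pericentral end.
- **Zonation testing.** Expression is averaged in 80 DPD bins per
  genotype and each gene is tested with a 4-df cubic B-spline regression
  (occupancy-weighted) against an intercept-only model by a nested
  F-test; a gene is zonated when p < 0.05 (strict). Genes are classified
  as zonated in both genotypes, control-only, knockout-only, or neither.
- **Module discovery and overlap.** Zonated genes, represented by
  z-scored 8-bin profiles per genotype (16 values), are clustered with
  1 − Pearson distance and complete linkage into modules A–D, and each
  module is scored against reference gene sets by the upper-tail
  hypergeometric test with Benjamini–Hochberg adjustment.
- **Differential expression and attenuation.** Equal-variance t-tests
  within clusters (genes expressed in >10% of both genotypes, BH FDR),
  and the ratio-slope statistic: regressing knockout pericentral/
  periportal log2 expression ratios on control ratios — a slope below 1
  means inter-zone contrast has collapsed.
- **smFISH radial quantification.** Spots are assigned to 10 bins by
  r = d_CV / (d_CV + d_PV) (distances to the central and portal vein
  outlines), counts are normalized by per-bin pixel area, reported as
  percentages, and averaged per mouse. A simple Laplacian-of-Gaussian
  detector with sub-pixel refinement handles sparse spot images.
- **Genotype-dosage association.** Prevalences and chi-squared tests from
  aggregate genotype-by-case tables, crude per-allele odds ratios,
  logistic/linear per-allele regressions with covariates, and a
  Bonferroni-thresholded multi-biomarker scan.
- **Synthetic generators with ground truth** for all three data kinds:
  zonated negative-binomial count matrices with configurable knockout
  effects (flatten / ablate / expand), inhomogeneous-Poisson smFISH spot
  fields around vein polygons, and Hardy–Weinberg cohorts with per-allele
  disease and biomarker effects.

## Worked example

Simulate a two-genotype lobule, reconstruct the lobular coordinate, and
test zonation per genotype:

```r
library(hepzone)

sim  <- simulate_lobule(lobule_sim_config(n_nuclei_per_genotype = 500,
                                          seed = 1))
norm <- normalize_log(sim$counts)
markers <- list(pericentral = sprintf("PC%03d", 1:20),
                periportal  = sprintf("PP%03d", 1:20))
scores <- score_markers(norm, markers)

dpd <- compute_dpd(norm, scores)
cor(dpd$dpd, sim$truth$u, method = "spearman")
#> [1] 0.903

geno <- sim$truth$genotype
res_con <- test_zonation(profile_bins(norm[, geno == "CON"],
                                      dpd$dpd[geno == "CON"], 80))
res_ko  <- test_zonation(profile_bins(norm[, geno == "KO"],
                                      dpd$dpd[geno == "KO"], 80))
classify_zonation(res_con, res_ko)$counts
#>     both con_only  ko_only  neither
#>       66       49        9       76
```

The reconstructed DPD rank-correlates at 0.90 with the latent coordinate
the generator drew. The simulation plants 40 genes whose gradients are
flattened in the knockout and 60 zonated genes left intact (plus 100
unzonated genes): the classifier reports 49 control-only genes (the 40
planted losses plus a handful of borderline calls), 66 zonated in both,
and a knockout-only/neither remainder consistent with the 5% test size.

Aggregate genotype statistics work directly on published-style count
tables:

```r
t1 <- data.frame(dosage = 0:2, n = c(54649, 44178, 9192),
                 cases = c(2353, 2508, 698))
genotype_prevalence(t1)$prevalence$percent_1dp
#> [1] 4.3 5.7 7.6
per_allele_regression(t1)$or
#> [1] 1.347273
```

— the per-T-allele odds ratio for type 2 diabetes fitted by grouped
logistic regression on dosage (unadjusted, so slightly below
covariate-adjusted published estimates).

See `vignettes/hepzone-methods.Rmd` for the models, parameter defaults,
numerical conventions, and what the synthetic generators do and do not
emulate.

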