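# Within-cluster genotype differential expression, BH adjustment, the
# HEP2/HEP1 ratio-slope attenuation statistic, and the metabolite
# volcano filter.

#' Differential expression between genotypes within a cluster
#'
#' Genes expressed (nonzero) in strictly more than `min_fraction` of the
#' nuclei of BOTH genotypes are tested by a two-sample equal-variance
#' Student t-test on normalized expression; p-values are BH-adjusted over
#' the tested genes. A gene passes when its expressed fractions exceed the
#' threshold in both genotypes and its FDR is below `fdr`.
#'
#' @param norm Normalized genes x nuclei matrix.
#' @param clusters Cluster label per nucleus.
#' @param genotypes Genotype label per nucleus (two levels within the
#'   cluster, conventionally CON and KO).
#' @param cluster The cluster to test.
#' @param min_fraction Expressed-fraction threshold (strict; default 0.10).
#' @param fdr FDR threshold for the pass flag (default 0.05).
#' @return data.frame per tested gene: `gene`, `mean_con`, `mean_ko`,
#'   `frac_con`, `frac_ko`, `t`, `p`, `fdr`, `pass`. Untested genes are
#'   omitted.
#' @export
de_within_cluster <- function(norm, clusters, genotypes, cluster,
                              min_fraction = 0.10, fdr = 0.05) {
  sel <- clusters == cluster
  if (!any(sel)) stop("cluster ", cluster, " is empty")
  gt <- genotypes[sel]
  levs <- sort(unique(gt))
  if (length(levs) != 2)
    stop("cluster ", cluster, " does not contain exactly two genotypes")
  x <- as.matrix(norm[, sel, drop = FALSE])
  a <- x[, gt == levs[1], drop = FALSE]
  b <- x[, gt == levs[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) stop("need at least two nuclei per genotype")
  frac1 <- rowMeans(a > 0); frac2 <- rowMeans(b > 0)
  test <- frac1 > min_fraction & frac2 > min_fraction
  if (!any(test)) return(data.frame())
  a <- a[test, , drop = FALSE]; b <- b[test, , drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(abs(t), df = n1 + n2 - 2, lower.tail = FALSE)
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  q <- bh_adjust(p)
  data.frame(gene = rownames(a), mean_con = m1, mean_ko = m2,
             frac_con = frac1[test], frac_ko = frac2[test],
             t = t, p = p, fdr = q, pass = q < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, preserving
#' names and returning an empty vector for empty input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Ratio-slope statistic: attenuation of inter-cluster contrast in the KO
#'
#' For each gene, the log2 ratio of its mean normalized expression in the
#' pericentral cluster (HEP2) versus the periportal cluster (HEP1) is
#' computed per genotype (with a small pseudocount), and the KO ratios are
#' regressed on the CON ratios by ordinary least squares. A slope below 1
#' indicates that the transcriptional contrast between the clusters is
#' attenuated in the knockout.
#'
#' @param norm Normalized genes x nuclei matrix.
#' @param clusters Cluster label per nucleus.
#' @param genotypes Genotype label per nucleus (`"CON"`/`"KO"`).
#' @param hep1,hep2 The periportal and pericentral cluster labels.
#' @param genes Genes to use (default: all rows); at least 3 required.
#' @param eps Pseudocount added to the cluster means (default 1e-9).
#' @return List: `slope`, `intercept`, `ci` (95% for the slope),
#'   `n_genes`, and the per-gene `ratios` data.frame.
#' @export
ratio_slope <- function(norm, clusters, genotypes, hep1, hep2,
                        genes = rownames(norm), eps = 1e-9) {
  if (length(genes) < 3) stop("need at least 3 genes for the ratio slope")
  x <- as.matrix(norm[genes, , drop = FALSE])
  cl_mean <- function(geno, cl) {
    sel <- genotypes == geno & clusters == cl
    if (!any(sel)) stop("no nuclei for genotype ", geno, " in cluster ", cl)
    rowMeans(x[, sel, drop = FALSE])
  }
  r_con <- log2((cl_mean("CON", hep2) + eps) / (cl_mean("CON", hep1) + eps))
  r_ko <- log2((cl_mean("KO", hep2) + eps) / (cl_mean("KO", hep1) + eps))
  fit <- stats::lm(r_ko ~ r_con)
  ci <- stats::confint(fit)["r_con", ]
  list(slope = unname(stats::coef(fit)["r_con"]),
       intercept = unname(stats::coef(fit)[1]),
       ci = unname(ci), n_genes = length(genes),
       ratios = data.frame(gene = genes, con = r_con, ko = r_ko,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Volcano filter for metabolite tables
#'
#' Keeps metabolites with `-log10(p) > 1.3` and `|log2 fold change| > 1`
#' (both strict) and tabulates the category composition of the
#' significant subset.
#'
#' @param table data.frame with columns `name`, `category`, `p`,
#'   `log2fc`.
#' @return List: `significant` (the passing rows) and `proportions`
#'   (named vector over categories, summing to 1 when any row passes).
#' @export
volcano_filter <- function(table) {
  stopifnot(all(c("name", "category", "p", "log2fc") %in% names(table)))
  if (any(table$p <= 0)) stop("p-values must be positive")
  if (any(table$p > 1)) stop("p-values must not exceed 1")
  keep <- -log10(table$p) > 1.3 & abs(table$log2fc) > 1.0
  sig <- table[keep, , drop = FALSE]
  props <- if (nrow(sig) > 0) {
    tab <- table(sig$category)
    stats::setNames(as.numeric(tab) / nrow(sig), names(tab))
  } else stats::setNames(numeric(0), character(0))
  list(significant = sig, proportions = props)
}
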