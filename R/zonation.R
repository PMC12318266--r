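# Binned zonation profiles along DPD, spline-ANOVA zonation testing,
# genotype classification, module discovery and gene-set overlap.

#' Bin expression along diffusion pseudodistance
#'
#' Equal-width bins on `[0, 1]`; a value of exactly 1 falls in the last
#' bin. Per gene and bin, the mean normalized expression over the nuclei in
#' the bin; empty bins are `NA` with a zero occupancy count.
#'
#' @param norm Normalized genes x nuclei matrix.
#' @param dpd Numeric DPD per nucleus in `[0, 1]` (or a `dpd` object).
#' @param n_bins Number of bins (2 or more; 80 for testing, 8 for module
#'   profiles). `n_bins = 1` is allowed as the degenerate overall mean.
#' @return A `zonation_profile` list: `means` (genes x bins), `counts`
#'   (nuclei per bin), `midpoints`.
#' @export
profile_bins <- function(norm, dpd, n_bins = 80) {
  if (inherits(dpd, "dpd")) dpd <- dpd$dpd
  stopifnot(length(dpd) == ncol(norm), n_bins >= 1)
  if (any(!is.finite(dpd)) || any(dpd < 0 | dpd > 1))
    stop("dpd values must lie in [0, 1]")
  bin <- pmin(floor(dpd * n_bins), n_bins - 1) + 1L
  counts <- tabulate(bin, n_bins)
  means <- matrix(NA_real_, nrow(norm), n_bins,
                  dimnames = list(rownames(norm), NULL))
  x <- as.matrix(norm)
  for (b in which(counts > 0))
    means[, b] <- rowMeans(x[, bin == b, drop = FALSE])
  structure(list(means = means, counts = counts,
                 midpoints = (seq_len(n_bins) - 0.5) / n_bins),
            class = "zonation_profile")
}

#' Test genes for zonation by spline regression on binned profiles
#'
#' For each gene, fits weighted least squares of per-bin mean expression on
#' a cubic B-spline basis of the bin midpoint (`df_spline` basis columns),
#' with weights equal to per-bin nucleus counts, and compares it with the
#' intercept-only model by a nested F-test (parametric ANOVA). A gene is
#' called zonated when p is strictly below `alpha`. Empty bins are dropped
#' from the fit; a constant gene has F = 0 and p = 1.
#'
#' @param profile A [profile_bins()] result (80 bins in the reference
#'   workflow).
#' @param df_spline Spline degrees of freedom (basis columns; default 4).
#' @param alpha Significance level for the zonated call (default 0.05,
#'   strict inequality).
#' @return data.frame: `gene`, `f`, `df1`, `df2`, `p`, `zonated`.
#' @export
test_zonation <- function(profile, df_spline = 4, alpha = 0.05) {
  stopifnot(inherits(profile, "zonation_profile"))
  keep <- profile$counts > 0
  if (sum(keep) < 10)
    stop("fewer than 10 non-empty bins; cannot fit the spline model")
  x <- profile$midpoints[keep]
  w <- profile$counts[keep]
  y <- t(profile$means[, keep, drop = FALSE])   # bins x genes
  basis <- splines::bs(x, df = df_spline)
  X1 <- cbind(1, basis)
  n <- length(x); p1 <- ncol(X1)
  if (n - p1 <= 0) stop("zero residual degrees of freedom")

  # shared design across genes: one weighted QR, matrix response
  sw <- sqrt(w)
  fit1 <- stats::lm.fit(X1 * sw, y * sw)
  rss1 <- colSums(fit1$residuals^2)
  ybar <- colSums(y * w) / sum(w)
  rss0 <- colSums((y - rep(ybar, each = n))^2 * w)
  df1 <- p1 - 1; df2 <- n - p1
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # constant profiles: no variance to explain => F = 0, p = 1
  const <- rss0 <= max(rss0, 1) * 1e-14
  f[const] <- 0; p[const] <- 1
  data.frame(gene = colnames(y), f = f, df1 = df1, df2 = df2, p = p,
             zonated = p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify genes by zonation status across genotypes
#'
#' @param results_con,results_ko [test_zonation()] results for the control
#'   and knockout genotypes over the same gene list.
#' @return List with `classification` (data.frame `gene`, `category` in
#'   both/con_only/ko_only/neither) and `counts` (named integer vector,
#'   summing to the panel size).
#' @export
classify_zonation <- function(results_con, results_ko) {
  if (!identical(sort(results_con$gene), sort(results_ko$gene)))
    stop("genotype result sets cover different gene lists")
  ko <- results_ko[match(results_con$gene, results_ko$gene), ]
  cat <- ifelse(results_con$zonated & ko$zonated, "both",
         ifelse(results_con$zonated, "con_only",
         ifelse(ko$zonated, "ko_only", "neither")))
  counts <- vapply(c("both", "con_only", "ko_only", "neither"),
                   function(k) sum(cat == k), integer(1))
  list(classification = data.frame(gene = results_con$gene, category = cat,
                                   stringsAsFactors = FALSE),
       counts = counts)
}

#' Discover zonation modules by hierarchical clustering
#'
#' Each zonated gene is represented by its concatenated 8-bin control and
#' knockout profiles (16 values), z-scored per gene. Distance is
#' 1 - Pearson correlation; complete-linkage agglomeration, tree cut at
#' `k` clusters (modules labeled A, B, C, ...).
#'
#' @param profile_con,profile_ko 8-bin [profile_bins()] results per
#'   genotype.
#' @param genes Character vector of zonated genes to cluster.
#' @param k Number of modules (default 4).
#' @return List with `modules` (data.frame `gene`, `module`),
#'   `centroids` (module x 16 mean z-profile) and the `hclust` tree.
#' @export
cluster_modules <- function(profile_con, profile_ko, genes, k = 4) {
  if (k > length(genes))
    stop("k exceeds the number of zonated genes")
  v <- cbind(profile_con$means[genes, , drop = FALSE],
             profile_ko$means[genes, , drop = FALSE])
  if (anyNA(v)) stop("empty bins in the 8-bin profiles; use wider bins")
  mu <- rowMeans(v); sd <- apply(v, 1, stats::sd)
  z <- (v - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  cors <- suppressWarnings(stats::cor(t(z)))
  cors[!is.finite(cors)] <- 0
  d <- stats::as.dist(1 - cors)
  tree <- stats::hclust(d, method = "complete")
  cut <- stats::cutree(tree, k = k)
  # module labels A.. assigned by first appearance along the gene list
  lab <- LETTERS[match(cut, unique(cut))]
  centroids <- do.call(rbind, lapply(unique(cut), function(m)
    colMeans(z[cut == m, , drop = FALSE])))
  rownames(centroids) <- LETTERS[seq_along(unique(cut))]
  list(modules = data.frame(gene = genes, module = lab,
                            stringsAsFactors = FALSE),
       centroids = centroids, tree = tree)
}

#' Hypergeometric overlap of a gene module with a reference set
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' intersection when `|module|` genes are drawn without replacement from
#' the universe containing `|set|` successes. Overlap fraction uses the
#' union denominator by default.
#'
#' @param module,set Character vectors of genes, both subsets of
#'   `universe`.
#' @param universe Character vector: the gene universe.
#' @param denominator `"union"` (default), `"set"` or `"min"` for the
#'   overlap-fraction denominator.
#' @return One-row data.frame: `overlap`, `fraction`, `p`.
#' @export
hypergeom_overlap <- function(module, set, universe,
                              denominator = c("union", "set", "min")) {
  denominator <- match.arg(denominator)
  if (length(universe) == 0) stop("empty universe")
  if (!all(module %in% universe) || !all(set %in% universe))
    stop("module and set must be subsets of the universe")
  module <- unique(module); set <- unique(set)
  ov <- length(intersect(module, set))
  denom <- switch(denominator,
                  union = length(union(module, set)),
                  set = length(set),
                  min = min(length(module), length(set)))
  p <- stats::phyper(ov - 1, m = length(set),
                     n = length(universe) - length(set),
                     k = length(module), lower.tail = FALSE)
  data.frame(overlap = ov,
             fraction = if (denom > 0) ov / denom else 0,
             p = p)
}

#' Overlap every module with every reference gene set
#'
#' Runs [hypergeom_overlap()] for each module x set pair and adjusts the
#' p-values across all pairs by Benjamini-Hochberg.
#'
#' @param modules data.frame `gene`, `module` ([cluster_modules()]).
#' @param sets Named list of character vectors (e.g. beta-catenin induced
#'   and suppressed genes).
#' @param universe Gene universe for the hypergeometric model.
#' @inheritParams hypergeom_overlap
#' @return data.frame: `module`, `set`, `overlap`, `fraction`, `p`,
#'   `p_adj`.
#' @export
overlap_table <- function(modules, sets, universe,
                          denominator = c("union", "set", "min")) {
  denominator <- match.arg(denominator)
  ids <- sort(unique(modules$module))
  rows <- list()
  for (m in ids) for (s in names(sets)) {
    r <- hypergeom_overlap(modules$gene[modules$module == m],
                           intersect(sets[[s]], universe), universe,
                           denominator)
    rows[[length(rows) + 1L]] <- cbind(data.frame(module = m, set = s,
                                                  stringsAsFactors = FALSE),
                                       r)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}
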