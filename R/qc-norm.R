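# Nucleus-level QC, library-size normalization, marker scoring and
# graph-based clustering.

#' Filter nuclei on detected genes and mitochondrial fraction
#'
#' Retains nuclei with at least `min_genes` detected (nonzero) genes and a
#' mitochondrial read fraction strictly below `max_mito`; a nucleus at
#' exactly `max_mito` is discarded. Idempotent; nucleus order preserved.
#'
#' @param x List with `counts` (genes x nuclei), `genes` (with logical
#'   `mito` column) and `nuclei`, as returned by [simulate_lobule()] or
#'   [read_counts_mtx()].
#' @param min_genes Minimum detected-gene count (inclusive).
#' @param max_mito Mitochondrial fraction at or above which a nucleus is
#'   discarded.
#' @return `x` restricted to passing nuclei, with `nuclei` gaining
#'   `n_features` and `mito_fraction` columns.
#' @export
filter_nuclei <- function(x, min_genes = 500, max_mito = 0.02) {
  stopifnot(!is.null(x$genes$mito))
  n_features <- Matrix::colSums(x$counts > 0)
  totals <- Matrix::colSums(x$counts)
  mito_counts <- if (any(x$genes$mito))
    Matrix::colSums(x$counts[x$genes$mito, , drop = FALSE]) else
      rep(0, ncol(x$counts))
  mito_fraction <- ifelse(totals > 0, mito_counts / totals, 0)
  keep <- n_features >= min_genes & mito_fraction < max_mito
  if (!any(keep)) stop("all nuclei removed by QC filters")
  x$counts <- x$counts[, keep, drop = FALSE]
  x$nuclei <- x$nuclei[keep, , drop = FALSE]
  x$nuclei$n_features <- as.integer(n_features[keep])
  x$nuclei$mito_fraction <- mito_fraction[keep]
  if (!is.null(x$truth)) {
    x$truth$u <- x$truth$u[keep]
    x$truth$genotype <- x$truth$genotype[keep]
    x$truth$nucleus <- x$truth$nucleus[keep]
    x$truth$size_factor <- x$truth$size_factor[keep]
  }
  x
}

#' Log-normalize counts by library size
#'
#' `log1p(count * scale / nucleus_total)`, the standard log-normalization
#' of droplet data. Zeros map to zero, so the sparsity pattern is
#' preserved.
#'
#' @param counts Genes x nuclei count matrix (sparse or dense).
#' @param scale Scale factor (default 1e4).
#' @return Genes x nuclei sparse normalized matrix.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("nucleus with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  m <- methods::as(counts, "CsparseMatrix")
  # operate on the nonzero slots only; log1p(0) = 0 keeps zeros in place
  col_of <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * scale / totals[col_of])
  m
}

#' Score nuclei for marker-set expression
#'
#' Per-nucleus score of a marker set: mean over member genes of the
#' gene-wise z-scored normalized expression. Genes with zero variance
#' contribute 0; markers missing from the panel are dropped with a
#' warning.
#'
#' @param norm Normalized genes x nuclei matrix with rownames.
#' @param markers List with `pericentral` and `periportal` character
#'   vectors ([read_marker_sets()]).
#' @return data.frame with per-nucleus `pericentral` and `periportal`
#'   scores.
#' @export
score_markers <- function(norm, markers) {
  score_one <- function(set, label) {
    present <- intersect(set, rownames(norm))
    if (length(present) == 0L)
      stop("no ", label, " marker genes found in the panel")
    if (length(present) < length(set))
      warning(length(set) - length(present), " ", label,
              " marker(s) absent from the panel; dropped")
    sub <- as.matrix(norm[present, , drop = FALSE])
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    z <- (sub - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    colMeans(z)
  }
  data.frame(pericentral = score_one(markers$pericentral, "pericentral"),
             periportal = score_one(markers$periportal, "periportal"),
             row.names = colnames(norm))
}

#' Cluster nuclei by PCA, k-nearest neighbors and Louvain communities
#'
#' PCA of the normalized matrix, a shared k-nearest-neighbor graph in PC
#' space, and modularity-based Louvain community detection at the given
#' resolution. Deterministic for a given `seed`.
#'
#' @param norm Normalized genes x nuclei matrix.
#' @param n_pcs Number of principal components (default 12).
#' @param resolution Louvain resolution parameter (default 0.12).
#' @param k_neighbors Neighbors per nucleus in the kNN graph.
#' @param seed Seed for the community search.
#' @return Integer cluster labels (1-based), one per nucleus.
#' @export
cluster_nuclei <- function(norm, n_pcs = 12, resolution = 0.12,
                           k_neighbors = 20, seed = 1L) {
  stopifnot(n_pcs >= 2, resolution > 0)
  if (ncol(norm) < k_neighbors)
    stop("fewer nuclei than k_neighbors")
  pcs <- pca_scores(norm, n_pcs)
  if (ncol(pcs) < 2) return(rep(1L, ncol(norm)))  # degenerate geometry
  d <- as.matrix(stats::dist(pcs))
  n <- nrow(d)
  k <- min(k_neighbors, n - 1)
  edges <- lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(k + 1)]
    cbind(i, nb)
  })
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm))
}

# PCA scores (nuclei x components). A zero-rank (all-identical) matrix
# yields a single zero column. With strict = TRUE, asking for more
# components than the rank is an error; otherwise the request is capped.
pca_scores <- function(norm, n_pcs, strict = TRUE) {
  x <- t(as.matrix(norm))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pos <- sum(pr$sdev > max(pr$sdev, .Machine$double.eps) * 1e-8)
  if (pos == 0) return(matrix(0, nrow(x), 1))
  if (strict && n_pcs > pos)
    stop("n_pcs (", n_pcs, ") exceeds the rank of the matrix (", pos, ")")
  pr$x[, seq_len(min(n_pcs, pos)), drop = FALSE]
}
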