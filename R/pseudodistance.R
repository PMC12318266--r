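# Diffusion-map embedding, diffusion pseudotime, and its rescaled,
# lobule-oriented form: diffusion pseudodistance (DPD).

#' Diffusion-map embedding of normalized expression
#'
#' PCA to `n_pcs` components, a global-bandwidth Gaussian kernel in PC
#' space (bandwidth = median distance to the `knn`-th neighbor),
#' Coifman-Lafon density normalization with exponent `alpha`, and the
#' eigendecomposition of the resulting row-stochastic Markov matrix. The
#' trivial unit eigenpair is removed.
#'
#' @param norm Normalized genes x nuclei matrix.
#' @param n_pcs Principal components fed to the kernel (default 30; capped
#'   at the matrix rank).
#' @param n_evecs Diffusion components to keep (default 10).
#' @param knn Neighbor index for the median-distance bandwidth rule.
#' @param alpha Density-normalization exponent (1 recovers the Laplace-
#'   Beltrami limit, removing sampling-density effects).
#' @return A `diffusion_map` list: `evalues` (descending, in (-1, 1)),
#'   `evectors` (nuclei x `n_evecs`), `markov` transition matrix, and the
#'   bandwidth used.
#' @export
diffusion_map <- function(norm, n_pcs = 30, n_evecs = 10, knn = 15,
                          alpha = 1) {
  n <- ncol(norm)
  stopifnot(n_evecs >= 2, n > 2)
  pcs <- pca_scores(norm, min(n_pcs, n - 1), strict = FALSE)
  d <- as.matrix(stats::dist(pcs))
  k <- min(knn, n - 1)
  kth <- apply(d, 1, function(row) sort(row)[k + 1])
  sigma <- stats::median(kth)
  if (sigma == 0) sigma <- .Machine$double.eps
  w <- exp(-d^2 / (2 * sigma^2))
  off <- w; diag(off) <- 0
  if (any(rowSums(off) < 1e-12))
    stop("kernel graph is disconnected; increase the bandwidth (knn)")
  # density normalization: W <- W / (q_i q_j)^alpha, then row-normalize
  q <- rowSums(w)
  w <- w / (outer(q, q)^alpha)
  dd <- rowSums(w)
  # symmetric conjugate S = D^-1/2 W D^-1/2 shares eigenvalues with the
  # Markov matrix P = D^-1 W; eigenvectors map back via D^-1/2
  s <- w / sqrt(outer(dd, dd))
  s <- (s + t(s)) / 2
  eig <- eigen(s, symmetric = TRUE)
  phi <- eig$vectors / sqrt(dd)
  # drop the trivial (constant) eigenpair; deterministic sign convention
  keep <- 2:(min(n_evecs + 1, n))
  evec <- phi[, keep, drop = FALSE]
  for (j in seq_len(ncol(evec))) {
    i <- which.max(abs(evec[, j]))
    if (evec[i, j] < 0) evec[, j] <- -evec[, j]
  }
  structure(list(evalues = eig$values[keep],
                 evectors = evec,
                 markov = w / dd,
                 bandwidth = sigma,
                 nucleus = colnames(norm)),
            class = "diffusion_map")
}

#' Diffusion pseudotime from a root nucleus
#'
#' Euclidean distance from the root in the eigenvalue-rescaled diffusion
#' space, each component weighted by \eqn{\lambda / (1 - \lambda)}.
#'
#' @param dmap A [diffusion_map()] result.
#' @param root Root nucleus: an index or a nucleus ID.
#' @return Numeric pseudotime per nucleus; 0 at the root.
#' @export
diffusion_pseudotime <- function(dmap, root) {
  stopifnot(inherits(dmap, "diffusion_map"))
  if (is.character(root)) {
    root <- match(root, dmap$nucleus)
    if (is.na(root)) stop("root nucleus not found")
  }
  n <- nrow(dmap$evectors)
  if (root < 1 || root > n) stop("root index out of range")
  lam <- dmap$evalues
  if (any(lam >= 1 - 1e-12))
    stop("non-trivial eigenvalue at 1: kernel graph is disconnected")
  w <- lam / (1 - lam)
  psi <- sweep(dmap$evectors, 2, w, `*`)
  dpt <- sqrt(colSums((t(psi) - psi[root, ])^2))
  names(dpt) <- dmap$nucleus
  dpt
}

#' Rescale and orient pseudotime into diffusion pseudodistance
#'
#' Min-max rescales pseudotime to `[0, 1]` and orients it along the lobular
#' axis: if the rescaled values correlate positively (Spearman) with the
#' pericentral score, they are flipped so that 0 is the pericentral end and
#' 1 the periportal end.
#'
#' @param dpt Numeric pseudotime vector.
#' @param pc_scores Per-nucleus pericentral marker scores.
#' @return A `dpd` list: `dpd` (values in `[0, 1]`), `flipped`, and
#'   `orientation` (`"oriented"` or `"ambiguous"` when the score is
#'   constant).
#' @export
rescale_orient <- function(dpt, pc_scores) {
  rng <- range(dpt)
  if (!all(is.finite(rng)) || diff(rng) == 0)
    stop("pseudotime is constant; cannot rescale")
  dpd <- (dpt - rng[1]) / diff(rng)
  flipped <- FALSE
  orientation <- "oriented"
  if (stats::sd(pc_scores) == 0) {
    orientation <- "ambiguous"
  } else {
    rho <- stats::cor(dpd, pc_scores, method = "spearman")
    if (is.na(rho)) {
      orientation <- "ambiguous"
    } else if (rho > 0) {
      dpd <- 1 - dpd
      flipped <- TRUE
    }
  }
  structure(list(dpd = dpd, flipped = flipped, orientation = orientation),
            class = "dpd")
}

#' Full pseudodistance pipeline: embedding, root choice, DPT, DPD
#'
#' Convenience wrapper: diffusion map on the normalized matrix, root
#' selection in two passes, pseudotime from the root, then rescaling and
#' orientation against the pericentral score.
#'
#' Root selection is two-pass: anchor at the nucleus with the maximal
#' pericentral score, measure pseudotime from that anchor, and take as
#' root the farthest nucleus among the `root_pool` highest periportal
#' scorers (the periportal tip of the trajectory). Distance from a root
#' that is not at the trajectory's extreme folds back on itself for
#' nuclei beyond the root; picking the geometric tip avoids the fold,
#' and restricting the pool to strong periportal scorers keeps the choice
#' biologically anchored and insensitive to stray outliers.
#'
#' @param norm Normalized genes x nuclei matrix.
#' @param scores data.frame from [score_markers()].
#' @param root_pool Number of top periportal-score nuclei eligible as
#'   root (default 5% of nuclei, at least 5).
#' @inheritParams diffusion_map
#' @return A `dpd` object (see [rescale_orient()]) with the root index
#'   attached as `root`.
#' @export
compute_dpd <- function(norm, scores, n_pcs = 30, n_evecs = 10, knn = 15,
                        alpha = 1, root_pool = NULL) {
  dmap <- diffusion_map(norm, n_pcs = n_pcs, n_evecs = n_evecs, knn = knn,
                        alpha = alpha)
  n <- ncol(norm)
  if (is.null(root_pool)) root_pool <- max(5L, ceiling(0.05 * n))
  anchor <- which.max(scores$pericentral)
  pool <- order(scores$periportal, decreasing = TRUE)[seq_len(min(root_pool, n))]
  dpt0 <- diffusion_pseudotime(dmap, anchor)
  root <- pool[which.max(dpt0[pool])]
  dpt <- diffusion_pseudotime(dmap, root)
  out <- rescale_orient(dpt, scores$pericentral)
  out$root <- root
  out
}
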