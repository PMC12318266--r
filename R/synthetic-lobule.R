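# Synthetic zonated count matrices with known ground truth.

#' Configuration for the synthetic lobule count generator
#'
#' Defines a gene panel with four expression-profile classes along the
#' lobular axis \eqn{u \in [0,1]} (0 = pericentral, 1 = periportal), the
#' negative-binomial noise model, and the knockout perturbation applied to
#' the KO genotype.
#'
#' Expected expression for a monotone gene is a logistic ramp
#' \eqn{\mu(u) = lo + (hi - lo) / (1 + \exp(\pm s (u - 1/2)))} with
#' \eqn{hi / lo =} `gradient_fold`; mid-peaked genes are a Gaussian bump
#' centred at \eqn{u = 1/2}; flat genes are constant. Counts are drawn
#' negative-binomially around `mu * size_factor`, where per-nucleus size
#' factors are log-normal.
#'
#' @param n_nuclei_per_genotype Nuclei simulated for each of CON and KO.
#' @param n_pericentral,n_periportal,n_mid,n_flat Gene-class sizes
#'   (monotone decreasing in `u`, monotone increasing, mid-lobular bump,
#'   unzonated).
#' @param gradient_fold Ratio of maximal to minimal expected expression
#'   along `u` for zonated genes; must exceed 1.
#' @param base_mean Panel-wide expected count per nucleus at unit size
#'   factor (arithmetic mean of the profile endpoints for ramps).
#' @param nb_dispersion Negative-binomial dispersion \eqn{\alpha}
#'   (variance \eqn{\mu + \alpha \mu^2}); values near 0 approach Poisson.
#' @param library_size_logmean,library_size_logsd Parameters of the
#'   log-normal per-nucleus size factor.
#' @param ko_effect Named list mapping an effect in
#'   `c("flatten", "ablate", "expand")` to a character vector of gene IDs.
#'   `"flatten"` replaces the profile by its mean over `u` (zonation lost,
#'   bulk level preserved), `"ablate"` floors it near zero, `"expand"`
#'   raises it to its maximum everywhere. The default flattens the first
#'   half of each monotone class in the KO genotype, so a majority of
#'   zonated genes retain their gradients — the partial collapse seen in
#'   zonation-disrupting knockouts.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A `lobule_sim_config` list.
#' @export
lobule_sim_config <- function(n_nuclei_per_genotype = 1000,
                              n_pericentral = 40,
                              n_periportal = 40,
                              n_mid = 20,
                              n_flat = 100,
                              gradient_fold = 2,
                              base_mean = 20,
                              nb_dispersion = 0.25,
                              library_size_logmean = 0,
                              library_size_logsd = 0.3,
                              ko_effect = NULL,
                              seed = 1L) {
  stopifnot(n_nuclei_per_genotype >= 1,
            n_pericentral >= 0, n_periportal >= 0, n_mid >= 0, n_flat >= 0,
            gradient_fold > 1, base_mean > 0, nb_dispersion > 0,
            library_size_logsd >= 0)
  genes <- data.frame(
    gene = c(sprintf("PC%03d", seq_len2(n_pericentral)),
             sprintf("PP%03d", seq_len2(n_periportal)),
             sprintf("MID%03d", seq_len2(n_mid)),
             sprintf("FLAT%03d", seq_len2(n_flat))),
    class = rep(c("pericentral_monotone", "periportal_monotone",
                  "mid_peaked", "flat"),
                times = c(n_pericentral, n_periportal, n_mid, n_flat)),
    stringsAsFactors = FALSE
  )
  if (nrow(genes) == 0L)
    stop("gene panel is empty: all class counts are zero")
  if (is.null(ko_effect)) {
    first_half <- function(g) g[seq_len(floor(length(g) / 2))]
    pc <- genes$gene[genes$class == "pericentral_monotone"]
    pp <- genes$gene[genes$class == "periportal_monotone"]
    mono <- c(first_half(pc), first_half(pp))
    ko_effect <- if (length(mono)) list(flatten = mono) else list()
  }
  bad_eff <- setdiff(names(ko_effect), c("flatten", "ablate", "expand"))
  if (length(bad_eff))
    stop("unknown ko_effect kind(s): ", paste(bad_eff, collapse = ", "))
  missing <- setdiff(unlist(ko_effect, use.names = FALSE), genes$gene)
  if (length(missing))
    stop("ko_effect names genes absent from the panel: ",
         paste(utils::head(missing, 5), collapse = ", "))
  structure(list(n_nuclei_per_genotype = as.integer(n_nuclei_per_genotype),
                 genes = genes,
                 gradient_fold = gradient_fold,
                 base_mean = base_mean,
                 nb_dispersion = nb_dispersion,
                 library_size_logmean = library_size_logmean,
                 library_size_logsd = library_size_logsd,
                 ko_effect = ko_effect,
                 seed = as.integer(seed)),
            class = "lobule_sim_config")
}

# 0-length-safe seq_len for class counts
seq_len2 <- function(n) if (n <= 0) integer(0) else seq_len(n)

# Expected expression of one gene class at lobular coordinate u, before
# any knockout perturbation. Monotone ramps are logistic in u, rescaled so
# the endpoints mu(0), mu(1) equal exactly (hi, lo) for pericentral and
# (lo, hi) for periportal genes; steepness 4 keeps the gradient informative
# across the whole lobule rather than saturating at the poles.
profile_mean <- function(u, class, lo, hi, steep = 4) {
  ramp <- function(v) {                       # increasing, ramp(0)=0, ramp(1)=1
    raw <- 1 / (1 + exp(-steep * (v - 0.5)))
    a <- 1 / (1 + exp(steep / 2))
    (raw - a) / (1 - 2 * a)
  }
  switch(class,
    pericentral_monotone = hi - (hi - lo) * ramp(u),
    periportal_monotone  = lo + (hi - lo) * ramp(u),
    mid_peaked           = lo + (hi - lo) * exp(-(u - 0.5)^2 / (2 * 0.15^2)),
    flat                 = rep(lo, length(u)),
    stop("unknown gene class: ", class)
  )
}

# Apply a knockout effect to a vector of expected means evaluated on u.
# "flatten" uses the profile's mean over u in [0,1] (numeric integral),
# "ablate" floors at 1% of the profile minimum, "expand" uses the maximum.
apply_ko_effect <- function(mu, effect, class, lo, hi) {
  grid <- seq(0, 1, length.out = 201)
  prof <- profile_mean(grid, class, lo, hi)
  switch(effect,
    flatten = rep(mean(prof), length(mu)),
    ablate  = rep(0.01 * min(prof), length(mu)),
    expand  = rep(max(prof), length(mu)),
    stop("unknown ko effect: ", effect)
  )
}

#' Expected (noise-free) expression surface of a simulated lobule
#'
#' @param truth The `truth` element returned by [simulate_lobule()].
#' @return Genes-by-nuclei matrix of expected counts at unit size factor.
#' @export
expected_expression <- function(truth) {
  g <- truth$genes
  mu <- matrix(0, nrow(g), length(truth$u),
               dimnames = list(g$gene, truth$nucleus))
  for (i in seq_len(nrow(g))) {
    m <- profile_mean(truth$u, g$class[i], g$lo[i], g$hi[i])
    ko <- truth$genotype == "KO"
    if (!is.na(g$ko_effect[i]) && any(ko))
      m[ko] <- apply_ko_effect(m[ko], g$ko_effect[i], g$class[i],
                               g$lo[i], g$hi[i])
    mu[i, ] <- m
  }
  mu
}

#' Simulate a zonated gene-by-nucleus count matrix
#'
#' Draws a latent lobular coordinate \eqn{u \sim U[0,1]} per nucleus,
#' evaluates each gene's class profile at `u` (applying the configured
#' knockout effect in the KO genotype), and samples counts from a
#' negative binomial with per-nucleus log-normal size factors.
#'
#' @param config A [lobule_sim_config()].
#' @return List with `counts` (genes x nuclei [dgCMatrix][Matrix::dgCMatrix-class]),
#'   `genes` (gene annotation with `mito` flag, all `FALSE` here), `nuclei`
#'   (nucleus ID and genotype), and `truth` (per-nucleus `u`, genotype,
#'   per-gene class, profile endpoints `lo`/`hi` and applied `ko_effect`).
#' @export
simulate_lobule <- function(config) {
  stopifnot(inherits(config, "lobule_sim_config"))
  n_per <- config$n_nuclei_per_genotype
  genes <- config$genes
  if (nrow(genes) == 0L || n_per == 0L)
    stop("cannot simulate zero genes or zero nuclei")
  n <- 2L * n_per
  set.seed(config$seed)

  u <- stats::runif(n)
  genotype <- rep(c("CON", "KO"), each = n_per)
  nucleus <- sprintf("N%05d", seq_len(n))
  sf <- stats::rlnorm(n, config$library_size_logmean,
                      config$library_size_logsd)

  # profile endpoints: arithmetic mean of (lo, hi) equals base_mean,
  # hi / lo = gradient_fold; flat genes sit at base_mean
  fold <- config$gradient_fold
  lo <- ifelse(genes$class == "flat", config$base_mean,
               2 * config$base_mean / (1 + fold))
  hi <- ifelse(genes$class == "flat", config$base_mean, fold * lo)

  eff <- rep(NA_character_, nrow(genes))
  for (kind in names(config$ko_effect))
    eff[genes$gene %in% config$ko_effect[[kind]]] <- kind

  truth <- list(u = u, genotype = genotype, nucleus = nucleus,
                size_factor = sf,
                genes = data.frame(gene = genes$gene, class = genes$class,
                                   lo = lo, hi = hi, ko_effect = eff,
                                   stringsAsFactors = FALSE))
  mu <- expected_expression(truth)
  mu <- sweep(mu, 2, sf, `*`)
  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = size),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  list(counts = Matrix::Matrix(counts, sparse = TRUE),
       genes = data.frame(gene = genes$gene, class = genes$class,
                          mito = FALSE, stringsAsFactors = FALSE),
       nuclei = data.frame(nucleus = nucleus, genotype = genotype,
                           stringsAsFactors = FALSE),
       truth = truth)
}
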