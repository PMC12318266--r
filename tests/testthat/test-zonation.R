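# Binned profiles, the spline-ANOVA zonation test, classification,
# module clustering and hypergeometric overlap.

test_that("profile_bins collapses, bins boundaries, and tracks a linear
           expectation", {
  sim <- small_lobule(seed = 6, n = 400, ko_effect = list())
  norm <- normalize_log(sim$counts)
  u <- sim$truth$u
  # single-bin collapse equals the overall mean
  p1 <- profile_bins(norm, u, n_bins = 1)
  expect_equal(p1$means[, 1], rowMeans(as.matrix(norm)), tolerance = 1e-12)
  # a DPD of exactly 1 goes to the last bin
  m <- Matrix::Matrix(matrix(1:4, 2, 2,
                             dimnames = list(c("a", "b"), NULL)),
                      sparse = TRUE)
  p2 <- profile_bins(m, c(0.1, 1.0), n_bins = 5)
  expect_equal(p2$counts, c(1, 0, 0, 0, 1))
  expect_equal(as.numeric(p2$means["a", 5]), 3)
  # bin means of a monotone gene follow the expected profile within 3 SE
  p <- profile_bins(norm, u, n_bins = 20)
  g <- sim$truth$genes[sim$truth$genes$gene == "PP001", ]
  mids <- p$midpoints
  expected_mu <- hepzone:::profile_mean(mids, "periportal_monotone",
                                        g$lo, g$hi)
  # normalized scale: compare monotone trend, not raw counts
  expect_gt(cor(p$means["PP001", ], expected_mu), 0.9)
})

test_that("the zonation F-test flags gradients, not flat genes, with the
           strict 0.05 rule", {
  sim <- simulate_lobule(lobule_sim_config(
    n_nuclei_per_genotype = 500, n_pericentral = 10, n_periportal = 10,
    n_mid = 5, n_flat = 60, ko_effect = list(), seed = 12))
  norm <- normalize_log(sim$counts)
  con <- sim$truth$genotype == "CON"
  p <- profile_bins(norm[, con], sim$truth$u[con], n_bins = 80)
  res <- test_zonation(p)
  cls <- sim$genes$class[match(res$gene, sim$genes$gene)]
  expect_true(all(res$zonated[cls != "flat"]))
  expect_lt(mean(res$zonated[cls == "flat"]), 0.15)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # strictness: the flag is p strictly below alpha; at alpha it is off
  res_at <- test_zonation(p, alpha = min(res$p))
  expect_false(res_at$zonated[which.min(res$p)])
  expect_identical(res$zonated, res$p < 0.05)
})

test_that("a constant gene yields F = 0 and p = 1", {
  m <- Matrix::Matrix(rbind(const = rep(2, 200),
                            vari = rnorm(200, 5)), sparse = TRUE)
  p <- profile_bins(m, seq(0, 1, length.out = 200), n_bins = 20)
  res <- test_zonation(p)
  expect_equal(res$f[res$gene == "const"], 0)
  expect_equal(res$p[res$gene == "const"], 1)
  expect_false(res$zonated[res$gene == "const"])
  # too few occupied bins errors
  p2 <- profile_bins(m, rep(c(0.1, 0.9), 100), n_bins = 20)
  expect_error(test_zonation(p2), "non-empty bins")
})

test_that("classification partitions genes and conserves counts", {
  con <- data.frame(gene = c("a", "b", "c", "d"),
                    zonated = c(TRUE, TRUE, FALSE, FALSE))
  ko <- data.frame(gene = c("a", "b", "c", "d"),
                   zonated = c(TRUE, FALSE, TRUE, FALSE))
  cl <- classify_zonation(con, ko)
  expect_identical(cl$classification$category,
                   c("both", "con_only", "ko_only", "neither"))
  expect_identical(sum(cl$counts), 4L)
  # mismatched gene lists rejected
  expect_error(classify_zonation(con, ko[1:3, ]), "different gene lists")
  # all-neither case conserves the panel size
  none <- data.frame(gene = letters[1:5], zonated = FALSE)
  expect_identical(unname(classify_zonation(none, none)$counts["neither"]),
                   5L)
})

test_that("module clustering recovers planted archetypes and handles
           degenerate cuts", {
  set.seed(31)
  mids8 <- (1:8 - 0.5) / 8
  arche <- rbind(pc = 1 - mids8, pp = mids8,
                 mid = exp(-(mids8 - 0.5)^2 / 0.02),
                 ko_gain = mids8^2)
  arche_ko <- rbind(pc = rep(0.5, 8), pp = mids8,
                    mid = exp(-(mids8 - 0.5)^2 / 0.02),
                    ko_gain = rep(0.2, 8))
  genes <- sprintf("g%03d", 1:80)
  truth <- rep(1:4, each = 20)
  noise <- function() matrix(rnorm(80 * 8, 0, 0.03), 80, 8)
  pc_con <- list(means = arche[truth, ] + noise(), counts = rep(10, 8),
                 midpoints = mids8)
  pc_ko <- list(means = arche_ko[truth, ] + noise(), counts = rep(10, 8),
                midpoints = mids8)
  rownames(pc_con$means) <- rownames(pc_ko$means) <- genes
  mod <- cluster_modules(pc_con, pc_ko, genes, k = 4)
  expect_gte(ari_oracle(mod$modules$module, truth), 0.9)
  # k = 1: everything in one module
  mod1 <- cluster_modules(pc_con, pc_ko, genes, k = 1)
  expect_identical(unique(mod1$modules$module), "A")
  # duplicated gene rows co-cluster
  pc_con$means[2, ] <- pc_con$means[1, ]
  pc_ko$means[2, ] <- pc_ko$means[1, ]
  mod2 <- cluster_modules(pc_con, pc_ko, genes, k = 4)
  expect_identical(mod2$modules$module[1], mod2$modules$module[2])
  expect_error(cluster_modules(pc_con, pc_ko, genes[1:3], k = 4), "k exceeds")
})

test_that("hypergeometric overlap equals exhaustive enumeration and
           handles boundary cases", {
  universe <- paste0("u", 1:20)
  module <- universe[1:5]
  set <- universe[c(1, 2, 3, 10)]
  r <- hypergeom_overlap(module, set, universe)
  expect_identical(r$overlap, 3L)
  expect_equal(r$p, 496 / 15504, tolerance = 1e-10)
  expect_equal(r$p, hyper_tail_oracle(3, 20, 4, 5), tolerance = 1e-12)
  # sweep of small configurations against the oracle
  for (n_set in c(2, 6, 10)) for (n_mod in c(3, 7)) {
    set_i <- sample(universe, n_set)
    mod_i <- sample(universe, n_mod)
    ri <- hypergeom_overlap(mod_i, set_i, universe)
    expect_equal(ri$p, hyper_tail_oracle(ri$overlap, 20, n_set, n_mod),
                 tolerance = 1e-10)
  }
  # disjoint: overlap 0, p = 1
  d <- hypergeom_overlap(universe[1:3], universe[10:12], universe)
  expect_identical(d$overlap, 0L)
  expect_equal(d$p, 1)
  # module contained in set: minimal attainable tail value
  sub <- hypergeom_overlap(universe[1:3], universe[1:10], universe)
  expect_identical(sub$overlap, 3L)
  expect_equal(sub$p, hyper_tail_oracle(3, 20, 10, 3), tolerance = 1e-12)
  expect_error(hypergeom_overlap("a", "a", character(0)), "empty universe")
  expect_error(hypergeom_overlap("zz", set, universe), "subsets")
})

test_that("overlap_table adjusts across module-set pairs with BH", {
  universe <- paste0("u", 1:40)
  modules <- data.frame(gene = universe[1:12],
                        module = rep(c("A", "B"), each = 6))
  sets <- list(ind = universe[c(1:4, 20:25)], sup = universe[c(7:9, 30)])
  tab <- overlap_table(modules, sets, universe)
  expect_identical(nrow(tab), 4L)
  expect_equal(tab$p_adj, bh_oracle(tab$p), tolerance = 1e-12)
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))
})
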