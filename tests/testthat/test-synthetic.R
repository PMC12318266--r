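# Generators: reproducibility, moment structure, boundary behavior.

test_that("lobule generator is seed-reproducible and well-formed", {
  cfg <- lobule_sim_config(n_nuclei_per_genotype = 100, seed = 42)
  a <- simulate_lobule(cfg)
  b <- simulate_lobule(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth$u, b$truth$u)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$truth$u >= 0 & a$truth$u <= 1))
  # class labels partition the panel
  expect_identical(sort(table(a$genes$class))[["mid_peaked"]], 20L)
  expect_identical(nrow(a$genes), 200L)
  expect_identical(ncol(a$counts), 200L)
})

test_that("lobule generator rejects empty panels and bad configs", {
  expect_error(lobule_sim_config(n_pericentral = 0, n_periportal = 0,
                                 n_mid = 0, n_flat = 0),
               "empty")
  expect_error(lobule_sim_config(gradient_fold = 1))
  expect_error(lobule_sim_config(ko_effect = list(flatten = "NOPE")),
               "absent")
  expect_error(lobule_sim_config(ko_effect = list(boost = "PC001")),
               "unknown ko_effect")
})

test_that("noiseless expectations are monotone with rank correlation 1", {
  sim <- small_lobule(seed = 3, n = 50)
  mu <- expected_expression(sim$truth)
  con <- sim$truth$genotype == "CON"
  u <- sim$truth$u[con]
  expect_equal(cor(mu["PC001", con], u, method = "spearman"), -1)
  expect_equal(cor(mu["PP001", con], u, method = "spearman"), 1)
  # endpoint ratio equals gradient_fold exactly
  g <- sim$truth$genes[sim$truth$genes$gene == "PC001", ]
  expect_equal(g$hi / g$lo, 2)
})

test_that("counts match negative-binomial moment formulas", {
  cfg <- lobule_sim_config(n_nuclei_per_genotype = 1000, n_pericentral = 0,
                           n_periportal = 0, n_mid = 0, n_flat = 30,
                           library_size_logsd = 0, ko_effect = list(),
                           base_mean = 20, nb_dispersion = 0.25, seed = 9)
  sim <- simulate_lobule(cfg)
  x <- as.matrix(sim$counts)
  mu <- 20; alpha <- 0.25
  v <- mu + alpha * mu^2               # NB variance
  n <- ncol(x)
  se_mean <- sqrt(v / n)
  expect_true(all(abs(rowMeans(x) - mu) < 3 * se_mean))
  # variance of the sample variance for NB via 4th central moment bound
  vars <- apply(x, 1, var)
  expect_lt(abs(mean(vars) - v), 3 * sd(vars) / sqrt(nrow(x)))
})

test_that("near-zero dispersion with equal library sizes is near its
           expectation", {
  cfg <- lobule_sim_config(n_nuclei_per_genotype = 400, n_pericentral = 0,
                           n_periportal = 0, n_mid = 0, n_flat = 5,
                           base_mean = 50, nb_dispersion = 1e-6,
                           library_size_logsd = 0, ko_effect = list(),
                           seed = 11)
  sim <- simulate_lobule(cfg)
  # Poisson-limit tolerance: mean within 3 * sqrt(mu / n)
  expect_true(all(abs(rowMeans(as.matrix(sim$counts)) - 50) <
                    3 * sqrt(50 / 800)))
})

test_that("knockout effects reshape expected profiles as declared", {
  cfg <- lobule_sim_config(n_nuclei_per_genotype = 100,
                           ko_effect = list(flatten = "PC001",
                                            ablate = "PC002",
                                            expand = "PP001"),
                           seed = 2)
  sim <- simulate_lobule(cfg)
  mu <- expected_expression(sim$truth)
  ko <- sim$truth$genotype == "KO"
  expect_equal(sd(mu["PC001", ko]), 0)                # flattened
  expect_lt(max(mu["PC002", ko]), min(mu["PC002", !ko]))  # ablated
  pp1 <- sim$truth$genes[sim$truth$genes$gene == "PP001", ]
  expect_equal(unique(mu["PP001", ko]), pp1$hi)               # expanded
  # flatten preserves the bulk level
  expect_equal(mean(mu["PC001", ko]),
               mean(hepzone:::profile_mean(seq(0, 1, length.out = 201),
                                           "pericentral_monotone",
                                           sim$truth$genes$lo[1],
                                           sim$truth$genes$hi[1])))
})

test_that("smFISH generator is reproducible and respects geometry", {
  cfg <- smfish_sim_config(n_images = 2, seed = 8)
  a <- simulate_smfish(cfg)
  b <- simulate_smfish(cfg)
  expect_identical(a$spots, b$spots)
  expect_true(all(a$spots$x >= 0 & a$spots$x <= 200))
  expect_true(all(a$spots$y >= 0 & a$spots$y <= 200))
  # no spot inside either vein interior
  expect_false(any(hepzone:::in_polygon(a$spots$x, a$spots$y, a$cv)))
  expect_false(any(hepzone:::in_polygon(a$spots$x, a$spots$y, a$pv)))
})

test_that("smFISH generator rejects overlapping or out-of-image veins", {
  expect_error(smfish_sim_config(cv_center = c(100, 100),
                                 pv_center = c(110, 100)), "overlap")
  expect_error(smfish_sim_config(cv_center = c(5, 5), cv_radius = 20),
               "inside the image")
  expect_error(smfish_sim_config(lambda_intercept = 0.1,
                                 lambda_slope = -0.2), "non-negative")
})

test_that("total spot count matches the Poisson integral of lambda", {
  cfg <- smfish_sim_config(lambda_intercept = 0.01, lambda_slope = 0.02,
                           n_images = 30, seed = 21)
  f <- simulate_smfish(cfg)
  # oracle: numeric integral of lambda over tissue pixels
  px <- hepzone:::pixel_grid(200, 200)
  tissue <- !hepzone:::in_polygon(px$x, px$y, f$cv) &
    !hepzone:::in_polygon(px$x, px$y, f$pv)
  r <- hepzone:::relative_radius(px$x[tissue], px$y[tissue], f$cv, f$pv)
  expected_total <- sum(f$lambda(r))
  per_image <- as.numeric(table(factor(f$spots$image,
                                       levels = unique(f$spots$image))))
  se <- sqrt(expected_total / 30)
  expect_lt(abs(mean(per_image) - expected_total), 3 * se)
})

test_that("cohort generator obeys Hardy-Weinberg and the null model", {
  # boundary: q = 0 gives all dosage 0
  z <- simulate_cohort(cohort_sim_config(n_individuals = 500, q = 0,
                                         seed = 1))
  expect_true(all(z$cohort$dosage == 0))
  # q = 0.3: TT fraction near q^2 within 3 binomial SE
  big <- simulate_cohort(cohort_sim_config(n_individuals = 100000, q = 0.3,
                                           seed = 4))
  tt <- mean(big$cohort$dosage == 2)
  expect_lt(abs(tt - 0.09), 3 * sqrt(0.09 * 0.91 / 100000))
  # beta = 0: prevalence flat across genotypes
  null <- simulate_cohort(cohort_sim_config(n_individuals = 60000,
                                            disease_beta = 0, seed = 6))
  prev <- with(null$table, cases / n)
  p0 <- sum(null$table$cases) / sum(null$table$n)
  se <- sqrt(p0 * (1 - p0) / null$table$n)
  expect_true(all(abs(prev - p0) < 3 * se))
  # aggregation is consistent with the individual table
  expect_identical(sum(null$table$n), 60000L)
  expect_identical(sum(null$table$cases), sum(null$cohort$disease))
  # reproducibility
  again <- simulate_cohort(cohort_sim_config(n_individuals = 60000,
                                             disease_beta = 0, seed = 6))
  expect_identical(null$cohort, again$cohort)
})
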