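# Genotype-dosage association statistics: prevalences, crude allelic odds
# ratio, per-allele regressions, and a Bonferroni-thresholded biomarker
# scan.

check_genotype_table <- function(table) {
  stopifnot(all(c("dosage", "n", "cases") %in% names(table)))
  if (!setequal(table$dosage, 0:2))
    stop("genotype table must contain dosages 0, 1 and 2")
  if (any(table$cases > table$n)) stop("cases exceed n")
  table[order(table$dosage), , drop = FALSE]
}

#' Per-genotype case prevalence and chi-squared test
#'
#' @param table Aggregate genotype-by-case table: data.frame `dosage`
#'   (0/1/2), `n`, `cases`.
#' @return List: `prevalence` (data.frame with `percent`, full precision,
#'   and `percent_1dp` as conventionally reported) and `p` from the 2 x 3
#'   chi-squared test of independence.
#' @export
genotype_prevalence <- function(table) {
  table <- check_genotype_table(table)
  if (any(table$n == 0)) stop("zero total for a genotype")
  pct <- 100 * table$cases / table$n
  chi <- stats::chisq.test(rbind(table$cases, table$n - table$cases))
  list(prevalence = data.frame(dosage = table$dosage, n = table$n,
                               cases = table$cases, percent = pct,
                               percent_1dp = round(pct, 1)),
       p = unname(chi$p.value))
}

#' Crude per-allele odds ratio from an aggregate genotype table
#'
#' Collapses genotypes to allele counts (each individual contributes two
#' alleles, `dosage` of them the risk allele) and computes the 2 x 2 odds
#' ratio with a Woolf (log) 95% confidence interval. Zero cells get the
#' Haldane-Anscombe +0.5 correction.
#'
#' @param table data.frame `dosage`, `n`, `cases`.
#' @return List: `or`, `ci` (95%), `alleles` (the 2 x 2 table).
#' @export
allelic_or <- function(table) {
  table <- check_genotype_table(table)
  controls <- table$n - table$cases
  if (sum(table$cases) == 0 || sum(controls) == 0)
    stop("degenerate table: no cases or no controls")
  case_t <- sum(table$dosage * table$cases)
  case_c <- sum((2 - table$dosage) * table$cases)
  ctrl_t <- sum(table$dosage * controls)
  ctrl_c <- sum((2 - table$dosage) * controls)
  cells <- c(case_t = case_t, case_c = case_c,
             ctrl_t = ctrl_t, ctrl_c = ctrl_c)
  adj <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (adj["case_t"] * adj["ctrl_c"]) / (adj["case_c"] * adj["ctrl_t"])
  se <- sqrt(sum(1 / adj))
  list(or = unname(or),
       ci = unname(exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)),
       alleles = matrix(cells, 2, 2, byrow = TRUE,
                        dimnames = list(c("case", "control"),
                                        c("T", "C"))))
}

#' Per-allele regression of a phenotype on genotype dosage
#'
#' Individual-level data: logistic (binary phenotype) or linear
#' (continuous) regression of the phenotype on dosage plus any covariates,
#' with Wald inference on the dosage coefficient. An aggregate
#' genotype-by-case table is also accepted (grouped binomial logistic, no
#' covariates).
#'
#' @param data Individual-level data.frame with a `dosage` column, or an
#'   aggregate table (`dosage`, `n`, `cases`).
#' @param phenotype Column name of the outcome (ignored for aggregate
#'   tables).
#' @param covariates Character vector of covariate column names.
#' @return One-row data.frame: `phenotype`, `type` ("logistic"/"linear"),
#'   `estimate` (log-odds or mean shift per allele), `se`, `p`, and `or`
#'   (`NA` for linear fits).
#' @export
per_allele_regression <- function(data, phenotype = NULL,
                                  covariates = character(0)) {
  if (all(c("n", "cases") %in% names(data))) {
    tab <- check_genotype_table(data)
    fit <- stats::glm(cbind(cases, n - cases) ~ dosage, data = tab,
                      family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    type <- "logistic"
    phenotype <- if (is.null(phenotype)) "cases" else phenotype
  } else {
    stopifnot(!is.null(phenotype), phenotype %in% names(data))
    y <- data[[phenotype]]
    rhs <- paste(c("dosage", covariates), collapse = " + ")
    fml <- stats::as.formula(paste(phenotype, "~", rhs))
    binary <- all(y %in% c(0, 1))
    if (binary) {
      fit <- stats::glm(fml, data = data, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
      if (!fit$converged || any(abs(stats::coef(fit)) > 20))
        stop("logistic fit did not converge cleanly (possible separation)")
      type <- "logistic"
    } else {
      fit <- stats::lm(fml, data = data)
      type <- "linear"
    }
  }
  sm <- summary(fit)$coefficients["dosage", ]
  est <- unname(sm[1]); se <- unname(sm[2])
  p <- unname(sm[4])
  data.frame(phenotype = phenotype, type = type, estimate = est, se = se,
             p = p, or = if (type == "logistic") exp(est) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Phenome-style scan of many biomarkers against genotype dosage
#'
#' Runs [per_allele_regression()] for each biomarker, applies the
#' Bonferroni threshold `alpha / m` (m = number of biomarkers), and
#' returns results ranked by p-value.
#'
#' @param cohort Individual-level data.frame with `dosage`.
#' @param biomarkers Character vector of biomarker column names.
#' @param covariates Covariate column names passed to each regression.
#' @param alpha Family-wise error target (default 0.05).
#' @return List: `results` (data.frame ranked by `p`, with `significant`
#'   flag) and `threshold`.
#' @export
phewas_scan <- function(cohort, biomarkers, covariates = character(0),
                        alpha = 0.05) {
  m <- length(biomarkers)
  if (m == 0) stop("no biomarkers to scan")
  threshold <- alpha / m
  res <- do.call(rbind, lapply(biomarkers, function(b)
    per_allele_regression(cohort, b, covariates)))
  res$significant <- res$p < threshold
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  list(results = res, threshold = threshold)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the one-way ANOVA F-test from group sizes, means and
#' standard deviations, as needed for continuous rows of aggregate
#' genotype tables reported as mean (SD).
#'
#' @param n,mean,sd Numeric vectors, one entry per group.
#' @return List: `f`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd),
            all(n > 1), all(sd >= 0))
  k <- length(n); total <- sum(n)
  grand <- sum(n * mean) / total
  ss_between <- sum(n * (mean - grand)^2)
  ss_within <- sum((n - 1) * sd^2)
  df1 <- k - 1; df2 <- total - k
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
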