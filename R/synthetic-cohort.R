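# Synthetic Hardy-Weinberg cohorts with per-allele disease and biomarker
# effects, covariates included so adjusted regressions can be exercised.

#' Configuration for the synthetic cohort generator
#'
#' Genotype dosages (count of the risk allele, 0/1/2) are drawn under
#' Hardy-Weinberg equilibrium at allele frequency `q`. Disease status
#' follows a logistic model with a per-allele log-odds `disease_beta`;
#' continuous biomarkers are Gaussian with per-allele mean shifts. Age,
#' sex and ten ancestry principal components are simulated so that
#' covariate-adjusted regressions are well-posed; their default effects on
#' outcomes are zero.
#'
#' Defaults mirror a biobank-scale type 2 diabetes setting: risk-allele
#' frequency 0.29, baseline prevalence ~4.3% (intercept -3.1), per-allele
#' log-odds log(1.35), and glucose/glutamine-like biomarkers with
#' per-allele shifts +0.055 mmol/l and -2.137 umol/l.
#'
#' @param n_individuals Cohort size.
#' @param q Risk-allele frequency in `[0, 1]`.
#' @param disease_intercept,disease_beta Logistic intercept and per-allele
#'   log-odds for the binary outcome.
#' @param biomarkers data.frame with columns `name`, `shift` (mean change
#'   per allele) and `sd` (residual standard deviation, > 0).
#' @param covariate_effects Optional named numeric vector of effects of
#'   `age`, `sex`, `PC1`..`PC10` on the disease liability (logit scale).
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_individuals = 10000,
                              q = 0.29,
                              disease_intercept = -3.1,
                              disease_beta = log(1.35),
                              biomarkers = data.frame(
                                name = c("glucose", "glutamine"),
                                shift = c(0.055, -2.137),
                                sd = c(1.1, 79),
                                stringsAsFactors = FALSE),
                              covariate_effects = NULL,
                              seed = 1L) {
  stopifnot(n_individuals >= 1, q >= 0, q <= 1)
  if (nrow(biomarkers) > 0 && any(biomarkers$sd <= 0))
    stop("biomarker residual SDs must be positive")
  structure(list(n_individuals = as.integer(n_individuals), q = q,
                 disease_intercept = disease_intercept,
                 disease_beta = disease_beta,
                 biomarkers = biomarkers,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a Hardy-Weinberg cohort and its aggregate genotype table
#'
#' @param config A [cohort_sim_config()].
#' @return List with `cohort` (one row per individual: `dosage`, `disease`,
#'   one column per biomarker, `age`, `sex`, `PC1`..`PC10`) and `table`
#'   (aggregate genotype-by-case counts: `dosage`, `n`, `cases`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  dosage <- stats::rbinom(n, 2, config$q)

  age <- stats::rnorm(n, 56.6, 8)
  sex <- stats::rbinom(n, 1, 0.46)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))

  eta <- config$disease_intercept + config$disease_beta * dosage
  ce <- config$covariate_effects
  if (!is.null(ce)) {
    covs <- cbind(age = age, sex = sex, pcs)
    for (nm in names(ce)) eta <- eta + ce[[nm]] * covs[, nm]
  }
  disease <- stats::rbinom(n, 1, stats::plogis(eta))

  cohort <- data.frame(dosage = dosage, disease = disease)
  for (i in seq_len(nrow(config$biomarkers))) {
    b <- config$biomarkers[i, ]
    cohort[[b$name]] <- stats::rnorm(n, b$shift * dosage, b$sd)
  }
  cohort <- cbind(cohort, age = age, sex = sex, as.data.frame(pcs))

  tab <- data.frame(dosage = 0:2,
                    n = as.integer(tabulate(dosage + 1L, 3L)),
                    cases = as.integer(vapply(0:2, function(d)
                      sum(disease[dosage == d]), numeric(1))))
  list(cohort = cohort, table = tab)
}
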