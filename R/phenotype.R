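#' Simulate clinical covariates
#'
#' Emits the eight clinical records carried by the association model:
#' maternal age and BMI as Gaussians, and six binary indicators (fetal sex,
#' a single-gene disease in either parent, a chromosome abnormality in
#' either parent, multiple pregnancy, preeclampsia, gestational diabetes)
#' as Bernoulli draws with typical clinical prevalences.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return An `n x 8` numeric matrix with named columns.
#' @export
simulate_covariates <- function(n, seed = 1) {
  set.seed(seed)
  x <- cbind(
    maternal_age = rnorm(n, 32, 4),
    maternal_bmi = rnorm(n, 22, 3),
    fetal_sex = rbinom(n, 1, 0.5),
    parent_single_gene_disease = rbinom(n, 1, 0.15),
    parent_chrom_abnormality = rbinom(n, 1, 0.10),
    multiple_pregnancy = rbinom(n, 1, 0.05),
    preeclampsia = rbinom(n, 1, 0.05),
    gestational_diabetes = rbinom(n, 1, 0.10))
  x
}

#' Construct a quantitative-phenotype model
#'
#' Describes how the simulated trait is assembled: additive causal SNP
#' effects on the z-scale, linear clinical-covariate effects, additive
#' batch shifts (a planted confounder), and Gaussian residual noise.
#'
#' @param causal_sites Integer site indices of causal SNPs.
#' @param betas Per-causal-site additive effect per alt allele.
#' @param covariate_effects Numeric vector of length 8 (one per clinical
#'   covariate column).
#' @param batch_effects List with named numeric vectors `wga` and/or
#'   `platform` giving additive shifts per batch level; defaults to no shift.
#' @param noise_sd Residual standard deviation (> 0).
#' @return An object of class `phenotype_model`.
#' @export
phenotype_model <- function(causal_sites = integer(0), betas = numeric(0),
                            covariate_effects = rep(0, 8),
                            batch_effects = list(), noise_sd = 1) {
  if (length(causal_sites) != length(betas))
    stop("causal_sites and betas must have equal length")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(covariate_effects) != 8)
    stop("covariate_effects must have length 8")
  structure(list(causal_sites = as.integer(causal_sites), betas = betas,
                 covariate_effects = covariate_effects,
                 batch_effects = batch_effects, noise_sd = noise_sd),
            class = "phenotype_model")
}

#' Residual SD that brings the raw trait to (approximately) unit variance
#'
#' Computes `sqrt(1 - var(genetic) - var(covariates) - var(batch))` from the
#' realized cohort, floored at `min_sd`, so a planted effect size can be
#' interpreted on the z-scale of the final phenotype.
#'
#' @param cohort A `cohort_truth`.
#' @param model A `phenotype_model` (its `noise_sd` is ignored).
#' @param covariates Covariate matrix as from [simulate_covariates()].
#' @param min_sd Lower bound for the returned SD.
#' @return A single positive number.
#' @export
residual_sd_for_unit_variance <- function(cohort, model, covariates,
                                          min_sd = 0.2) {
  sig <- .phenotype_signal(cohort, model, covariates)
  sqrt(max(1 - var(sig), min_sd^2))
}

.phenotype_signal <- function(cohort, model, covariates) {
  n <- cohort$n_samples
  sig <- numeric(n)
  if (length(model$causal_sites)) {
    if (any(model$causal_sites < 1 | model$causal_sites > ncol(cohort$genotypes)))
      stop("causal site index out of range")
    g <- cohort$genotypes[, model$causal_sites, drop = FALSE]
    sig <- sig + drop(g %*% model$betas)
  }
  sig <- sig + drop(covariates %*% model$covariate_effects)
  for (fac in intersect(names(model$batch_effects), c("wga", "platform"))) {
    sh <- model$batch_effects[[fac]]
    sig <- sig + unname(sh[cohort$batch[[fac]]])
  }
  sig
}

#' Simulate a z-scored quantitative phenotype
#'
#' `y_raw = sum_j beta_j g_j + covariate terms + batch shift + N(0, noise_sd)`,
#' then standardized to mean 0 and SD 1 (the trait enters association as a
#' z-scored quantitative phenotype).
#'
#' @param cohort A `cohort_truth`.
#' @param model A `phenotype_model`.
#' @param covariates `n x 8` covariate matrix; row count must match the
#'   cohort.
#' @param seed Integer seed.
#' @return Numeric phenotype vector of length `n`, mean 0 and SD 1.
#' @export
simulate_phenotype <- function(cohort, model, covariates, seed = 1) {
  stopifnot(inherits(cohort, "cohort_truth"), inherits(model, "phenotype_model"))
  if (nrow(covariates) != cohort$n_samples)
    stop("covariate row count must equal n_samples")
  set.seed(seed)
  y <- .phenotype_signal(cohort, model, covariates) +
    rnorm(cohort$n_samples, 0, model$noise_sd)
  standardize_phenotype(y)
}
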