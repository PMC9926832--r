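#' Bonferroni-corrected per-test significance threshold
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise error level in `(0, 1)` (default 0.05).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(1107198)  # ~4.52e-8 genome-wide level
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / n_tests
}

#' Construct an accuracy model from known coefficients
#'
#' The expected-genotype-accuracy surface
#' `acc = coef_coverage * c + coef_samplesize * s + intercept`, valid on the
#' stated domain.
#'
#' @param coef_coverage Coefficient of sequencing coverage `c`.
#' @param coef_samplesize Coefficient of sample size `s`.
#' @param intercept Intercept.
#' @param r2 Optional coefficient of determination of the source fit.
#' @param c_min,s_min Domain bounds (accuracy is still computed outside the
#'   domain, with a warning).
#' @return An object of class `accuracy_model`.
#' @export
accuracy_model <- function(coef_coverage, coef_samplesize, intercept,
                           r2 = NA_real_, c_min = 0.01, s_min = 4000) {
  structure(list(coef_coverage = coef_coverage,
                 coef_samplesize = coef_samplesize,
                 intercept = intercept, r2 = r2,
                 c_min = c_min, s_min = s_min),
            class = "accuracy_model")
}

#' @export
print.accuracy_model <- function(x, ...) {
  cat(sprintf("accuracy_model: acc = %.4g*c + %.4g*s + %.4g (c >= %g, s >= %g)",
              x$coef_coverage, x$coef_samplesize, x$intercept,
              x$c_min, x$s_min))
  if (is.finite(x$r2)) cat(sprintf(", r2 = %.3f", x$r2))
  cat("\n")
  invisible(x)
}

#' Benchmark imputation accuracy over a coverage x sample-size grid
#'
#' For each combination `(c, s)`: draw a cohort of `s` samples sequenced at
#' the cohort's own coverage, add `n_truth` held-out truth samples whose
#' pileups are simulated at coverage `c`, run population SNV calling on the
#' cohort reads only (the truth samples contribute no information to the
#' population call), fit the imputation HMM on everyone, and score the
#' truth samples against their known genotypes. Each truth sample is
#' evaluated on the intersection of PASS-called sites and its own variant
#' sites (sites where it truly carries a non-reference allele), pooled over
#' truth samples.
#'
#' @param panel A [generate_panel()] result.
#' @param coverages Truth-sample coverages to test (each > 0).
#' @param sizes Cohort sizes to test (each >= 2).
#' @param params [hmm_params()] for the imputation fit.
#' @param cohort_coverage Mean coverage of the cohort samples (default
#'   0.04, the ultra-low regime).
#' @param n_truth Number of truth samples per grid point (default 8;
#'   averaging over several truth samples narrows the accuracy estimate the
#'   way a large evaluated-site intersection does).
#' @param sibs_per_family Sibling structure of the cohort.
#' @param error_profile Per-batch error probabilities.
#' @param call_alpha Population-calling significance level.
#' @param seed Integer seed; one deterministic sub-seed per grid point.
#' @return Data.frame (`benchmark_grid`): `coverage`, `sample_size`,
#'   `n_sites_called`, `n_evaluated`, `genotype_accuracy`,
#'   `allele_accuracy`.
#' @export
run_grid <- function(panel, coverages, sizes, params,
                     cohort_coverage = 0.04, n_truth = 8,
                     sibs_per_family = 2,
                     error_profile = default_error_profile(),
                     call_alpha = 1e-6, seed = 1) {
  stopifnot(all(coverages > 0), all(sizes >= 2))
  out <- list()
  pt <- 0L
  for (s in sizes) for (cv in coverages) {
    pt <- pt + 1L
    sub_seed <- (seed * 1000L + pt) %% .Machine$integer.max
    gp <- .grid_point(panel, cv, s, params, cohort_coverage, n_truth,
                      sibs_per_family, error_profile, call_alpha, sub_seed)
    out[[pt]] <- data.frame(coverage = cv, sample_size = s,
                            n_sites_called = gp$n_sites_called,
                            n_evaluated = gp$n_evaluated,
                            genotype_accuracy = gp$genotype_accuracy,
                            allele_accuracy = gp$allele_accuracy)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

.grid_point <- function(panel, coverage, size, params, cohort_coverage,
                        n_truth, sibs_per_family, error_profile, call_alpha,
                        seed, keep_posteriors = FALSE) {
  cohort <- sample_cohort(panel, size, sibs_per_family, seed = seed)
  truth <- sample_cohort(panel, n_truth, 1, seed = seed + 1L)
  pu_cohort <- simulate_pileups(cohort, panel, cohort_coverage,
                                error_profile, seed = seed + 2L)
  pu_truth <- simulate_pileups(truth, panel, coverage,
                               error_profile, seed = seed + 3L)

  calls <- call_population(pu_cohort, panel$sites, alpha = call_alpha,
                           fix_alt = TRUE)
  pass <- calls$site_index[calls$status == "PASS"]
  if (length(pass) < 2) stop("population calling yielded < 2 PASS sites")
  sites <- panel$sites[pass, , drop = FALSE]
  f_hat <- calls$f_hat[calls$status == "PASS"]

  pu_all <- bind_pileups(pu_cohort, pu_truth)
  pu_sub <- .subset_pileup(pu_all, pass)
  post <- impute_region(pu_sub, sites, params, init_af = f_hat)

  truth_rows <- size + seq_len(n_truth)
  truth_g <- truth$genotypes[, pass, drop = FALSE]
  hc <- hard_calls(post)[truth_rows, , drop = FALSE]
  eval_mask <- truth_g > 0           # per-sample variant sites
  n_eval <- sum(eval_mask)
  if (n_eval == 0) stop("no truth variant site intersects the callset")
  gacc <- mean((hc == truth_g)[eval_mask])
  aacc <- mean(((hc > 0) == (truth_g > 0))[eval_mask])
  res <- list(n_sites_called = length(pass), n_evaluated = n_eval,
              genotype_accuracy = gacc, allele_accuracy = aacc)
  if (keep_posteriors) {
    res$post <- post
    res$pass <- pass
    res$truth_rows <- truth_rows
    res$truth_g <- truth_g
    res$f_hat <- f_hat
  }
  res
}

#' Fit the linear accuracy surface to benchmark results
#'
#' Ordinary least squares of genotype accuracy on coverage and sample size,
#' restricted to in-domain grid points (`coverage >= c_min` and
#' `sample_size >= s_min`).
#'
#' @param grid A [run_grid()] result (or any data.frame with `coverage`,
#'   `sample_size`, `genotype_accuracy`).
#' @param c_min,s_min Domain bounds (defaults 0.01 and 4000).
#' @return An [accuracy_model()] with the fitted `r2`.
#' @export
fit_accuracy_model <- function(grid, c_min = 0.01, s_min = 4000) {
  d <- grid[grid$coverage >= c_min & grid$sample_size >= s_min, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 in-domain grid points")
  fit <- lm(genotype_accuracy ~ coverage + sample_size, data = d)
  if (any(!is.finite(coef(fit))))
    stop("collinear benchmark design; cannot fit the accuracy surface")
  cf <- coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # silence exact-fit notice
  accuracy_model(cf[["coverage"]], cf[["sample_size"]], cf[["(Intercept)"]],
                 r2 = r2, c_min = c_min, s_min = s_min)
}

#' Predict expected genotype accuracy
#'
#' Linear prediction from an [accuracy_model()], clamped to `[0, 1]`.
#' Out-of-domain inputs are still computed but raise a warning.
#'
#' @param fit An `accuracy_model`.
#' @param c Sequencing coverage.
#' @param s Sample size.
#' @return Expected genotype accuracy.
#' @export
predict_accuracy <- function(fit, c, s) {
  stopifnot(inherits(fit, "accuracy_model"))
  if (any(c < fit$c_min) || any(s < fit$s_min))
    warning("prediction outside the fitted domain (c >= ", fit$c_min,
            ", s >= ", fit$s_min, ")")
  pmin(pmax(fit$coef_coverage * c + fit$coef_samplesize * s + fit$intercept,
            0), 1)
}
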