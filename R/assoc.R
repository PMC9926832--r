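#' Z-score a quantitative phenotype
#'
#' Centers to mean 0 and scales to SD 1 (denominator `N - 1`);
#' order-preserving.
#'
#' @param y Numeric vector with at least two distinct values.
#' @return The standardized vector.
#' @export
standardize_phenotype <- function(y) {
  if (length(unique(y)) < 2) stop("phenotype is constant")
  as.numeric((y - mean(y)) / sd(y))
}

#' Principal components of a dosage matrix
#'
#' Restricts to sites with `maf >= maf_min`, centers each site by
#' `2 * theta_hat` and scales by `sqrt(2 * theta_hat * (1 - theta_hat))`,
#' and returns the sample scores of the top right-singular directions,
#' ordered by variance and sign-fixed so that each component's
#' largest-magnitude site loading is positive. Used to absorb batch
#' structure (WGA kit, sequencing platform) as association covariates.
#'
#' @param dosage `N x M` dosage matrix.
#' @param n_pcs Number of components (default 8).
#' @param maf_min Minor-allele-frequency restriction (default 0.05).
#' @return `N x n_pcs` matrix of PC scores.
#' @export
compute_pcs <- function(dosage, n_pcs = 8, maf_min = 0.05) {
  n <- nrow(dosage)
  if (n < n_pcs + 1) stop("need at least n_pcs + 1 samples")
  af <- colMeans(dosage) / 2
  keep <- pmin(af, 1 - af) >= maf_min
  if (!any(keep)) stop("no site passes the MAF restriction")
  af <- af[keep]
  z <- sweep(dosage[, keep, drop = FALSE], 2, 2 * af)
  z <- sweep(z, 2, sqrt(2 * af * (1 - af)), "/")
  sv <- svd(z, nu = n_pcs, nv = n_pcs)
  if (sv$d[1] <= 1e-12) stop("degenerate input: dosage matrix has no variance")
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  sweep(scores, 2, flip, "*")
}

#' Build the association covariate matrix
#'
#' Intercept, top principal components, and clinical covariates, with a
#' full-column-rank check.
#'
#' @param pcs `N x n_pcs` PC score matrix (may be `NULL`).
#' @param clinical `N x C` clinical covariate matrix (may be `NULL`).
#' @return Numeric matrix with leading intercept column.
#' @export
covariate_matrix <- function(pcs = NULL, clinical = NULL) {
  n <- if (!is.null(pcs)) nrow(pcs) else nrow(clinical)
  x <- cbind(intercept = rep(1, n), pcs, clinical)
  if (qr(x)$rank < ncol(x)) stop("covariate matrix is rank-deficient")
  x
}

#' Score-test scan of a quantitative trait on genotype dosages
#'
#' Fits the null linear model `y = X beta` once; per site, with residuals
#' `r`, `sigma2 = r'r / (N - C)` and dosage vector `e`:
#' `U = e'r / sigma2`, `V = (e'e - e'X (X'X)^-1 X'e) / sigma2`,
#' `chi2 = U^2 / V` referred to chi-square(1). A site is tested only when at
#' least `min_high` samples have a high-credibility genotype
#' (max posterior `>= high_cutoff`); dosage vectors inside the covariate
#' span (`V` ~ 0) are flagged untested.
#'
#' @param dosage `N x M` dosage matrix (posterior mean genotypes).
#' @param y Z-scored phenotype.
#' @param X Covariate matrix from [covariate_matrix()].
#' @param post Optional `genotype_posteriors` for the high-credibility
#'   count; when absent every dosage is treated as high-credibility.
#' @param min_high Minimum number of high-credibility genotypes (default 15).
#' @param high_cutoff Posterior cutoff defining high credibility
#'   (default 0.9).
#' @return Data.frame (`score_scan`): `site`, `score_u`, `score_v`, `chi2`,
#'   `p_value`, `n_high`, `tested`.
#' @export
score_test <- function(dosage, y, X, post = NULL, min_high = 15,
                       high_cutoff = 0.9) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  stopifnot(length(y) == n, nrow(X) == n)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank-deficient")
  r <- qr.resid(qx, y)
  sigma2 <- sum(r^2) / (n - ncol(X))

  q <- qr.Q(qx)
  qe <- crossprod(q, dosage)                     # C x M
  v_raw <- colSums(dosage^2) - colSums(qe^2)     # e'Pe
  u <- drop(crossprod(dosage, r)) / sigma2
  v <- v_raw / sigma2
  ok_v <- v > 1e-8 * n
  chi2 <- ifelse(ok_v, u^2 / v, NA_real_)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)

  n_high <- if (is.null(post)) rep(n, ncol(dosage)) else {
    pmax_mat <- pmax(post$p0, post$p1, post$p2)
    colSums(pmax_mat >= high_cutoff)
  }
  data.frame(site = seq_len(ncol(dosage)),
             score_u = u, score_v = v, chi2 = chi2, p_value = p,
             n_high = n_high,
             tested = ok_v & n_high >= min_high)
}

#' Per-allele effect size by linear regression
#'
#' Ordinary least squares of the phenotype on the covariates plus the
#' site's dosage; the effect is the dosage coefficient with its standard
#' error.
#'
#' @param e Dosage vector at one site.
#' @param y Z-scored phenotype.
#' @param X Covariate matrix.
#' @return List with `beta` and `se`.
#' @export
effect_size <- function(e, y, X) {
  d <- cbind(X, dosage = e)
  if (qr(d)$rank < ncol(d)) stop("singular design (dosage in covariate span)")
  fit <- lm.fit(d, y)
  sigma2 <- sum(fit$residuals^2) / (length(y) - ncol(d))
  xtx_inv <- chol2inv(chol(crossprod(d)))
  list(beta = unname(fit$coefficients[ncol(d)]),
       se = sqrt(sigma2 * xtx_inv[ncol(d), ncol(d)]))
}

#' Genomic-control summary of a chi-square scan
#'
#' `lambda_gc = median(chi2) / qchisq(0.5, 1)` plus the mean statistic.
#'
#' @param chi2 Vector of chi-square(1) statistics (non-finite entries are
#'   dropped).
#' @return List (`gc_report`): `lambda_gc`, `mean_chi2`, `n`.
#' @export
genomic_control <- function(chi2) {
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0) stop("no finite statistics")
  list(lambda_gc = median(chi2) / qchisq(0.5, df = 1),
       mean_chi2 = mean(chi2), n = length(chi2))
}

#' Expected-vs-observed quantiles for a QQ plot
#'
#' @param p Vector of p-values.
#' @return Data.frame with `expected` and `observed` `-log10(p)` columns,
#'   sorted for direct plotting.
#' @export
qq_data <- function(p) {
  p <- sort(p[is.finite(p)])
  data.frame(expected = -log10(ppoints(length(p))), observed = -log10(p))
}
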