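#' Exact conditional test of Hardy-Weinberg equilibrium
#'
#' Conditions on the observed allele counts and sums, over all heterozygote
#' counts with the same parity and the same allele totals, the exact
#' probabilities that are no larger than the probability of the observed
#' configuration. Probabilities are evaluated in log space from
#' `P(n_het = h) = n! / (n_AA! n_Aa! n_aa!) * 2^h * nA! na! / (2n)!`
#' (normalized over the support).
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (total >= 1).
#' @return The exact p-value in `(0, 1]`; 1 for a monomorphic site.
#' @export
#' @examples
#' hwe_exact_test(5, 10, 5)
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("counts must be >= 0")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype is required")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0) return(1)

  h <- seq(n_rare %% 2, n_rare, by = 2)  # possible het counts
  hom_rare <- (n_rare - h) / 2
  hom_common <- n - h - hom_rare
  logp <- lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
    lgamma(hom_common + 1) + h * log(2) +
    lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, h)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Hard-call genotypes from posteriors
#'
#' Argmax over the posterior triple; at a tie the lower genotype is chosen.
#'
#' @param post A `genotype_posteriors`.
#' @return Integer `N x M` matrix over 0/1/2.
#' @export
hard_calls <- function(post) {
  g <- matrix(0L, nrow(post$p0), ncol(post$p0))
  g[post$p1 > post$p0 & post$p1 >= post$p2] <- 1L
  g[post$p2 > post$p0 & post$p2 > post$p1] <- 2L
  g
}

#' Per-site quality records
#'
#' For every site: the IMPUTE2-style INFO score, the exact
#' Hardy-Weinberg p-value computed on argmax hard calls, the minor-allele
#' frequency from mean dosage (`maf = min(theta_hat, 1 - theta_hat)`), and
#' a known-variant membership flag (a stand-in for dbSNP membership).
#'
#' @param post A `genotype_posteriors`.
#' @param known_flag Logical vector (recycled) marking known variants.
#' @return Data.frame (`site_qc`): `site`, `chrom`, `pos`, `est_af`, `maf`,
#'   `info_score`, `hwe_p`, `known_flag`.
#' @export
site_qc <- function(post, known_flag = TRUE) {
  stopifnot(inherits(post, "genotype_posteriors"))
  m <- ncol(post$p0)
  g <- hard_calls(post)
  hwe <- vapply(seq_len(m), function(j) {
    tab <- tabulate(g[, j] + 1L, nbins = 3L)
    hwe_exact_test(tab[1], tab[2], tab[3])
  }, numeric(1))
  af <- post$site_info$est_af
  data.frame(site = seq_len(m),
             chrom = post$site_info$chrom, pos = post$site_info$pos,
             est_af = af, maf = pmin(af, 1 - af),
             info_score = post$site_info$info, hwe_p = hwe,
             known_flag = rep_len(known_flag, m))
}

#' Apply site filters
#'
#' Keeps sites with `info_score >= info_min`, `hwe_p > hwe_min`,
#' `maf >= maf_min`, and (optionally) `known_flag`. The operation is
#' idempotent and monotone in every threshold.
#'
#' @param records A [site_qc()] data.frame.
#' @param info_min INFO score threshold (default 0.4).
#' @param hwe_min Hardy-Weinberg p-value threshold (default 1e-6, strict
#'   inequality).
#' @param maf_min Minor-allele-frequency threshold (default 0.01).
#' @param require_known Require the known-variant flag.
#' @return The surviving subset of `records`.
#' @export
apply_filters <- function(records, info_min = 0.4, hwe_min = 1e-6,
                          maf_min = 0.01, require_known = FALSE) {
  keep <- records$info_score >= info_min &
    records$hwe_p > hwe_min &
    records$maf >= maf_min &
    (!require_known | records$known_flag)
  records[keep, , drop = FALSE]
}

#' Genotype and allele accuracy against truth
#'
#' `genotype_accuracy` is the fraction of evaluated (sample, site) pairs
#' where the argmax hard call equals the true genotype;
#' `allele_accuracy` relaxes zygosity and only requires agreement on the
#' presence of a non-reference allele. Both use the same denominator, so
#' `allele_accuracy >= genotype_accuracy`.
#'
#' @param post A `genotype_posteriors` (or a hard-call matrix).
#' @param truth Integer matrix of true genotypes, same shape.
#' @param eval_sites Site indices to evaluate (default all).
#' @param eval_samples Sample indices to evaluate (default all).
#' @return List (`accuracy_report`): `n_evaluated`, `genotype_accuracy`,
#'   `allele_accuracy`.
#' @export
accuracy_vs_truth <- function(post, truth, eval_sites = NULL,
                              eval_samples = NULL) {
  g <- if (inherits(post, "genotype_posteriors")) hard_calls(post) else post
  if (is.null(eval_sites)) eval_sites <- seq_len(ncol(g))
  if (is.null(eval_samples)) eval_samples <- seq_len(nrow(g))
  if (length(eval_sites) == 0) stop("empty evaluation site set")
  g <- g[eval_samples, eval_sites, drop = FALSE]
  tr <- truth[eval_samples, eval_sites, drop = FALSE]
  structure(list(
    n_evaluated = length(g),
    genotype_accuracy = mean(g == tr),
    allele_accuracy = mean((g > 0) == (tr > 0))
  ), class = "accuracy_report")
}
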