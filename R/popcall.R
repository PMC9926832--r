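#' Maximum-likelihood allele-frequency estimate from pooled reads
#'
#' Maximizes the pooled-read two-allele mixture likelihood
#' `L(f) = prod_r [ f P(b_r|alt) + (1-f) P(b_r|ref) ]` over `f` in `[0,1]`,
#' with `P(b|a) = 1 - e_r` when the read base matches allele `a` and
#' `e_r / 3` otherwise. The concave log-likelihood is maximized by
#' golden-section search (tolerance 1e-6) and the interior optimum is
#' compared against both boundaries, so monomorphic pileups return exactly
#' `f = 0` or `f = 1`.
#'
#' @param bases Character vector of observed read bases.
#' @param error_prob Per-read substitution error probabilities in `(0, 0.75]`.
#' @param ref_base,alt_base The site's reference and alternate base.
#' @return An object of class `af_estimate`: list with `f_hat`,
#'   `loglik_fhat`, `loglik_null` (log-likelihood at `f = 0`), `n_reads`.
#' @export
#' @examples
#' estimate_af(c("A", "A", "C"), rep(0.01, 3), "A", "C")$f_hat
estimate_af <- function(bases, error_prob, ref_base, alt_base) {
  if (length(bases) != length(error_prob))
    stop("bases and error_prob must have equal length")
  if (any(error_prob <= 0 | error_prob > 0.75))
    stop("error_prob must lie in (0, 0.75]")
  if (ref_base == alt_base) stop("ref and alt base must differ")

  if (length(bases) == 0L) {
    return(structure(list(f_hat = 0, loglik_fhat = 0, loglik_null = 0,
                          n_reads = 0L), class = "af_estimate"))
  }
  palt <- ifelse(bases == alt_base, 1 - error_prob, error_prob / 3)
  pref <- ifelse(bases == ref_base, 1 - error_prob, error_prob / 3)
  ll <- function(f) sum(log(f * palt + (1 - f) * pref))

  fg <- .golden_max(ll, 0, 1, tol = 1e-6)
  cand <- c(0, fg, 1)
  lls <- vapply(cand, ll, numeric(1))
  best <- which.max(lls)
  structure(list(f_hat = cand[best], loglik_fhat = lls[best],
                 loglik_null = lls[1], n_reads = length(bases)),
            class = "af_estimate")
}

# golden-section maximization of a unimodal function on [lo, hi]
.golden_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Likelihood-ratio SNV call at one site
#'
#' Tests `f = 0` against the maximum-likelihood allele frequency with
#' `Lambda = 2 (loglik_fhat - loglik_null)`, referred to a chi-square
#' distribution with one degree of freedom (conservative at the `f = 0`
#' boundary relative to the half-half mixture).
#'
#' @param est An [estimate_af()] result.
#' @param chrom,pos,ref_base,alt_base Site metadata (1-based position).
#' @param alpha Calling significance level (default 1e-6).
#' @param multiallelic Flag from [determine_alt()]; a multi-allelic site is
#'   reported with status `MULTIALLELIC`.
#' @return A one-row data.frame (`site_call`): `chrom`, `pos`, `ref`, `alt`,
#'   `f_hat`, `lrt_stat`, `p_value`, `status`, `n_reads`.
#' @export
lrt_call <- function(est, chrom, pos, ref_base, alt_base, alpha = 1e-6,
                     multiallelic = FALSE) {
  stopifnot(inherits(est, "af_estimate"))
  lam <- max(0, 2 * (est$loglik_fhat - est$loglik_null))
  p <- pchisq(lam, df = 1, lower.tail = FALSE)
  status <- if (multiallelic) "MULTIALLELIC"
            else if (p <= alpha) "PASS" else "NOT_SIGNIFICANT"
  data.frame(chrom = chrom, pos = pos, ref = ref_base, alt = alt_base,
             f_hat = est$f_hat, lrt_stat = lam, p_value = p, status = status,
             n_reads = est$n_reads, stringsAsFactors = FALSE)
}

#' Determine the alternate allele from pooled reads
#'
#' Each non-reference base is scored under its own single-allele
#' substitution model; the base attaining the highest maximized likelihood
#' is the candidate alternate allele (ties broken lexicographically
#' A < C < G < T). The site is flagged multi-allelic when a second
#' non-reference base also passes the per-allele likelihood-ratio test at
#' the calling level.
#'
#' @inheritParams estimate_af
#' @param alpha Per-allele LRT level used for the multi-allelic flag.
#' @return List with `alt_base`, `is_multiallelic`, and `est` (the
#'   `af_estimate` for the chosen alternate).
#' @export
determine_alt <- function(bases, error_prob, ref_base, alpha = 1e-6) {
  if (length(bases) == 0L) stop("reads must be non-empty")
  cand <- setdiff(c("A", "C", "G", "T"), ref_base)  # lexicographic order
  ests <- lapply(cand, function(b) estimate_af(bases, error_prob, ref_base, b))
  ll <- vapply(ests, function(e) e$loglik_fhat, numeric(1))
  lam <- vapply(ests, function(e) max(0, 2 * (e$loglik_fhat - e$loglik_null)),
                numeric(1))
  pval <- pchisq(lam, df = 1, lower.tail = FALSE)
  best <- which.max(ll)  # first maximum = lexicographic tie-break
  list(alt_base = cand[best],
       is_multiallelic = sum(pval <= alpha) >= 2,
       est = ests[[best]])
}

#' Population SNV calling over a pileup
#'
#' Pools all reads per site, determines the alternate allele, estimates the
#' population allele frequency by maximum likelihood, and applies the
#' likelihood-ratio test. Sites with no reads are not called.
#'
#' @param pileup A `read_pileup`.
#' @param sites Site table (`chrom`, `pos`, `ref`, and optionally `alt`).
#' @param alpha Calling significance level.
#' @param regions Optional exclusion regions (see [read_bed()]); overlapping
#'   calls get status `REGION_FILTERED`.
#' @param fix_alt If `TRUE`, the alternate allele is taken from `sites$alt`
#'   instead of being re-determined from the reads (default `FALSE`).
#' @return A `site_call` data.frame with one row per covered site, plus a
#'   `site_index` column mapping back into `sites`.
#' @export
call_population <- function(pileup, sites, alpha = 1e-6, regions = NULL,
                            fix_alt = FALSE) {
  stopifnot(inherits(pileup, "read_pileup"))
  idx <- split(seq_len(nrow(pileup)), pileup$site)
  out <- vector("list", length(idx))
  site_ids <- as.integer(names(idx))
  for (i in seq_along(idx)) {
    s <- site_ids[i]
    rows <- idx[[i]]
    bases <- pileup$base[rows]
    e <- pileup$error_prob[rows]
    ref <- sites$ref[s]
    if (fix_alt && !is.null(sites$alt)) {
      alt <- sites$alt[s]
      est <- estimate_af(bases, e, ref, alt)
      multi <- FALSE
    } else {
      da <- determine_alt(bases, e, ref, alpha = alpha)
      alt <- da$alt_base
      est <- da$est
      multi <- da$is_multiallelic
    }
    out[[i]] <- lrt_call(est, sites$chrom[s], sites$pos[s], ref, alt,
                         alpha = alpha, multiallelic = multi)
  }
  calls <- do.call(rbind, out)
  calls$site_index <- site_ids
  row.names(calls) <- NULL
  if (!is.null(regions)) calls <- apply_region_filters(calls, regions)
  calls
}

#' Flag calls inside exclusion regions
#'
#' Any call whose 1-based position falls inside a half-open 0-based interval
#' (`start <= pos - 1 < end`) has its status replaced by `REGION_FILTERED`;
#' all other calls and the input order are unchanged.
#'
#' @param calls A `site_call` data.frame.
#' @param regions Exclusion regions: data.frame `chrom`, `start`, `end`
#'   (0-based half-open), as returned by [read_bed()].
#' @return The calls with updated `status`.
#' @export
apply_region_filters <- function(calls, regions) {
  if (nrow(regions) > 0 && any(regions$end <= regions$start))
    stop("malformed interval: end <= start")
  hit <- in_regions(calls$chrom, calls$pos, regions)
  calls$status[hit] <- "REGION_FILTERED"
  calls
}
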