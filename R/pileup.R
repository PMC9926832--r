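#' Convert Phred quality to substitution error probability
#'
#' `e = 10^(-Q/10)`, floored at 1e-4 and capped at 0.75 so that error
#' probabilities stay in the domain of the pooled-read likelihood.
#'
#' @param q Numeric vector of Phred qualities.
#' @return Error probabilities in `(0, 0.75]`.
#' @export
phred_to_error <- function(q) pmin(pmax(10^(-q / 10), 1e-4), 0.75)

#' Default per-batch sequencing error profile
#'
#' One substitution error probability per WGA-kit x platform combination.
#' Platform dominates the default rates (semiconductor platforms are set an
#' order of magnitude noisier than sequencing-by-synthesis), which plants a
#' realistic batch confounder in the simulated pileups.
#'
#' @param rates Named numeric vector of per-platform error probabilities.
#' @return Named vector keyed `"<wga>:<platform>"`.
#' @export
default_error_profile <- function(rates = c(BGISeq500 = 0.002, MiSeq = 0.001,
                                            IonProton = 0.010, IonTorrent = 0.012)) {
  lv <- batch_levels()
  if (!all(lv$platform %in% names(rates)))
    stop("rates must name every platform")
  keys <- as.vector(outer(lv$wga, lv$platform, paste, sep = ":"))
  e <- rates[sub("^.*:", "", keys)]
  names(e) <- keys
  if (any(e <= 0 | e > 0.75)) stop("error probabilities must lie in (0, 0.75]")
  e
}

#' Simulate ultra-low-coverage read pileups for a cohort
#'
#' Per sample and site the read count is Poisson(`coverage`); each read
#' copies one of the sample's two true alleles uniformly at random and is
#' then substituted to one of the three other bases (uniformly) with the
#' batch-specific error probability.
#'
#' @param cohort A [sample_cohort()] result.
#' @param panel The panel the cohort was drawn from (supplies ref/alt bases).
#' @param coverage Mean read depth per site (>= 0).
#' @param error_profile Named vector keyed `"<wga>:<platform>"` with error
#'   probabilities in `(0, 0.75]`; see [default_error_profile()].
#' @param seed Integer seed.
#'
#' @return An object of class `read_pileup`: data.frame with columns
#'   `sample`, `site` (1-based indices), `base`, `error_prob`, plus
#'   attributes `n_samples` and `n_sites`.
#' @export
simulate_pileups <- function(cohort, panel, coverage,
                             error_profile = default_error_profile(),
                             seed = 1) {
  stopifnot(inherits(cohort, "cohort_truth"), inherits(panel, "haplotype_panel"))
  if (coverage < 0) stop("coverage must be >= 0")
  if (any(error_profile <= 0 | error_profile > 0.75))
    stop("error probabilities must lie in (0, 0.75]")
  set.seed(seed)

  n <- cohort$n_samples
  m <- nrow(panel$sites)
  key <- paste(cohort$batch$wga, cohort$batch$platform, sep = ":")
  if (!all(key %in% names(error_profile)))
    stop("error_profile is missing batch key(s): ",
         paste(unique(key[!key %in% names(error_profile)]), collapse = ", "))
  e_sample <- unname(error_profile[key])

  counts <- rpois(n * m, coverage)
  nz <- which(counts > 0L)
  if (length(nz) == 0L) {
    pu <- data.frame(sample = integer(0), site = integer(0),
                     base = character(0), error_prob = numeric(0))
  } else {
    # row-major layout: index = (sample - 1) * m + site
    smp <- rep.int((nz - 1L) %/% m + 1L, counts[nz])
    site <- rep.int((nz - 1L) %% m + 1L, counts[nz])
    r <- length(smp)

    g1 <- panel$alleles[cbind(cohort$hap_pairs[smp, 1], site)]
    g2 <- panel$alleles[cbind(cohort$hap_pairs[smp, 2], site)]
    allele <- ifelse(runif(r) < 0.5, g1, g2)
    true_base <- ifelse(allele == 1, panel$sites$alt[site], panel$sites$ref[site])

    e <- e_sample[smp]
    err <- runif(r) < e
    obs <- true_base
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      # substitute to one of the three non-true bases, uniformly
      shift <- sample.int(3, sum(err), replace = TRUE)
      idx <- match(true_base[err], bases)
      obs[err] <- bases[((idx - 1L + shift) %% 4L) + 1L]
    }
    pu <- data.frame(sample = smp, site = site, base = obs, error_prob = e,
                     stringsAsFactors = FALSE)
    pu <- pu[order(pu$sample, pu$site), , drop = FALSE]
    row.names(pu) <- NULL
  }
  structure(pu, n_samples = n, n_sites = m,
            class = c("read_pileup", "data.frame"))
}

#' Combine pileups from several cohorts into one
#'
#' Sample indices of later pileups are shifted so the result indexes samples
#' consecutively. Used by the benchmark harness to append truth samples to a
#' cohort pileup.
#'
#' @param ... `read_pileup` objects over the same site set.
#' @return A `read_pileup` over the union of samples.
#' @export
bind_pileups <- function(...) {
  ps <- list(...)
  stopifnot(length(ps) > 0, all(vapply(ps, inherits, TRUE, "read_pileup")))
  m <- attr(ps[[1]], "n_sites")
  if (!all(vapply(ps, attr, 0L, "n_sites") == m))
    stop("pileups must share a site set")
  offset <- 0L
  out <- vector("list", length(ps))
  for (i in seq_along(ps)) {
    d <- as.data.frame(ps[[i]])
    d$sample <- d$sample + offset
    out[[i]] <- d
    offset <- offset + attr(ps[[i]], "n_samples")
  }
  d <- do.call(rbind, out)
  d <- d[order(d$sample, d$site), , drop = FALSE]
  row.names(d) <- NULL
  structure(d, n_samples = offset, n_sites = m,
            class = c("read_pileup", "data.frame"))
}

# Per-read emission probabilities against a site's ref/alt pair:
# P(b | allele) = 1 - e when b matches the allele's base, e/3 otherwise.
# Bases matching neither ref nor alt get e/3 under both and carry no
# frequency information.
.read_likelihoods <- function(pileup, sites) {
  ref <- sites$ref[pileup$site]
  alt <- sites$alt[pileup$site]
  e <- pileup$error_prob
  list(palt = ifelse(pileup$base == alt, 1 - e, e / 3),
       pref = ifelse(pileup$base == ref, 1 - e, e / 3))
}

#' Write / read a pileup as TSV
#'
#' Plain-text interchange format with columns `sample_id`, `chrom`, `pos`
#' (1-based), `base`, `error_prob`.
#'
#' @param pileup A `read_pileup`.
#' @param sites Site table with `chrom` and `pos` (as in a panel).
#' @param path Output path.
#' @return `write_pileup_tsv` returns `path` invisibly; `read_pileup_tsv`
#'   returns a `read_pileup`.
#' @export
write_pileup_tsv <- function(pileup, sites, path) {
  d <- data.frame(sample_id = pileup$sample,
                  chrom = sites$chrom[pileup$site],
                  pos = sites$pos[pileup$site],
                  base = pileup$base,
                  error_prob = pileup$error_prob)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @param n_samples Number of samples the pileup indexes (samples with no
#'   reads are legal and must still be counted).
#' @export
read_pileup_tsv <- function(path, sites, n_samples) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  site <- match(paste(d$chrom, d$pos), paste(sites$chrom, sites$pos))
  if (anyNA(site)) stop("pileup refers to positions absent from the site table")
  if (any(d$error_prob <= 0 | d$error_prob > 0.75))
    stop("error probabilities must lie in (0, 0.75]")
  pu <- data.frame(sample = d$sample_id, site = site, base = d$base,
                   error_prob = d$error_prob, stringsAsFactors = FALSE)
  pu <- pu[order(pu$sample, pu$site), , drop = FALSE]
  row.names(pu) <- NULL
  structure(pu, n_samples = as.integer(n_samples), n_sites = nrow(sites),
            class = c("read_pileup", "data.frame"))
}
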