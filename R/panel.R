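#' Generate a haplotype panel with tunable linkage disequilibrium
#'
#' Builds a panel of binary haplotypes by a founder-mosaic copying process:
#' a small set of founder haplotypes is drawn site-wise from an allele
#' frequency spectrum, and each panel haplotype is a mosaic of the founders
#' with ancestry switches occurring at a per-bp rate of
#' `recomb_rate * n_meioses`. This gives LD that decays with physical
#' distance (length scale `1 / (recomb_rate * n_meioses)` bp) together with
#' exact ground truth, without simulating a full coalescent.
#'
#' @param n_hap Number of haplotypes in the panel (>= 2).
#' @param n_sites Number of polymorphic sites (>= 1).
#' @param region_length Length of the simulated region in bp.
#' @param recomb_rate Per-bp, per-meiosis recombination probability.
#' @param n_meioses Effective number of meioses since founding; the mosaic
#'   switch rate per bp is `recomb_rate * n_meioses`.
#' @param n_founders Number of founder haplotypes the mosaics copy from.
#' @param af_spectrum Function of one argument `n` returning `n` founder
#'   alt-allele probabilities in `[0, 1]`. The default is skewed toward low
#'   frequencies (`Beta(0.8, 2.4)` truncated to `[0.02, 0.98]`), so that the
#'   alternate allele is usually the minor allele, as in a real site
#'   frequency spectrum.
#' @param chrom Chromosome label for the generated sites.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `n_hap`, `sites` (data.frame `chrom`, `pos`, `ref`, `alt`),
#'   `alleles` (`n_hap x n_sites` 0/1 matrix), `recomb_rate`, `n_meioses`,
#'   `founder_af`.
#' @export
#' @examples
#' p <- generate_panel(20, 50, region_length = 1e6, seed = 1)
#' dim(p$alleles)
generate_panel <- function(n_hap, n_sites, region_length = 5e6,
                           recomb_rate = 1e-8, n_meioses = 100,
                           n_founders = 16,
                           af_spectrum = function(n)
                             pmin(pmax(rbeta(n, 0.8, 2.4), 0.02), 0.98),
                           chrom = "1", seed = 1) {
  if (n_hap < 2 || n_sites < 1 || region_length < n_sites)
    stop("non-positive or inconsistent panel dimensions")
  if (recomb_rate < 0) stop("recomb_rate must be >= 0")
  n_founders <- max(1L, as.integer(n_founders))
  set.seed(seed)

  pos <- sort(sample.int(region_length, n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  p <- pmin(pmax(af_spectrum(n_sites), 0), 1)
  founders <- matrix(rbinom(n_founders * n_sites, 1, rep(p, each = n_founders)),
                     nrow = n_founders)

  # per-gap switch probability of the mosaic process
  gap <- diff(pos)
  p_switch <- 1 - exp(-recomb_rate * n_meioses * gap)

  alleles <- matrix(0L, nrow = n_hap, ncol = n_sites)
  for (h in seq_len(n_hap)) {
    f <- integer(n_sites)
    f[1] <- sample.int(n_founders, 1)
    if (n_sites > 1) {
      sw <- runif(n_sites - 1) < p_switch
      for (m in 2:n_sites)
        f[m] <- if (sw[m - 1]) sample.int(n_founders, 1) else f[m - 1]
    }
    alleles[h, ] <- founders[cbind(f, seq_len(n_sites))]
  }

  structure(list(
    n_hap = as.integer(n_hap),
    sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE, row.names = NULL),
    alleles = alleles,
    recomb_rate = recomb_rate,
    n_meioses = n_meioses,
    founder_af = p
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d sites (%s:%d-%d)\n",
              x$n_hap, nrow(x$sites), x$sites$chrom[1],
              min(x$sites$pos), max(x$sites$pos)))
  invisible(x)
}

#' Batch factor levels used by the cohort generator
#'
#' Three whole-genome-amplification kits crossed with four sequencing
#' platforms, mirroring typical preimplantation-genetic-testing batch
#' structure.
#' @return A list with character vectors `wga` and `platform`.
#' @export
batch_levels <- function() {
  list(wga = c("MDA", "dopPCR", "PicoPlex"),
       platform = c("BGISeq500", "MiSeq", "IonProton", "IonTorrent"))
}

#' Sample a sibling-structured diploid cohort from a haplotype panel
#'
#' Samples are grouped into families of `sibs_per_family` siblings; each
#' family draws two maternal and two paternal haplotypes from the panel and
#' every sibling inherits one haplotype from each parental pair, so siblings
#' share parental haplotypes (the within-family genotype concordance exceeds
#' the between-family concordance). Each sample carries a batch label
#' (WGA kit x sequencing platform).
#'
#' @param panel A [generate_panel()] result.
#' @param n_samples Cohort size (>= 1). The last family may be smaller when
#'   `n_samples` is not a multiple of `sibs_per_family`.
#' @param sibs_per_family Number of siblings per family (>= 1).
#' @param batch_probs Optional list with numeric vectors `wga` (length 3)
#'   and `platform` (length 4) of assignment probabilities; defaults to
#'   uniform mixing.
#' @param seed Integer seed.
#'
#' @return An object of class `cohort_truth`: list with `n_samples`,
#'   `hap_pairs` (`n x 2` matrix of panel haplotype indices), `genotypes`
#'   (`n x n_sites` matrix over 0/1/2), `family_id`, `batch` (data.frame
#'   `wga`, `platform`), `true_af`.
#' @export
sample_cohort <- function(panel, n_samples, sibs_per_family = 1,
                          batch_probs = NULL, seed = 1) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_samples < 1 || sibs_per_family < 1)
    stop("n_samples and sibs_per_family must be >= 1")
  set.seed(seed)

  lv <- batch_levels()
  if (is.null(batch_probs))
    batch_probs <- list(wga = rep(1 / 3, 3), platform = rep(1 / 4, 4))

  n_fam <- ceiling(n_samples / sibs_per_family)
  fam_sizes <- rep(sibs_per_family, n_fam)
  fam_sizes[n_fam] <- n_samples - sibs_per_family * (n_fam - 1)

  replace <- panel$n_hap < 4
  hap_pairs <- matrix(0L, nrow = n_samples, ncol = 2)
  family_id <- integer(n_samples)
  i <- 1L
  for (f in seq_len(n_fam)) {
    par <- sample.int(panel$n_hap, 4, replace = replace)
    for (s in seq_len(fam_sizes[f])) {
      hap_pairs[i, ] <- c(par[sample.int(2, 1)], par[2 + sample.int(2, 1)])
      family_id[i] <- f
      i <- i + 1L
    }
  }

  genotypes <- panel$alleles[hap_pairs[, 1], , drop = FALSE] +
    panel$alleles[hap_pairs[, 2], , drop = FALSE]
  storage.mode(genotypes) <- "integer"

  batch <- data.frame(
    wga = sample(lv$wga, n_samples, replace = TRUE, prob = batch_probs$wga),
    platform = sample(lv$platform, n_samples, replace = TRUE,
                      prob = batch_probs$platform),
    stringsAsFactors = FALSE)

  structure(list(
    n_samples = as.integer(n_samples),
    hap_pairs = hap_pairs,
    genotypes = genotypes,
    family_id = family_id,
    batch = batch,
    true_af = colMeans(genotypes) / 2
  ), class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("cohort_truth: %d samples x %d sites, %d families\n",
              x$n_samples, ncol(x$genotypes), max(x$family_id)))
  invisible(x)
}
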