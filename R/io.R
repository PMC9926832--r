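#' Write population SNV calls as VCF 4.2
#'
#' One record per call; INFO carries `AF` (the ML allele-frequency
#' estimate), `LRT` (the likelihood-ratio statistic) and `LRTP` (its
#' p-value); the FILTER column carries the call status (`PASS`,
#' `NOT_SIGNIFICANT`, `MULTIALLELIC`, `REGION_FILTERED`).
#'
#' @param calls A `site_call` data.frame from [call_population()].
#' @param path Output path.
#' @param pass_only Write only PASS records (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, pass_only = FALSE) {
  if (pass_only) calls <- calls[calls$status == "PASS", , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ulcgwas population SNV calling (1-based positions)",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"ML alt allele frequency\">",
    "##INFO=<ID=LRT,Number=1,Type=Float,Description=\"Likelihood ratio statistic\">",
    "##INFO=<ID=LRTP,Number=1,Type=Float,Description=\"LRT p-value (chi-square 1 df)\">",
    "##FILTER=<ID=NOT_SIGNIFICANT,Description=\"LRT above calling alpha\">",
    "##FILTER=<ID=MULTIALLELIC,Description=\"Second alternate allele passes LRT\">",
    "##FILTER=<ID=REGION_FILTERED,Description=\"Inside an exclusion region\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- if (nrow(calls) == 0) character(0) else
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tAF=%.6g;LRT=%.6g;LRTP=%.6g",
            calls$chrom, calls$pos, calls$ref, calls$alt, calls$status,
            calls$f_hat, calls$lrt_stat, calls$p_value)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write imputed genotype posteriors as VCF 4.2
#'
#' Per-sample FORMAT fields `GT` (argmax hard call), `GP` (posterior
#' triple, 4 decimals) and `DS` (dosage, 4 decimals); INFO fields `EAF`
#' (estimated allele frequency from dosages) and `INFO` (IMPUTE2-style
#' score). Posterior triples that do not sum to 1 within `1e-3` are
#' rejected.
#'
#' @param post A `genotype_posteriors`.
#' @param sites Site table supplying `ref` and `alt`.
#' @param path Output path.
#' @param sample_ids Optional sample names (default `S1..SN`).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(post, sites, path, sample_ids = NULL) {
  stopifnot(inherits(post, "genotype_posteriors"))
  n <- nrow(post$p0); m <- ncol(post$p0)
  sums <- post$p0 + post$p1 + post$p2
  if (any(abs(sums - 1) > 1e-3))
    stop("genotype posterior triples must sum to 1 within 1e-3")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ulcgwas genotype imputation (1-based positions)",
    "##INFO=<ID=EAF,Number=1,Type=Float,Description=\"Estimated alt allele frequency\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"IMPUTE2-style INFO score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Argmax genotype\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  gt <- c("0/0", "0/1", "1/1")[hard_calls(post) + 1L]
  dim(gt) <- c(n, m)
  fld <- matrix(sprintf("%s:%.4f,%.4f,%.4f:%.4f", gt,
                        post$p0, post$p1, post$p2, post$dosage),
                nrow = n)
  rec <- vapply(seq_len(m), function(j) {
    paste(c(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tEAF=%.6g;INFO=%.6g\tGT:GP:DS",
                    sites$chrom[j], sites$pos[j], sites$ref[j], sites$alt[j],
                    post$site_info$est_af[j], post$site_info$info[j]),
            fld[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read an imputed-genotype VCF back into posteriors
#'
#' Parses a VCF written by [write_genotype_vcf()] (via `vcfR`) and rebuilds
#' the posterior matrices, dosages and site table.
#'
#' @param path VCF path (plain or bgzipped).
#' @return List with `sites` (chrom, pos, ref, alt), `post`
#'   (a `genotype_posteriors`), and `sample_ids`.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  m <- nrow(sites)
  if (m == 0) {
    empty <- matrix(0, 0, 0)
    return(list(sites = sites,
                post = .as_genotype_posteriors(empty, empty, empty, sites),
                sample_ids = character(0)))
  }
  gp <- vcfR::extract.gt(v, element = "GP")   # M x N character
  n <- ncol(gp)
  parts <- strsplit(as.vector(gp), ",", fixed = TRUE)
  pm <- matrix(as.numeric(unlist(parts)), nrow = 3)  # 3 x (M*N)
  p0 <- matrix(pm[1, ], nrow = m)
  p1 <- matrix(pm[2, ], nrow = m)
  p2 <- matrix(pm[3, ], nrow = m)
  # vcfR is site x sample; posteriors are sample x site
  list(sites = sites,
       post = .as_genotype_posteriors(t(p0), t(p1), t(p2), sites),
       sample_ids = colnames(gp))
}

#' Read exclusion regions from BED
#'
#' BED intervals are 0-based half-open; overlapping or adjacent intervals
#' are merged and the result is sorted. An interval with `end <= start` is
#' a format error.
#'
#' @param path BED path (3+ columns).
#' @return Data.frame (`exclusion_regions`): `chrom`, `start`, `end`
#'   (0-based half-open), sorted and disjoint.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1)) stop("malformed BED interval")
  gr <- GenomicRanges::reduce(gr)
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # back to 0-based
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# merge possibly-overlapping 0-based half-open intervals per chromosome
.merge_intervals <- function(regions) {
  do.call(rbind, lapply(split(regions, regions$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start; e <- d$end
    keep_s <- s[1]; keep_e <- e[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (s[i] <= keep_e[length(keep_e)]) {
        keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[i])
      } else {
        keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
      }
    }
    data.frame(chrom = d$chrom[1], start = keep_s, end = keep_e,
               stringsAsFactors = FALSE)
  }))
}

#' Test 1-based positions for membership in exclusion regions
#'
#' A 1-based position `pos` is inside the 0-based half-open interval
#' `[start, end)` iff `start <= pos - 1 < end`.
#'
#' @param chrom,pos Vectors of chromosome labels and 1-based positions.
#' @param regions Data.frame `chrom`, `start`, `end` (0-based half-open).
#' @return Logical vector.
#' @export
in_regions <- function(chrom, pos, regions) {
  hit <- logical(length(pos))
  if (nrow(regions) == 0) return(hit)
  regions <- .merge_intervals(regions)
  for (cr in unique(regions$chrom)) {
    d <- regions[regions$chrom == cr, , drop = FALSE]
    sel <- which(chrom == cr)
    if (length(sel) == 0) next
    p0 <- pos[sel] - 1L
    idx <- findInterval(p0, d$start)
    hit[sel] <- idx >= 1 & p0 < d$end[pmax(idx, 1)]
  }
  hit
}

#' Write a site QC table as TSV
#'
#' Columns: `chrom`, `pos` (1-based), `ref`, `alt`, `EAF`, `MAF`, `INFO`,
#' `HWE_P`, `KNOWN`, `PASS`.
#'
#' @param qc A [site_qc()] data.frame.
#' @param sites Site table supplying `ref`/`alt`.
#' @param pass Logical vector marking filter survivors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_tsv <- function(qc, sites, pass, path) {
  d <- data.frame(chrom = qc$chrom, pos = qc$pos,
                  ref = sites$ref, alt = sites$alt,
                  EAF = qc$est_af, MAF = qc$maf, INFO = qc$info_score,
                  HWE_P = qc$hwe_p, KNOWN = qc$known_flag, PASS = pass)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association summary statistics as TSV
#'
#' Columns: `CHR`, `POS`, `ID`, `REF`, `ALT`, `EAF`, `INFO`, `N_HIGH`,
#' `CHI2`, `P`, `BETA`, `SE`, `TESTED`.
#'
#' @param scan A [score_test()] data.frame.
#' @param sites Site table aligned with the scan.
#' @param qc Matching [site_qc()] rows (for `EAF`/`INFO`).
#' @param effects Optional data.frame with `site`, `beta`, `se`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats_tsv <- function(scan, sites, qc, effects = NULL, path) {
  beta <- se <- rep(NA_real_, nrow(scan))
  if (!is.null(effects) && nrow(effects) > 0) {
    i <- match(effects$site, scan$site)
    beta[i] <- effects$beta; se[i] <- effects$se
  }
  d <- data.frame(CHR = sites$chrom, POS = sites$pos,
                  ID = paste0(sites$chrom, ":", sites$pos),
                  REF = sites$ref, ALT = sites$alt,
                  EAF = qc$est_af, INFO = qc$info_score,
                  N_HIGH = scan$n_high, CHI2 = scan$chi2, P = scan$p_value,
                  BETA = beta, SE = se, TESTED = scan$tested)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write risk loci as TSV
#'
#' Columns: `locus_id`, `chrom`, `start`, `end`, `lead_id`, `lead_p`,
#' `n_ind`, `n_cand`.
#'
#' @param loci A [define_loci()] result.
#' @param sites Site table (for lead IDs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_tsv <- function(loci, sites, path) {
  d <- data.frame(locus_id = loci$locus_id, chrom = loci$chrom,
                  start = loci$start, end = loci$end,
                  lead_id = paste0(sites$chrom[loci$lead], ":",
                                   sites$pos[loci$lead]),
                  lead_p = loci$lead_p, n_ind = loci$n_independent,
                  n_cand = loci$n_candidates)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
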