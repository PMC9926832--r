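#' Pairwise LD (r-squared) from dosages
#'
#' Squared Pearson correlation of dosage vectors between sites; the
#' analysis cohort's own dosages stand in for an external reference panel.
#' Monomorphic sites get r-squared 0 off the diagonal.
#'
#' @param dosage `N x M` dosage matrix.
#' @return `M x M` symmetric matrix with unit diagonal.
#' @export
ld_matrix <- function(dosage) {
  v <- apply(dosage, 2, var)
  r <- suppressWarnings(cor(dosage))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 1
  r2[v == 0, ] <- 0
  r2[, v == 0] <- 0
  diag(r2) <- 1
  r2
}

# greedy ascending-p selection under a mutual r2 constraint;
# position breaks p ties deterministically
.greedy_select <- function(idx, p, pos, r2, r2_max) {
  ord <- idx[order(p[idx], pos[idx])]
  acc <- integer(0)
  for (i in ord) {
    if (all(r2[i, acc] < r2_max)) acc <- c(acc, i)
  }
  sort(acc)
}

#' Independent significant SNPs
#'
#' Greedy by ascending p-value over genome-wide-significant SNPs: a SNP is
#' accepted iff its LD r-squared with every already-accepted SNP is below
#' `r2_indep`.
#'
#' @param pvals Per-site p-values (NA = untested).
#' @param pos Per-site bp positions (deterministic tie-break).
#' @param r2 LD matrix from [ld_matrix()].
#' @param p_thresh Genome-wide significance threshold.
#' @param r2_indep Independence threshold (default 0.6).
#' @return Sorted integer site indices.
#' @export
find_independent <- function(pvals, pos, r2, p_thresh, r2_indep = 0.6) {
  sig <- which(!is.na(pvals) & pvals <= p_thresh)
  .greedy_select(sig, pvals, pos, r2, r2_indep)
}

#' Lead SNPs among the independent significant SNPs
#'
#' Same greedy-by-p selection, with the stricter mutual constraint
#' `r2 < r2_lead` (default 0.1).
#'
#' @inheritParams find_independent
#' @param independents Indices from [find_independent()].
#' @param r2_lead Lead mutual-LD threshold.
#' @return Sorted integer site indices (a subset of `independents`).
#' @export
find_leads <- function(independents, pvals, pos, r2, r2_lead = 0.1) {
  .greedy_select(independents, pvals, pos, r2, r2_lead)
}

#' Candidate SNPs of the independent significant SNPs
#'
#' Union of the independent significant SNPs and every SNP with
#' `p < p_cand` that is in LD (`r2 >= r2_cand`) with at least one
#' independent SNP.
#'
#' @inheritParams find_leads
#' @param r2_cand Linkage threshold (default 0.6).
#' @param p_cand Nominal p-value ceiling for linked SNPs (default 0.05).
#' @return Sorted integer site indices.
#' @export
candidate_snps <- function(independents, pvals, r2, r2_cand = 0.6,
                           p_cand = 0.05) {
  if (length(independents) == 0) return(integer(0))
  linked <- which(!is.na(pvals) & pvals < p_cand &
    apply(r2[, independents, drop = FALSE] >= r2_cand, 1, any))
  sort(union(independents, linked))
}

#' Define genomic risk loci
#'
#' Each candidate SNP is assigned to its nearest lead SNP (bp distance);
#' the per-lead region spans its candidates' min..max positions; regions on
#' the same chromosome closer than `merge_dist` are merged iteratively to a
#' fixed point (the result is independent of processing order), and each
#' merged locus reports the smallest-p lead as its lead SNP.
#'
#' @param leads Lead SNP indices.
#' @param candidates Candidate SNP indices (must cover `leads`).
#' @param pvals,pos Per-site p-values and positions.
#' @param chrom Per-site chromosome labels.
#' @param independents Independent significant SNP indices (reported per
#'   locus).
#' @param merge_dist Merge distance in bp (default 250 kbp).
#' @return Data.frame (`risk_loci`): `locus_id`, `chrom`, `start`, `end`,
#'   `lead`, `lead_p`, `n_independent`, `n_candidates`, with a
#'   `members` attribute listing candidate indices per locus.
#' @export
define_loci <- function(leads, candidates, pvals, pos, chrom,
                        independents = leads, merge_dist = 2.5e5) {
  leads <- as.integer(leads)
  candidates <- as.integer(candidates)
  independents <- as.integer(independents)
  if (length(leads) == 0)
    return(structure(data.frame(locus_id = integer(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                lead = integer(0), lead_p = numeric(0),
                                n_independent = integer(0),
                                n_candidates = integer(0)),
                     members = list()))
  candidates <- sort(union(candidates, leads))
  # nearest lead on the same chromosome
  assign_lead <- vapply(candidates, function(s) {
    same <- leads[chrom[leads] == chrom[s]]
    same[which.min(abs(pos[same] - pos[s]))]
  }, integer(1))

  regions <- lapply(leads, function(l) {
    mem <- candidates[assign_lead == l]
    list(chrom = chrom[l], start = min(pos[mem]), end = max(pos[mem]),
         leads = l, members = mem)
  })

  # iterative merging to fixed point
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(regions)) {
      j <- i + 1
      while (j <= length(regions)) {
        a <- regions[[i]]; b <- regions[[j]]
        if (a$chrom == b$chrom &&
            max(a$start, b$start) - min(a$end, b$end) < merge_dist) {
          regions[[i]] <- list(chrom = a$chrom,
                               start = min(a$start, b$start),
                               end = max(a$end, b$end),
                               leads = c(a$leads, b$leads),
                               members = sort(union(a$members, b$members)))
          regions[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }

  ord <- order(vapply(regions, function(r) r$chrom, character(1)),
               vapply(regions, function(r) r$start, numeric(1)))
  regions <- regions[ord]
  out <- do.call(rbind, lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    lead <- r$leads[which.min(pvals[r$leads])]
    data.frame(locus_id = i, chrom = r$chrom, start = r$start, end = r$end,
               lead = lead, lead_p = pvals[lead],
               n_independent = sum(independents %in% r$members),
               n_candidates = length(r$members),
               stringsAsFactors = FALSE)
  }))
  attr(out, "members") <- lapply(regions, function(r) r$members)
  out
}

#' Positional gene mapping of candidate SNPs
#'
#' A gene is reported for a locus iff some candidate SNP lies within the
#' gene interval extended by `max_dist` bp on both sides.
#'
#' @param loci A [define_loci()] result (uses its `members` attribute).
#' @param pos Per-site bp positions.
#' @param chrom Per-site chromosome labels.
#' @param genes Data.frame with `chrom`, `start`, `end` (1-based inclusive
#'   gene spans) and `gene` (name).
#' @param max_dist Maximum mapping distance in bp (default 10 kbp).
#' @return List of character vectors, one per locus.
#' @export
map_genes_positional <- function(loci, pos, chrom, genes, max_dist = 1e4) {
  if (nrow(genes) > 0 && any(genes$end < genes$start))
    stop("malformed gene interval: end < start")
  members <- attr(loci, "members")
  lapply(members, function(mem) {
    hit <- vapply(seq_len(nrow(genes)), function(g) {
      same <- chrom[mem] == genes$chrom[g]
      any(same &
            pos[mem] >= genes$start[g] - max_dist &
            pos[mem] <= genes$end[g] + max_dist)
    }, logical(1))
    sort(unique(genes$gene[hit]))
  })
}
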