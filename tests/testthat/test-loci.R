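# build a toy LD-block instance: blocks of correlated sites with known r2
toy_instance <- function(n = 400, blocks = 6, per_block = 5, seed = 501) {
  set.seed(seed)
  m <- blocks * per_block
  g <- matrix(0, n, m)
  pos <- integer(m)
  for (b in seq_len(blocks)) {
    core <- rbinom(n, 2, runif(1, 0.2, 0.5))
    for (j in seq_len(per_block)) {
      col <- (b - 1) * per_block + j
      flip <- rbinom(n, 1, 0.15)  # partial decorrelation within block
      g[, col] <- ifelse(flip == 1, sample(core), core)
      pos[col] <- (b - 1) * 6e5 + j * 1e4
    }
  }
  list(g = g, pos = pos, chrom = rep("1", m),
       p = runif(m, 1e-12, 1))
}

# independent reimplementation of greedy-by-p selection (oracle)
greedy_oracle <- function(idx, p, pos, r2, thr) {
  ord <- idx[order(p[idx], pos[idx])]
  acc <- integer(0)
  for (i in ord) if (length(acc) == 0 || max(r2[i, acc]) < thr)
    acc <- c(acc, i)
  sort(acc)
}

test_that("LD matrix is a valid correlation-squared matrix", {
  ti <- toy_instance()
  r2 <- ld_matrix(ti$g)
  expect_equal(diag(r2), rep(1, ncol(ti$g)))
  expect_true(all(r2 >= 0 & r2 <= 1 + 1e-12))
  expect_equal(r2, t(r2), tolerance = 1e-12)
  # monomorphic sites do not poison the matrix
  g2 <- cbind(ti$g, 1)
  r2b <- ld_matrix(g2)
  expect_true(all(is.finite(r2b)))
  expect_equal(r2b[ncol(g2), 1], 0)
})

test_that("independent / lead selection equals the greedy oracle", {
  ti <- toy_instance()
  r2 <- ld_matrix(ti$g)
  thr <- sort(ti$p)[8]  # make 8 sites "significant"
  ind <- find_independent(ti$p, ti$pos, r2, thr, 0.6)
  expect_identical(ind, greedy_oracle(which(ti$p <= thr), ti$p, ti$pos,
                                      r2, 0.6))
  leads <- find_leads(ind, ti$p, ti$pos, r2, 0.1)
  expect_identical(leads, greedy_oracle(ind, ti$p, ti$pos, r2, 0.1))
  expect_true(all(leads %in% ind))

  # raising r2_indep never loses independent SNPs
  ind2 <- find_independent(ti$p, ti$pos, r2, thr, 0.9)
  expect_true(all(ind %in% ind2))

  # no significant SNP -> empty set
  expect_length(find_independent(ti$p, ti$pos, r2, 1e-300), 0)

  # two significant SNPs in strong LD -> only the smaller p survives
  r2p <- matrix(c(1, 0.9, 0.9, 1), 2)
  p2 <- c(1e-10, 1e-9)
  expect_identical(find_independent(p2, c(100, 200), r2p, 1e-8), 1L)
  # r2 = 0.3 pair: both independent, one lead
  r2q <- matrix(c(1, 0.3, 0.3, 1), 2)
  indq <- find_independent(p2, c(100, 200), r2q, 1e-8)
  expect_identical(indq, c(1L, 2L))
  expect_identical(find_leads(indq, p2, c(100, 200), r2q, 0.1), 1L)
})

test_that("candidate selection requires both LD and nominal significance", {
  r2 <- matrix(c(1, 0.7, 0.1,
                 0.7, 1, 0.2,
                 0.1, 0.2, 1), 3)
  p <- c(1e-10, 0.2, 0.01)
  # neighbor 2 has r2 = 0.7 but p = 0.2 -> excluded; site 3 not linked
  expect_identical(candidate_snps(1L, p, r2), 1L)
  p2 <- c(1e-10, 0.04, 0.01)
  expect_identical(candidate_snps(1L, p2, r2), c(1L, 2L))
  # set-comprehension oracle on the toy instance
  ti <- toy_instance()
  r2t <- ld_matrix(ti$g)
  thr <- sort(ti$p)[8]
  ind <- find_independent(ti$p, ti$pos, r2t, thr, 0.6)
  cand <- candidate_snps(ind, ti$p, r2t, 0.6, 0.05)
  oracle <- sort(union(ind, Filter(function(j)
    ti$p[j] < 0.05 && any(r2t[j, ind] >= 0.6), seq_along(ti$p))))
  expect_identical(cand, oracle)
  expect_length(candidate_snps(integer(0), ti$p, r2t), 0)
})

test_that("risk-locus definition merges regions to an order-free fixed point", {
  # one lead with a 40-kbp candidate span
  pos <- c(100e3, 110e3, 140e3)
  p <- c(1e-10, 1e-3, 1e-3)
  loci1 <- define_loci(1L, 1:3, p, pos, rep("1", 3))
  expect_equal(nrow(loci1), 1)
  expect_equal(loci1$start, 100e3)
  expect_equal(loci1$end, 140e3)
  expect_equal(loci1$lead, 1L)

  # two leads 100 kbp apart merge under the 250-kbp rule
  pos2 <- c(100e3, 200e3)
  p2 <- c(1e-10, 1e-9)
  loci2 <- define_loci(1:2, 1:2, p2, pos2, rep("1", 2))
  expect_equal(nrow(loci2), 1)
  expect_equal(loci2$lead, 1L)
  # but stay separate on different chromosomes
  loci2b <- define_loci(1:2, 1:2, p2, pos2, c("1", "2"))
  expect_equal(nrow(loci2b), 2)

  # random 5-lead instance: fixed point independent of lead ordering
  set.seed(502)
  m <- 40
  pos3 <- sort(sample.int(5e6, m))
  p3 <- runif(m, 1e-12, 0.04)
  leads3 <- sort(sample.int(m, 5))
  for (perm in 1:5) {
    lp <- sample(leads3)
    li <- define_loci(lp, seq_len(m), p3, pos3, rep("1", m))
    if (perm == 1) ref <- li
    expect_equal(li[names(li) != "locus_id"], ref[names(ref) != "locus_id"])
  }
  # every candidate belongs to exactly one locus
  members <- attr(ref, "members")
  expect_identical(sort(unlist(members)), seq_len(m))
})

test_that("positional gene mapping honors the 10-kbp boundary exactly", {
  pos <- c(50e3, 120e3)
  p <- c(1e-10, 1e-9)
  loci <- define_loci(1:2, 1:2, p, pos, rep("1", 2))
  # g_in contains SNP 1; g_out starts 10,001 bp beyond SNP 2 even after the
  # 10-kbp extension (140001 - 10000 = 130001 > 120000), so it must not map
  genes2 <- data.frame(chrom = "1",
                       start = c(40e3, 130001 + 10000),
                       end = c(60e3, 140001 + 10000),
                       gene = c("g_in", "g_out"), stringsAsFactors = FALSE)
  maps <- map_genes_positional(loci, pos, rep("1", 2), genes2)
  expect_true("g_in" %in% maps[[1]])
  expect_false(any(vapply(maps, function(m) "g_out" %in% m, logical(1))))
  # exact 10-kbp edge is mapped
  genes3 <- data.frame(chrom = "1", start = 130e3, end = 131e3,
                       gene = "edge", stringsAsFactors = FALSE)
  maps3 <- map_genes_positional(loci, pos, rep("1", 2), genes3)
  expect_true("edge" %in% unlist(maps3))

  # brute-force distance scan on a random instance
  set.seed(503)
  posr <- sort(sample.int(2e6, 50))
  pr <- runif(50, 1e-12, 1e-9)
  locir <- define_loci(which.min(pr), seq_len(50), pr, posr, rep("1", 50))
  genesr <- data.frame(chrom = "1", start = sort(sample.int(2e6, 20)),
                       gene = paste0("g", 1:20), stringsAsFactors = FALSE)
  genesr$end <- genesr$start + sample.int(3e4, 20)
  mapsr <- map_genes_positional(locir, posr, rep("1", 50), genesr)
  mem <- attr(locir, "members")[[1]]
  brute <- sort(unique(genesr$gene[vapply(seq_len(20), function(g) {
    any(posr[mem] >= genesr$start[g] - 1e4 & posr[mem] <= genesr$end[g] + 1e4)
  }, logical(1))]))
  expect_identical(mapsr[[1]], brute)
  expect_error(map_genes_positional(locir, posr, rep("1", 50),
                                    data.frame(chrom = "1", start = 10,
                                               end = 5, gene = "bad")),
               "malformed")
})
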