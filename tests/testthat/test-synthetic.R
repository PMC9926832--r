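test_that("panel generation is deterministic and respects its invariants", {
  p1 <- generate_panel(40, 60, region_length = 5e5, seed = 7)
  p2 <- generate_panel(40, 60, region_length = 5e5, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$sites$pos) > 0))
  expect_true(all(p1$alleles %in% c(0L, 1L)))
  expect_true(all(p1$sites$ref != p1$sites$alt))
  expect_error(generate_panel(1, 10), "dimensions")
})

test_that("without recombination every haplotype copies a founder verbatim", {
  p <- generate_panel(30, 40, region_length = 1e6, recomb_rate = 0,
                      n_founders = 2, seed = 5)
  # at most two distinct haplotypes, and polymorphic site pairs in full LD
  uh <- unique(p$alleles)
  expect_lte(nrow(uh), 2)
  poly <- which(apply(p$alleles, 2, var) > 0)
  if (length(poly) >= 2) {
    r2 <- cor(p$alleles[, poly])^2
    expect_true(all(abs(r2 - 1) < 1e-12))
  }
})

test_that("LD decays with distance in the founder-mosaic panel", {
  p <- generate_panel(200, 500, region_length = 5e6, recomb_rate = 1e-8,
                      n_meioses = 100, n_founders = 8, seed = 9)
  poly <- which(apply(p$alleles, 2, var) > 0)
  a <- p$alleles[, poly]
  pos <- p$sites$pos[poly]
  r2 <- cor(a)^2
  d <- abs(outer(pos, pos, "-"))
  adjacent <- r2[cbind(seq_len(ncol(a) - 1), seq_len(ncol(a) - 1) + 1)]
  far <- r2[d > 1e6 & upper.tri(r2)]
  expect_gt(mean(adjacent), mean(far))
})

test_that("sibling cohorts share parental haplotypes and track panel AF", {
  panel <- small_panel()
  solo <- sample_cohort(panel, 25, 1, seed = 3)
  expect_equal(anyDuplicated(solo$family_id), 0)

  co <- sample_cohort(panel, 240, 3, seed = 4)
  expect_identical(co$genotypes,
                   panel$alleles[co$hap_pairs[, 1], ] +
                     panel$alleles[co$hap_pairs[, 2], ])
  # within-family genotype concordance beats between-family concordance
  fam <- split(seq_len(co$n_samples), co$family_id)
  within <- mean(vapply(fam[lengths(fam) >= 2], function(ix)
    mean(co$genotypes[ix[1], ] == co$genotypes[ix[2], ]), numeric(1)))
  others <- vapply(seq_len(100), function(i) {
    ix <- sample(co$n_samples, 2)
    if (co$family_id[ix[1]] == co$family_id[ix[2]]) return(NA_real_)
    mean(co$genotypes[ix[1], ] == co$genotypes[ix[2], ])
  }, numeric(1))
  expect_gt(within, mean(others, na.rm = TRUE))

  # cohort allele frequency within 4 binomial SDs of the panel frequency
  big <- sample_cohort(panel, 1000, 1, seed = 5)
  pf <- colMeans(panel$alleles)
  tol <- 4 * sqrt(pmax(pf * (1 - pf), 1e-4) / (2 * 1000))
  expect_true(all(abs(big$true_af - pf) <= tol))
})

test_that("a two-haplotype degenerate panel gives only homozygous genotypes", {
  p <- generate_panel(2, 30, region_length = 1e5, recomb_rate = 0,
                      n_founders = 1, seed = 2)
  expect_equal(p$alleles[1, ], p$alleles[2, ])
  co <- sample_cohort(p, 20, 2, seed = 1)
  expect_true(all(co$genotypes %in% c(0L, 2L)))
  expect_true(all(co$genotypes == 2L * p$alleles[rep(1, 20), ]))
})

test_that("pileups follow the coverage/error model", {
  panel <- small_panel()
  co <- sample_cohort(panel, 50, 1, seed = 6)
  expect_identical(nrow(simulate_pileups(co, panel, 0, seed = 1)), 0L)

  # noiseless deep coverage on a hom-alt sample reproduces the alt base
  p1 <- generate_panel(2, 5, region_length = 1e4, recomb_rate = 0,
                       n_founders = 1, seed = 3)
  co1 <- sample_cohort(p1, 4, 1, seed = 3)
  prof <- default_error_profile(c(BGISeq500 = 1e-9, MiSeq = 1e-9,
                                  IonProton = 1e-9, IonTorrent = 1e-9))
  pu <- simulate_pileups(co1, p1, 30, error_profile = prof, seed = 4)
  hom_alt <- which(co1$genotypes == 2L, arr.ind = TRUE)
  for (r in seq_len(min(nrow(hom_alt), 50))) {
    sel <- pu$sample == hom_alt[r, 1] & pu$site == hom_alt[r, 2]
    expect_true(all(pu$base[sel] == p1$sites$alt[hom_alt[r, 2]]))
  }

  # unknown batch key is a configuration error
  bad <- default_error_profile()
  names(bad)[1] <- "nonsense:key"
  expect_error(simulate_pileups(co, panel, 0.05, error_profile = bad),
               "batch key")
})

test_that("pooled alt-read fraction matches f(1-e) + (1-f)e/3", {
  panel <- generate_panel(100, 1, region_length = 1e3, n_founders = 4,
                          af_spectrum = function(n) rep(0.25, n), seed = 8)
  co <- sample_cohort(panel, 16000, 1, seed = 9)
  e <- 0.002
  prof <- default_error_profile(c(BGISeq500 = e, MiSeq = e,
                                  IonProton = e, IonTorrent = e))
  pu <- simulate_pileups(co, panel, 0.04, error_profile = prof, seed = 10)
  f <- co$true_af[1]
  expected <- f * (1 - e) + (1 - f) * e / 3
  frac <- mean(pu$base == panel$sites$alt[1])
  n_reads <- nrow(pu)
  expect_lt(abs(frac - expected),
            4 * sqrt(expected * (1 - expected) / n_reads))
})

test_that("phenotype simulation follows the additive model and is z-scored", {
  panel <- small_panel()
  co <- sample_cohort(panel, 1744, 2, seed = 12)
  cov8 <- simulate_covariates(co$n_samples, seed = 13)

  # pure-noise model: phenotype uncorrelated with genotypes
  m0 <- phenotype_model(noise_sd = 1)
  y0 <- simulate_phenotype(co, m0, cov8, seed = 14)
  expect_lt(abs(mean(y0)), 1e-9)
  expect_equal(sd(y0), 1, tolerance = 1e-9)
  poly <- which(apply(co$genotypes, 2, var) > 0)
  rs <- abs(cor(y0, co$genotypes[, poly]))
  expect_lt(max(rs), 5 / sqrt(co$n_samples))

  # single causal SNP, no noise floor: affine in the genotype
  site <- poly[which.min(abs(co$true_af[poly] - 0.5))]
  m1 <- phenotype_model(site, 0.5, rep(0, 8), noise_sd = 1e-9)
  y1 <- simulate_phenotype(co, m1, cov8 * 0, seed = 15)
  expect_equal(abs(cor(y1, co$genotypes[, site])), 1, tolerance = 1e-6)

  # variance decomposition at beta = 0.3, MAF ~ 0.3
  site <- poly[which.min(abs(pmin(co$true_af, 1 - co$true_af)[poly] - 0.3))]
  p30 <- co$true_af[site]
  beta <- 0.3
  exp_r2 <- beta^2 * var(co$genotypes[, site])
  m2 <- phenotype_model(site, beta, rep(0, 8),
                        noise_sd = sqrt(1 - exp_r2))
  y2 <- simulate_phenotype(co, m2, cov8 * 0, seed = 16)
  r <- cor(y2, co$genotypes[, site])
  se_r <- (1 - r^2) / sqrt(co$n_samples)
  expect_lt(abs(r^2 - exp_r2), 3 * 2 * abs(r) * se_r + 1e-3)

  expect_error(simulate_phenotype(co, phenotype_model(9999, 0.1, rep(0, 8)),
                                  cov8, seed = 1),
               "out of range")
})
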