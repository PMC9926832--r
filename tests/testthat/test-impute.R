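
test_that("grid assignment follows floor((pos - start) / grid_size)", {
  params <- hmm_params(K = 2, grid_size = 10000)
  s <- test_sites(c(1, 5000, 10001, 25000))
  expect_identical(build_grid(s, params, window_start = 1),
                   c(0L, 0L, 1L, 2L))
  # one grid when the grid size exceeds the span
  expect_identical(build_grid(s, hmm_params(K = 2, grid_size = 1e6),
                              window_start = 1), rep(0L, 4))
  expect_error(build_grid(test_sites(c(10, 5)), params), "sorted")
  set.seed(201)
  pos <- sort(sample.int(3e5, 500))
  g <- build_grid(test_sites(pos), params)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0))
})

test_that("K = 1 genotype posteriors equal the direct Bayes computation", {
  params <- hmm_params(K = 1, grid_size = 1000, seed = 1)
  sites <- test_sites(c(100, 2100, 4100))
  theta <- matrix(c(0.3, 0.7, 0.05), nrow = 1)
  model <- make_model(theta, 1, sites, params)
  pu <- make_pileup(sample = c(1, 1, 1), site = c(1, 1, 2),
                    base = c("C", "A", "C"), error_prob = rep(0.02, 3),
                    n_samples = 2, n_sites = 3)
  post <- genotype_posteriors(pu, model)
  orc <- enum_oracle(theta, 1, sites, params, as.data.frame(pu))
  for (m in 1:3) {
    expect_equal(c(post$p0[1, m], post$p1[1, m], post$p2[1, m]),
                 orc$post[, m], tolerance = 1e-12)
  }
  # read-free sample sits at the Hardy-Weinberg prior of theta
  for (m in 1:3) {
    th <- theta[1, m]
    expect_equal(c(post$p0[2, m], post$p1[2, m], post$p2[2, m]),
                 c((1 - th)^2, 2 * th * (1 - th), th^2), tolerance = 1e-12)
  }
})

test_that("diploid forward-backward equals exhaustive path enumeration", {
  params <- hmm_params(K = 2, grid_size = 1000, n_gen = 2000,
                       recomb_rate = 1e-7, seed = 1)
  sites <- test_sites(c(500, 1500, 2500, 3500))  # one grid per site
  set.seed(202)
  theta <- matrix(runif(8), nrow = 2)
  pi <- c(0.6, 0.4)
  model <- make_model(theta, pi, sites, params)
  pu <- make_pileup(sample = c(1, 1, 1), site = c(1, 3, 3),
                    base = c("C", "A", "C"), error_prob = c(0.01, 0.05, 0.02),
                    n_samples = 1, n_sites = 4)
  orc <- enum_oracle(theta, pi, sites, params, as.data.frame(pu))

  gamma <- fb_state_posteriors(pu, model, sample = 1)
  for (g in 1:4)
    expect_equal(gamma[, g], orc$gamma[, g], tolerance = 1e-9)

  post <- genotype_posteriors(pu, model)
  for (m in 1:4)
    expect_equal(c(post$p0[1, m], post$p1[1, m], post$p2[1, m]),
                 orc$post[, m], tolerance = 1e-9)
})

test_that("posteriors match enumeration on a random 3-sample 4-site instance", {
  params <- hmm_params(K = 2, grid_size = 800, n_gen = 1000,
                       recomb_rate = 5e-7, seed = 1)
  sites <- test_sites(c(100, 900, 1700, 2500))
  set.seed(203)
  theta <- matrix(runif(8), nrow = 2)
  pi <- c(0.5, 0.5)
  model <- make_model(theta, pi, sites, params)
  reads <- data.frame(
    sample = c(1, 1, 2, 3, 3, 3),
    site = c(2, 4, 1, 1, 2, 2),
    base = sample(c("A", "C", "G"), 6, replace = TRUE),
    error_prob = runif(6, 0.005, 0.1), stringsAsFactors = FALSE)
  pu <- make_pileup(reads$sample, reads$site, reads$base, reads$error_prob,
                    n_samples = 3, n_sites = 4)
  post <- genotype_posteriors(pu, model)
  for (i in 1:3) {
    ri <- as.data.frame(pu)[pu$sample == i, , drop = FALSE]
    orc <- enum_oracle(theta, pi, sites, params, ri)
    for (m in 1:4)
      expect_equal(c(post$p0[i, m], post$p1[i, m], post$p2[i, m]),
                   orc$post[, m], tolerance = 1e-9)
  }
  # normalization invariant
  expect_lt(max(abs(post$p0 + post$p1 + post$p2 - 1)), 1e-9)
})

test_that("overwhelming alt evidence forces a hom-alt posterior", {
  params <- hmm_params(K = 2, grid_size = 1000, seed = 1)
  sites <- test_sites(c(100, 1200))
  model <- make_model(matrix(0.3, 2, 2), c(0.5, 0.5), sites, params)
  pu <- make_pileup(rep(1, 30), rep(1, 30), rep("C", 30), rep(1e-4, 30),
                    n_samples = 1, n_sites = 2)
  post <- genotype_posteriors(pu, model)
  expect_gt(post$p2[1, 1], 0.999)
})

test_that("EM increases the log-likelihood and recovers two founders", {
  panel <- generate_panel(40, 40, region_length = 4e5, recomb_rate = 0,
                          n_founders = 2,
                          af_spectrum = function(n) rep(0.5, n), seed = 204)
  co <- sample_cohort(panel, 300, 1, seed = 205)
  pu <- simulate_pileups(co, panel, 1, seed = 206)
  params <- hmm_params(K = 2, n_em_iters = 20, grid_size = 10000, seed = 207)
  model <- em_fit(pu, panel$sites, params)
  expect_true(all(diff(model$loglik_trace) >= -1e-6 *
                    (abs(model$loglik_trace[-length(model$loglik_trace)]) + 1)))

  # the two founder haplotypes appear in the panel; recover up to label swap
  founders <- unique(panel$alleles)
  err <- function(perm) max(abs(model$theta[perm, ] - founders))
  expect_lt(min(err(1:2), err(2:1)), 0.1)
})

test_that("an empty pileup yields a prior-only model with a warning", {
  sites <- test_sites(c(100, 500))
  pu <- make_pileup(integer(0), integer(0), character(0), numeric(0),
                    n_samples = 3, n_sites = 2)
  expect_warning(model <- em_fit(pu, sites, hmm_params(K = 2, seed = 2)),
                 "no reads")
  expect_true(model$no_reads)
  post <- genotype_posteriors(pu, model)
  expect_lt(max(abs(post$p0 + post$p1 + post$p2 - 1)), 1e-9)
})

test_that("INFO score: point masses, Hardy-Weinberg prior, hand arithmetic", {
  onehot <- matrix(c(1, 0, 0, 0, 0, 1, 0, 1, 0), ncol = 3, byrow = TRUE)
  expect_equal(info_score(onehot)$info, 1)

  th <- 0.3
  hw <- matrix(rep(c((1 - th)^2, 2 * th * (1 - th), th^2), 5),
               ncol = 3, byrow = TRUE)
  expect_equal(info_score(hw)$info, 0, tolerance = 1e-12)

  set.seed(208)
  gp <- matrix(runif(15), ncol = 3)
  gp <- gp / rowSums(gp)
  e <- gp[, 2] + 2 * gp[, 3]
  f <- gp[, 2] + 4 * gp[, 3]
  thh <- sum(e) / 10
  by_hand <- 1 - sum(f - e^2) / (10 * thh * (1 - thh))
  r <- info_score(gp)
  expect_equal(r$info, min(max(by_hand, 0), 1), tolerance = 1e-12)
  expect_equal(r$est_af, thh, tolerance = 1e-12)
})

test_that("window stitching: identity, tie to the left, union without duplicates", {
  fx <- fit_small_run()
  # single window: impute_region equals em_fit + posteriors directly
  post1 <- impute_region(fx$sub, fx$panel$sites[fx$pass, ], fx$params,
                         init_af = fx$calls$f_hat[fx$calls$status == "PASS"])
  expect_equal(post1$dosage, fx$post$dosage, tolerance = 1e-12)

  # hand-built windows: tie site must come from the left window
  one_site <- test_sites(1000)
  mk_post <- function(p2val) {
    p2 <- matrix(p2val, 1, 1); p1 <- matrix(0, 1, 1); p0 <- 1 - p2
    ulcgwas:::.as_genotype_posteriors(p0, p1, p2, one_site)
  }
  wl <- list(start = 0, end = 1200, center = 600, site_index = 1L,
             post = mk_post(0.2))
  wr <- list(start = 200, end = 1400, center = 1400, site_index = 1L,
             post = mk_post(0.9))
  # |1000-600| = 400 = |1000-1400|: exact tie -> left window
  out <- stitch_windows(list(wl, wr), one_site)
  expect_equal(out$p2[1, 1], 0.2)

  # three overlapping windows tile without duplication
  params3 <- hmm_params(K = 4, window_size = 5e5, window_overlap = 1e5,
                        n_em_iters = 4, seed = 31)
  sub_sites <- fx$panel$sites[fx$pass, ]
  post3 <- impute_region(fx$sub, sub_sites, params3,
                         init_af = fx$calls$f_hat[fx$calls$status == "PASS"])
  expect_equal(ncol(post3$p0), nrow(sub_sites))
  expect_lt(max(abs(post3$p0 + post3$p1 + post3$p2 - 1)), 1e-9)
  wins <- attr(post3, "windows")
  expect_gte(length(wins), 2)
})

test_that("imputed allele frequencies agree with the population call", {
  fx <- fit_small_run()
  f_hat <- fx$calls$f_hat[fx$calls$status == "PASS"]
  expect_gte(cor(fx$post$site_info$est_af, f_hat), 0.9)
})
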