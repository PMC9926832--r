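# Shared small fixtures, built once per test run.

small_panel <- function(n_hap = 60, n_sites = 80, region = 1e6,
                        n_founders = 6, seed = 11) {
  generate_panel(n_hap, n_sites, region_length = region,
                 n_founders = n_founders, seed = seed)
}

# cohort + pileup + PASS callset + fitted posteriors, reused across files
fit_small_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    panel <- small_panel()
    cohort <- sample_cohort(panel, 300, 2, seed = 21)
    pileup <- simulate_pileups(cohort, panel, 0.1, seed = 22)
    calls <- call_population(pileup, panel$sites, fix_alt = TRUE)
    pass <- calls$site_index[calls$status == "PASS"]
    sub <- ulcgwas:::.subset_pileup(pileup, pass)
    params <- hmm_params(K = 6, n_em_iters = 12, seed = 23)
    model <- em_fit(sub, panel$sites[pass, ], params,
                    init_af = calls$f_hat[calls$status == "PASS"])
    post <- genotype_posteriors(sub, model)
    cache <<- list(panel = panel, cohort = cohort, pileup = pileup,
                   calls = calls, pass = pass, sub = sub, params = params,
                   model = model, post = post)
    cache
  }
})

# dense grid-search maximizer of the pooled-read log-likelihood (oracle)
grid_af_oracle <- function(bases, e, ref, alt, step = 1e-5) {
  palt <- ifelse(bases == alt, 1 - e, e / 3)
  pref <- ifelse(bases == ref, 1 - e, e / 3)
  f <- seq(0, 1, by = step)
  ll <- colSums(log(outer(palt, f) + outer(pref, 1 - f)))
  f[which.max(ll)]
}

# exact HWE p-value by direct enumeration over heterozygote counts,
# computed from first principles with lchoose (independent of the
# implementation's lgamma route)
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  h <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  h <- h[(na - h) %% 2 == 0 & (na - h) / 2 >= 0 & n - h - (na - h) / 2 >= 0]
  logp <- vapply(h, function(hh) {
    aa <- (na - hh) / 2
    bb <- n - hh - aa
    lchoose(n, aa) + lchoose(n - aa, hh) + hh * log(2) -
      lchoose(2 * n, na)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[h == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
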