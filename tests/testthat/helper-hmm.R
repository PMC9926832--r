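# Hand-built HMM instances and an exhaustive-path enumeration oracle,
# shared by the imputation unit tests and the acceptance suite.

# helpers to build tiny instances by hand ------------------------------------

make_pileup <- function(sample, site, base, error_prob, n_samples, n_sites) {
  d <- data.frame(sample = sample, site = site, base = base,
                  error_prob = error_prob, stringsAsFactors = FALSE)
  d <- d[order(d$sample, d$site), , drop = FALSE]
  row.names(d) <- NULL
  structure(d, n_samples = as.integer(n_samples),
            n_sites = as.integer(n_sites),
            class = c("read_pileup", "data.frame"))
}

make_model <- function(theta, pi, sites, params) {
  grid <- build_grid(sites, params)
  structure(list(theta = theta, pi = pi, grid = grid,
                 cumlog = ulcgwas:::.cumlog_surv(max(grid) + 1L, params),
                 params = params, sites = sites,
                 loglik_trace = numeric(0), converged = TRUE,
                 no_reads = FALSE), class = "hap_model")
}

# exhaustive-path oracle for gamma and genotype posteriors on one sample
enum_oracle <- function(theta, pi, sites, params, reads) {
  K <- nrow(theta); M <- ncol(theta)
  grid <- build_grid(sites, params)
  G <- max(grid) + 1L
  s_adj <- exp(-(params$n_gen * params$recomb_rate * params$grid_size))
  states <- expand.grid(k1 = 1:K, k2 = 1:K)      # ordered pairs
  trans1 <- function(k, kp) s_adj * (k == kp) + (1 - s_adj) * pi[kp]

  lik <- .read_likelihoods_test(reads, sites)
  emis <- function(g, k1, k2) {
    w <- 1
    for (r in which(grid[reads$site] == g - 1L)) {
      b1 <- theta[k1, reads$site[r]] * lik$palt[r] +
        (1 - theta[k1, reads$site[r]]) * lik$pref[r]
      b2 <- theta[k2, reads$site[r]] * lik$palt[r] +
        (1 - theta[k2, reads$site[r]]) * lik$pref[r]
      w <- w * 0.5 * (b1 + b2)
    }
    w
  }

  n_states <- nrow(states)
  paths <- as.matrix(do.call(expand.grid, rep(list(1:n_states), G)))
  gamma <- matrix(0, n_states, G)
  for (pi_row in seq_len(nrow(paths))) {
    pth <- paths[pi_row, ]
    w <- pi[states$k1[pth[1]]] * pi[states$k2[pth[1]]] *
      emis(1, states$k1[pth[1]], states$k2[pth[1]])
    if (G > 1) for (g in 2:G) {
      w <- w * trans1(states$k1[pth[g - 1]], states$k1[pth[g]]) *
        trans1(states$k2[pth[g - 1]], states$k2[pth[g]]) *
        emis(g, states$k1[pth[g]], states$k2[pth[g]])
    }
    for (g in 1:G) gamma[pth[g], g] <- gamma[pth[g], g] + w
  }
  gamma <- sweep(gamma, 2, colSums(gamma), "/")

  # genotype posterior: marginalize allele draws given the state
  post <- matrix(0, 3, M)
  for (m in 1:M) {
    rr <- which(reads$site == m)
    lik00 <- prod(lik$pref[rr])
    lik11 <- prod(lik$palt[rr])
    lik01 <- prod(0.5 * (lik$pref[rr] + lik$palt[rr]))
    g <- grid[m] + 1L
    for (st in seq_len(n_states)) {
      t1 <- theta[states$k1[st], m]; t2 <- theta[states$k2[st], m]
      w00 <- (1 - t1) * (1 - t2) * lik00
      w01 <- ((1 - t1) * t2 + t1 * (1 - t2)) * lik01
      w11 <- t1 * t2 * lik11
      W <- w00 + w01 + w11
      post[, m] <- post[, m] + gamma[st, g] * c(w00, w01, w11) / W
    }
  }
  list(gamma = gamma, post = post)
}

.read_likelihoods_test <- function(reads, sites) {
  e <- reads$error_prob
  list(palt = ifelse(reads$base == sites$alt[reads$site], 1 - e, e / 3),
       pref = ifelse(reads$base == sites$ref[reads$site], 1 - e, e / 3))
}

test_sites <- function(pos, chrom = "1") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
             stringsAsFactors = FALSE)
}

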