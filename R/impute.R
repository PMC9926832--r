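#' Parameters of the ancestral-haplotype imputation HMM
#'
#' @param K Number of ancestral haplotypes (default 20, the value used for
#'   large ultra-low-coverage cohorts; the desk-scale preset lowers it).
#' @param n_gen Assumed number of generations since founding (default 2000);
#'   enters the transition probability `rho = 1 - exp(-n_gen * r * d)`.
#' @param grid_size Bp per grid window (default 10000); all sites in one
#'   grid share the hidden ancestry state.
#' @param window_size Bp per imputation window (default 5 Mbp).
#' @param window_overlap Overlap between adjacent windows (default 500 kbp);
#'   must be smaller than `window_size`.
#' @param n_em_iters Maximum EM iterations (default 30).
#' @param em_tol Relative log-likelihood change below which EM stops.
#' @param recomb_rate Per-bp recombination rate `r` (default 1e-8).
#' @param theta_prior Weight (in pseudo-reads) of the Beta prior that
#'   shrinks each ancestral allele probability toward the population allele
#'   frequency in the M-step (default 1). The shrinkage stabilizes thinly
#'   covered fits and washes out as read depth grows.
#' @param seed Seed for the Beta-perturbed initialization of the emission
#'   parameters.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(K = 20, n_gen = 2000, grid_size = 10000,
                       window_size = 5e6, window_overlap = 5e5,
                       n_em_iters = 30, em_tol = 1e-6,
                       recomb_rate = 1e-8, theta_prior = 1, seed = 1) {
  if (K < 1 || grid_size < 1) stop("K and grid_size must be >= 1")
  if (window_overlap >= window_size)
    stop("window_overlap must be smaller than window_size")
  if (theta_prior < 0) stop("theta_prior must be >= 0")
  structure(list(K = as.integer(K), n_gen = n_gen, grid_size = grid_size,
                 window_size = window_size, window_overlap = window_overlap,
                 n_em_iters = as.integer(n_em_iters), em_tol = em_tol,
                 recomb_rate = recomb_rate, theta_prior = theta_prior,
                 seed = seed),
            class = "hmm_params")
}

#' Assign sites to HMM grids
#'
#' `grid = floor((pos - window_start) / grid_size)` (0-based). Transitions
#' occur between consecutive grids; all sites in a grid share the hidden
#' diploid ancestry state.
#'
#' @param sites Site table sorted by position.
#' @param params An [hmm_params()].
#' @param window_start 1-based bp position of the window origin (defaults to
#'   the first site).
#' @return Integer vector of 0-based grid indices, one per site.
#' @export
build_grid <- function(sites, params, window_start = NULL) {
  pos <- sites$pos
  if (is.unsorted(pos)) stop("sites must be sorted by position")
  if (is.null(window_start)) window_start <- pos[1]
  as.integer((pos - window_start) %/% params$grid_size)
}

# cumulative log-survival of ancestry to grid g (uniform grid spacing)
.cumlog_surv <- function(n_grids, params) {
  -(params$n_gen * params$recomb_rate * params$grid_size) *
    (seq_len(n_grids) - 1)
}

.pileup_arrays <- function(pileup, sites) {
  n <- attr(pileup, "n_samples")
  lik <- .read_likelihoods(pileup, sites)
  offs <- c(0L, cumsum(tabulate(pileup$sample, nbins = n)))
  list(site0 = pileup$site - 1L, palt = lik$palt, pref = lik$pref,
       offsets = as.integer(offs), n_samples = n)
}

#' Fit the K-ancestral-haplotype model by EM
#'
#' Iterates forward-backward E-steps over the ordered diploid state space
#' (per-grid transitions `rho = 1 - exp(-n_gen * r * d)`, per-read emissions
#' `0.5 * (B(k1) + B(k2))` with `B(k) = theta[k,m] palt + (1-theta[k,m]) pref`)
#' and MAP M-step updates of `theta` from the expected alt-allele read
#' assignments plus a `theta_prior`-weighted Beta prior centered on the
#' population allele frequency. The tracked objective (log-likelihood plus
#' log prior) is nondecreasing across iterations. `theta` is initialized by
#' a Beta perturbation around the per-site allele frequency estimate, so
#' the fit is deterministic given `params$seed`.
#'
#' @param pileup A `read_pileup` over `sites`.
#' @param sites Site table (`chrom`, `pos`, `ref`, `alt`), sorted by
#'   position.
#' @param params An [hmm_params()].
#' @param init_af Optional per-site allele-frequency vector used to seed
#'   `theta` (e.g. the population-calling estimate); defaults to a pooled
#'   read-count moment estimate.
#' @param window_start Passed to [build_grid()].
#' @return An object of class `hap_model`: `theta` (K x M), `pi`, `grid`,
#'   `params`, `sites`, `loglik_trace` (data log-likelihood),
#'   `objective_trace` (MAP objective), `converged`, `no_reads`.
#' @export
em_fit <- function(pileup, sites, params, init_af = NULL,
                   window_start = NULL) {
  stopifnot(inherits(pileup, "read_pileup"), inherits(params, "hmm_params"))
  m <- nrow(sites)
  grid <- build_grid(sites, params, window_start)
  n_grids <- max(grid) + 1L
  cumlog <- .cumlog_surv(n_grids, params)
  arr <- .pileup_arrays(pileup, sites)

  if (is.null(init_af)) {
    n_alt <- n_tot <- numeric(m)
    if (nrow(pileup) > 0) {
      is_alt <- pileup$base == sites$alt[pileup$site]
      is_ref <- pileup$base == sites$ref[pileup$site]
      n_alt <- tabulate(pileup$site[is_alt], nbins = m)
      n_tot <- tabulate(pileup$site[is_alt | is_ref], nbins = m)
    }
    init_af <- (n_alt + 1) / (n_tot + 2)
  }
  init_af <- pmin(pmax(init_af, 1e-4), 1 - 1e-4)

  set.seed(params$seed)
  conc <- 10
  theta <- matrix(rbeta(params$K * m,
                        shape1 = rep(conc * init_af, each = params$K) + 0.5,
                        shape2 = rep(conc * (1 - init_af), each = params$K) + 0.5),
                  nrow = params$K)
  pi <- rep(1 / params$K, params$K)

  # Beta prior per (k, m): theta_prior pseudo-reads centered on init_af;
  # M-step is then the MAP update and the tracked objective is the
  # (unnormalized) log posterior, which EM makes nondecreasing.
  a_pr <- params$theta_prior * init_af
  b_pr <- params$theta_prior * (1 - init_af)
  log_prior <- function(th)
    sum(rep(a_pr, each = params$K) * log(th) +
          rep(b_pr, each = params$K) * log(1 - th))

  # one EM stage at the current number of ancestral haplotypes
  em_stage <- function(theta, max_iters) {
    K <- nrow(theta)
    pi_k <- rep(1 / K, K)
    lp <- function(th) sum(rep(a_pr, each = K) * log(th) +
                             rep(b_pr, each = K) * log(1 - th))
    trace <- obj <- numeric(0)
    occupancy <- NULL
    converged <- FALSE
    for (it in seq_len(max_iters)) {
      res <- hmm_forward_backward(theta, pi_k, cumlog, grid, arr$site0,
                                  arr$palt, arr$pref, arr$offsets,
                                  TRUE, FALSE, -1L)
      trace <- c(trace, res$loglik)
      obj <- c(obj, res$loglik + lp(theta))
      occupancy <- rowSums(res$theta_den)
      num <- res$theta_num + rep(a_pr, each = K)
      den <- res$theta_den + rep(a_pr + b_pr, each = K)
      upd <- den > 1e-12
      theta[upd] <- num[upd] / den[upd]
      if (it > 1 && abs(obj[it] - obj[it - 1]) <
            params$em_tol * (abs(obj[it - 1]) + 1)) {
        converged <- TRUE
        break
      }
    }
    list(theta = theta, trace = trace, obj = obj,
         occupancy = occupancy, converged = converged)
  }

  # split the busiest ancestral haplotypes into perturbed children until
  # the target K is reached (annealed fitting escapes symmetric optima
  # that direct K-hap EM gets trapped in)
  no_reads <- nrow(pileup) == 0
  trace <- numeric(0)
  obj_trace <- numeric(0)
  converged <- FALSE
  if (no_reads) {
    warning("pileup contains no reads; returning prior-only model")
  } else {
    k_seq <- unique(c(2^seq(1, ceiling(log2(params$K))), params$K))
    k_seq <- k_seq[k_seq <= params$K]
    if (params$K == 1) k_seq <- 1
    theta <- theta[seq_len(min(k_seq[1], params$K)), , drop = FALSE]
    for (si in seq_along(k_seq)) {
      if (si > 1) {
        k_new <- k_seq[si] - k_seq[si - 1]
        parents <- order(st$occupancy, decreasing = TRUE)[seq_len(k_new)]
        eps <- matrix(runif(k_new * m, -0.08, 0.08), nrow = k_new)
        child <- pmin(pmax(theta[parents, , drop = FALSE] + eps,
                           1e-3), 1 - 1e-3)
        theta <- rbind(theta, child)
      }
      st <- em_stage(theta, params$n_em_iters)
      theta <- st$theta
      trace <- c(trace, st$trace)
      obj_trace <- c(obj_trace, st$obj)
      converged <- st$converged
    }
  }
  pi <- rep(1 / nrow(theta), nrow(theta))

  structure(list(theta = theta, pi = pi, grid = grid, cumlog = cumlog,
                 params = params, sites = sites, init_af = init_af,
                 loglik_trace = trace, objective_trace = obj_trace,
                 converged = converged,
                 no_reads = no_reads), class = "hap_model")
}

#' @export
print.hap_model <- function(x, ...) {
  cat(sprintf("hap_model: K=%d over %d sites (%d grids), %d EM iterations\n",
              x$params$K, nrow(x$sites), max(x$grid) + 1L,
              length(x$loglik_trace)))
  invisible(x)
}

#' Per-sample genotype posteriors and site quality from a fitted model
#'
#' Runs forward-backward per sample under the fitted model and reports, at
#' every site, the posterior `(p0, p1, p2)` over the alt-allele count
#' (marginalizing the diploid ancestry state and the two allele draws given
#' the site's reads), the dosage `p1 + 2 p2`, the estimated allele frequency
#' `theta_hat = sum(dosage) / 2N`, and the IMPUTE2-style INFO score.
#'
#' @param pileup A `read_pileup` over the model's sites.
#' @param model A fitted [em_fit()] model.
#' @return An object of class `genotype_posteriors`: list with `p0`, `p1`,
#'   `p2`, `dosage` (N x M matrices) and `site_info` (data.frame `chrom`,
#'   `pos`, `est_af`, `info`).
#' @export
genotype_posteriors <- function(pileup, model) {
  stopifnot(inherits(model, "hap_model"))
  arr <- .pileup_arrays(pileup, model$sites)
  res <- hmm_forward_backward(model$theta, model$pi, model$cumlog, model$grid,
                              arr$site0, arr$palt, arr$pref, arr$offsets,
                              FALSE, TRUE, -1L)
  .as_genotype_posteriors(res$p0, res$p1, res$p2, model$sites)
}

.as_genotype_posteriors <- function(p0, p1, p2, sites) {
  dosage <- p1 + 2 * p2
  info <- .info_scores(p1, p2)
  structure(list(p0 = p0, p1 = p1, p2 = p2, dosage = dosage,
                 site_info = data.frame(chrom = sites$chrom, pos = sites$pos,
                                        est_af = info$est_af,
                                        info = info$info)),
            class = "genotype_posteriors")
}

# vectorized INFO over the columns (sites) of posterior matrices
.info_scores <- function(p1, p2) {
  n <- nrow(p1)
  e <- p1 + 2 * p2
  f <- p1 + 4 * p2
  theta_hat <- colSums(e) / (2 * n)
  denom <- 2 * n * theta_hat * (1 - theta_hat)
  info <- ifelse(denom > 0, 1 - colSums(f - e^2) / denom, 1)
  list(est_af = theta_hat, info = pmin(pmax(info, 0), 1))
}

#' IMPUTE2-style INFO score at one site
#'
#' With per-sample dosage `e_i = p1 + 2 p2` and second moment
#' `f_i = p1 + 4 p2`, and `theta_hat = sum(e_i) / 2N`:
#' `info = 1 - sum(f_i - e_i^2) / (2 N theta_hat (1 - theta_hat))`,
#' defined as 1 when `theta_hat` is 0 or 1 and clamped to `[0, 1]`.
#' The score is 1 when every posterior is a point mass and 0 when every
#' posterior equals the Hardy-Weinberg prior.
#'
#' @param gp `N x 3` matrix of genotype posterior triples.
#' @return List with `est_af` and `info`.
#' @export
info_score <- function(gp) {
  gp <- as.matrix(gp)
  if (ncol(gp) != 3 || nrow(gp) < 1) stop("gp must be an N x 3 matrix")
  r <- .info_scores(matrix(gp[, 2], ncol = 1), matrix(gp[, 3], ncol = 1))
  list(est_af = r$est_af[1], info = r$info[1])
}

#' Diploid state posteriors for one sample (diagnostic)
#'
#' Exposes the forward-backward posterior over ordered ancestral-haplotype
#' pairs at every grid, for checking the HMM against exhaustive path
#' enumeration on small instances.
#'
#' @param pileup A `read_pileup`.
#' @param model A fitted `hap_model`.
#' @param sample 1-based sample index.
#' @return A `K^2 x n_grids` matrix; rows ordered with `k1` varying fastest.
#' @export
fb_state_posteriors <- function(pileup, model, sample = 1) {
  arr <- .pileup_arrays(pileup, model$sites)
  res <- hmm_forward_backward(model$theta, model$pi, model$cumlog, model$grid,
                              arr$site0, arr$palt, arr$pref, arr$offsets,
                              FALSE, FALSE, as.integer(sample - 1L))
  res$gamma
}

#' Windowed imputation over a region
#'
#' Splits the site set into windows of `window_size` bp with
#' `window_overlap` bp overlap, fits the HMM and computes posteriors per
#' window, and stitches the windows back together (each site is taken from
#' the window whose center is nearest, ties to the left window).
#'
#' @inheritParams em_fit
#' @return A `genotype_posteriors` over all sites, with attribute
#'   `windows` describing the per-window spans.
#' @export
impute_region <- function(pileup, sites, params, init_af = NULL) {
  pos <- sites$pos
  if (is.unsorted(pos)) stop("sites must be sorted by position")
  span <- max(pos) - min(pos) + 1
  step <- params$window_size - params$window_overlap
  starts <- min(pos) + step * (0:max(0, ceiling((span - params$window_size) / step)))
  windows <- lapply(starts, function(s) {
    idx <- which(pos >= s & pos < s + params$window_size)
    list(start = s, end = s + params$window_size,
         center = s + params$window_size / 2, site_index = idx)
  })
  windows <- Filter(function(w) length(w$site_index) > 0, windows)

  results <- lapply(windows, function(w) {
    ss <- sites[w$site_index, , drop = FALSE]
    sub <- .subset_pileup(pileup, w$site_index)
    model <- em_fit(sub, ss, params, init_af = init_af[w$site_index],
                    window_start = w$start)
    w$post <- genotype_posteriors(sub, model)
    w
  })
  stitch_windows(results, sites)
}

# restrict a pileup to a site subset, re-indexing sites to 1..length(idx)
.subset_pileup <- function(pileup, site_index) {
  keep <- pileup$site %in% site_index
  d <- as.data.frame(pileup)[keep, , drop = FALSE]
  d$site <- match(d$site, site_index)
  row.names(d) <- NULL
  structure(d, n_samples = attr(pileup, "n_samples"),
            n_sites = length(site_index),
            class = c("read_pileup", "data.frame"))
}

#' Stitch per-window posteriors into a genome-wide result
#'
#' In overlap zones each site's posterior is taken from the window whose
#' center is nearer to the site; at an exact tie the left (lower-start)
#' window wins. Every site must be covered by at least one window.
#'
#' @param window_results List of window entries, each with `start`, `end`,
#'   `center`, `site_index` (global site indices) and `post`
#'   (a `genotype_posteriors` over those sites).
#' @param sites The global site table.
#' @return A `genotype_posteriors` over all sites.
#' @export
stitch_windows <- function(window_results, sites) {
  m <- nrow(sites)
  n <- nrow(window_results[[1]]$post$p0)
  src_win <- rep(NA_integer_, m)
  src_col <- rep(NA_integer_, m)
  best_d <- rep(Inf, m)
  ord <- order(vapply(window_results, function(w) w$start, numeric(1)))
  for (wi in ord) {
    w <- window_results[[wi]]
    d <- abs(sites$pos[w$site_index] - w$center)
    better <- d < best_d[w$site_index]  # strict: ties keep the left window
    gi <- w$site_index[better]
    src_win[gi] <- wi
    src_col[gi] <- which(better)
    best_d[gi] <- d[better]
  }
  if (anyNA(src_win))
    stop("window coverage gap: some sites fall in no window")
  p0 <- p1 <- p2 <- matrix(0, n, m)
  for (wi in unique(src_win)) {
    gi <- which(src_win == wi)
    cols <- src_col[gi]
    p0[, gi] <- window_results[[wi]]$post$p0[, cols, drop = FALSE]
    p1[, gi] <- window_results[[wi]]$post$p1[, cols, drop = FALSE]
    p2[, gi] <- window_results[[wi]]$post$p2[, cols, drop = FALSE]
  }
  out <- .as_genotype_posteriors(p0, p1, p2, sites)
  attr(out, "windows") <- lapply(window_results[ord], function(w)
    list(start = w$start, end = w$end, n_sites = length(w$site_index)))
  out
}
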