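.pipeline_defaults <- function(preset = "desk") {
  base <- list(
    panel = list(n_hap = 160, n_sites = 2000, region_length = 1.5e5,
                 recomb_rate = 1e-8, n_meioses = 100, n_founders = 6),
    cohort = list(n_samples = 1744, sibs_per_family = 2, coverage = 0.04),
    phenotype = list(n_causal = 1, beta = 0.35, causal_maf = 0.3,
                     covariate_effects = c(0.10, 0.05, 0, 0, 0, 0, 0.05, 0),
                     platform_shift = c(BGISeq500 = 0, MiSeq = 0.05,
                                       IonProton = -0.05, IonTorrent = 0.10),
                     noise_sd = NA),
    call = list(alpha = 1e-6, regions_bed = NA),
    impute = list(K = 6, n_gen = 100, grid_size = 10000,
                  window_size = 5e6, window_overlap = 5e5,
                  n_em_iters = 60, em_tol = 1e-7, recomb_rate = 1e-8),
    qc = list(info_min = 0.4, hwe_min = 1e-6, maf_min = 0.01,
              known_fraction = 0.95, require_known = TRUE),
    gwas = list(n_pcs = 0, min_high = 15, high_cutoff = 0.9, alpha = 0.05),
    loci = list(r2_indep = 0.6, r2_lead = 0.1, r2_cand = 0.6,
                p_cand = 0.05, merge_dist = 2.5e5))
  if (preset == "paper-scale") {
    base$panel <- list(n_hap = 400, n_sites = 5000, region_length = 5e6,
                       recomb_rate = 1e-8, n_meioses = 2000, n_founders = 20)
    base$cohort$n_samples <- 17844
    base$impute$K <- 20
    base$impute$n_gen <- 2000
    base$impute$n_em_iters <- 30
  }
  base
}

# recursive modifyList that rejects keys absent from the defaults
.merge_config <- function(defaults, overrides, path = "") {
  for (k in names(overrides)) {
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", path, k)
    if (is.list(defaults[[k]]) && is.list(overrides[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], overrides[[k]],
                                     paste0(path, k, "."))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Assembles the stage parameters of the end-to-end pipeline from a preset
#' plus overrides. The `"desk"` preset is a small synthetic study — one
#' densely genotyped 150-kbp locus (2000 sites, a single LD block) in 1744
#' samples at 0.04x with one planted causal SNP — sized for interactive
#' runs; `"paper-scale"` documents the parameters of a full-size
#' ultra-low-coverage cohort (17,844 samples, 5-Mbp windows, K = 20).
#' Unknown keys are rejected.
#'
#' @param preset `"desk"` or `"paper-scale"`.
#' @param overrides Named nested list of values to replace.
#' @return An object of class `pipeline_config` (nested list).
#' @export
pipeline_config <- function(preset = c("desk", "paper-scale"),
                            overrides = list()) {
  preset <- match.arg(preset)
  cfg <- .merge_config(.pipeline_defaults(preset), overrides)
  # YAML parses named numeric vectors back as lists; restore them
  cfg$phenotype$platform_shift <- unlist(cfg$phenotype$platform_shift)
  cfg$phenotype$covariate_effects <-
    unname(unlist(cfg$phenotype$covariate_effects))
  .validate_config(cfg)
  structure(cfg, preset = preset, class = c("pipeline_config", "list"))
}

.validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(panel$n_hap >= 2, panel$n_sites >= 1,
              cohort$n_samples >= 2, cohort$coverage >= 0,
              call$alpha > 0, call$alpha < 1,
              impute$K >= 1, impute$window_overlap < impute$window_size,
              qc$info_min >= 0, qc$info_min <= 1,
              qc$hwe_min >= 0, qc$hwe_min < 1,
              qc$maf_min >= 0, qc$maf_min <= 0.5,
              qc$known_fraction >= 0, qc$known_fraction <= 1,
              gwas$n_pcs >= 0, gwas$min_high >= 0,
              gwas$high_cutoff > 0, gwas$high_cutoff <= 1,
              loci$r2_indep >= 0, loci$r2_indep <= 1,
              loci$r2_lead >= 0, loci$r2_lead <= 1,
              loci$merge_dist >= 0)
  })
  invisible(cfg)
}

#' Serialize / parse a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # yaml drops names of atomic vectors; emit the batch shifts as a map
  cfg$phenotype$platform_shift <- as.list(cfg$phenotype$platform_shift)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @param preset Preset the parsed values override.
#' @export
read_config <- function(path, preset = "desk") {
  pipeline_config(preset, overrides = yaml::read_yaml(path))
}

.obj_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate -> population call -> impute -> QC -> GWAS -> risk
#' loci on a synthetic cohort, fully determined by `config` and `seed`.
#' Per-stage site/sample counts are logged to stderr and recorded in the
#' run manifest together with input/output checksums; a stage failure is
#' recorded and downstream stages are not run.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed; every stage derives its randomness from it.
#' @param out_dir Optional directory for VCF/TSV outputs.
#' @return An object of class `pipeline_run`: list with stage outputs
#'   (`panel`, `cohort`, `pileup`, `phenotype`, `covariates`, `calls`,
#'   `sites`, `post`, `qc`, `filtered`, `scan`, `effects`, `gc`, `loci`,
#'   ...) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed)
  manifest <- list(seed = seed, preset = attr(config, "preset"),
                   config_md5 = .obj_md5(unclass(config)),
                   counts = list(), md5 = list(), failed_stage = NULL)
  run <- list(config = config)
  t_all <- Sys.time()

  stage <- function(name, fun) {
    if (!is.null(manifest$failed_stage)) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(res)
      message(sprintf("[%s] FAILED: %s", name, conditionMessage(res)))
    } else {
      message(sprintf("[%s] done in %.1fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
    invisible(NULL)
  }

  stage("simulate", function() {
    cfgp <- config$panel; cfgc <- config$cohort
    run$panel <<- generate_panel(cfgp$n_hap, cfgp$n_sites,
                                 cfgp$region_length, cfgp$recomb_rate,
                                 cfgp$n_meioses, cfgp$n_founders,
                                 seed = seed + 11L)
    run$cohort <<- sample_cohort(run$panel, cfgc$n_samples,
                                 cfgc$sibs_per_family, seed = seed + 12L)
    run$pileup <<- simulate_pileups(run$cohort, run$panel, cfgc$coverage,
                                    seed = seed + 13L)
    run$covariates <<- simulate_covariates(cfgc$n_samples, seed = seed + 14L)
    ph <- config$phenotype
    causal <- integer(0); betas <- numeric(0)
    if (ph$n_causal > 0) {
      maf <- pmin(run$cohort$true_af, 1 - run$cohort$true_af)
      causal <- order(abs(maf - ph$causal_maf))[seq_len(ph$n_causal)]
      betas <- rep_len(ph$beta, ph$n_causal)
    }
    model <- phenotype_model(causal, betas, ph$covariate_effects,
                             batch_effects = list(platform = ph$platform_shift),
                             noise_sd = 1)
    if (is.na(ph$noise_sd)) {
      model$noise_sd <- residual_sd_for_unit_variance(run$cohort, model,
                                                      run$covariates)
    } else model$noise_sd <- ph$noise_sd
    run$phenotype_model <<- model
    run$causal_sites <<- causal
    run$phenotype <<- simulate_phenotype(run$cohort, model, run$covariates,
                                         seed = seed + 15L)
    manifest$counts$n_sites_simulated <<- nrow(run$panel$sites)
    manifest$counts$n_samples <<- run$cohort$n_samples
    manifest$counts$n_reads <<- nrow(run$pileup)
    manifest$md5$pileup <<- .obj_md5(run$pileup)
  })

  stage("call", function() {
    regions <- NULL
    if (!is.na(config$call$regions_bed) && nzchar(config$call$regions_bed))
      regions <- read_bed(config$call$regions_bed)
    run$calls <<- call_population(run$pileup, run$panel$sites,
                                  alpha = config$call$alpha,
                                  regions = regions)
    pass <- run$calls$status == "PASS"
    run$pass_sites <<- run$calls$site_index[pass]
    run$sites <<- data.frame(chrom = run$calls$chrom[pass],
                             pos = run$calls$pos[pass],
                             ref = run$calls$ref[pass],
                             alt = run$calls$alt[pass],
                             stringsAsFactors = FALSE)
    if (length(run$pass_sites) < 2) stop("fewer than 2 PASS sites called")
    manifest$counts$n_sites_called <<- length(run$pass_sites)
    manifest$md5$calls <<- .obj_md5(run$calls)
  })

  stage("impute", function() {
    ci <- config$impute
    params <- hmm_params(ci$K, ci$n_gen, ci$grid_size, ci$window_size,
                         ci$window_overlap, ci$n_em_iters, ci$em_tol,
                         ci$recomb_rate, seed = seed + 21L)
    pu <- .subset_pileup(run$pileup, run$pass_sites)
    f_hat <- run$calls$f_hat[run$calls$status == "PASS"]
    run$post <<- impute_region(pu, run$sites, params, init_af = f_hat)
    manifest$counts$n_sites_imputed <<- ncol(run$post$p0)
    manifest$md5$dosage <<- .obj_md5(run$post$dosage)
  })

  stage("qc", function() {
    set.seed(seed + 31L)
    # common variants are nearly always in dbSNP-like catalogs; rare ones
    # are "known" at the configured base rate
    af <- run$post$site_info$est_af
    p_known <- ifelse(pmin(af, 1 - af) >= 0.05, 0.99,
                      config$qc$known_fraction)
    known <- runif(ncol(run$post$p0)) < p_known
    run$qc <<- site_qc(run$post, known_flag = known)
    run$filtered <<- apply_filters(run$qc, config$qc$info_min,
                                   config$qc$hwe_min, config$qc$maf_min,
                                   config$qc$require_known)
    if (nrow(run$filtered) < 2) stop("fewer than 2 sites survive QC filters")
    manifest$counts$n_sites_filtered <<- nrow(run$filtered)
  })

  stage("gwas", function() {
    keep <- run$filtered$site
    dosage <- run$post$dosage[, keep, drop = FALSE]
    run$pcs <<- if (config$gwas$n_pcs > 0)
      compute_pcs(dosage, n_pcs = config$gwas$n_pcs) else NULL
    X <- covariate_matrix(run$pcs, run$covariates)
    sub <- .as_genotype_posteriors(run$post$p0[, keep, drop = FALSE],
                                   run$post$p1[, keep, drop = FALSE],
                                   run$post$p2[, keep, drop = FALSE],
                                   run$sites[keep, , drop = FALSE])
    scan <- score_test(dosage, run$phenotype, X, post = sub,
                       min_high = config$gwas$min_high,
                       high_cutoff = config$gwas$high_cutoff)
    scan$site_index <- keep
    run$scan <<- scan
    n_tested <- sum(scan$tested)
    if (n_tested < 1) stop("no site reaches the minHigh testing rule")
    run$p_thresh <<- bonferroni_threshold(n_tested, config$gwas$alpha)
    sig <- which(scan$tested & scan$p_value <= run$p_thresh)
    run$effects <<- if (length(sig)) do.call(rbind, lapply(sig, function(j) {
      es <- effect_size(dosage[, j], run$phenotype, X)
      data.frame(site = j, site_index = keep[j], beta = es$beta, se = es$se)
    })) else data.frame(site = integer(0), site_index = integer(0),
                        beta = numeric(0), se = numeric(0))
    run$gc <<- genomic_control(scan$chi2[scan$tested])
    manifest$counts$n_sites_tested <<- n_tested
    manifest$counts$n_significant <<- length(sig)
    manifest$md5$scan <<- .obj_md5(scan)
  })

  stage("clump", function() {
    keep <- run$filtered$site
    dosage <- run$post$dosage[, keep, drop = FALSE]
    pvals <- ifelse(run$scan$tested, run$scan$p_value, NA_real_)
    pos <- run$sites$pos[keep]
    chrom <- run$sites$chrom[keep]
    ld <- ld_matrix(dosage)
    cl <- config$loci
    indep <- find_independent(pvals, pos, ld, run$p_thresh, cl$r2_indep)
    leads <- find_leads(indep, pvals, pos, ld, cl$r2_lead)
    cands <- candidate_snps(indep, pvals, ld, cl$r2_cand, cl$p_cand)
    run$independent <<- indep
    run$leads <<- leads
    run$candidates <<- cands
    run$loci <<- define_loci(leads, cands, pvals, pos, chrom,
                             independents = indep,
                             merge_dist = cl$merge_dist)
    manifest$counts$n_loci <<- nrow(run$loci)
  })

  if (!is.null(out_dir) && is.null(manifest$failed_stage)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls_vcf(run$calls, file.path(out_dir, "calls.vcf"))
    write_genotype_vcf(run$post, run$sites,
                       file.path(out_dir, "imputed.vcf"))
    keep <- run$filtered$site
    write_qc_tsv(run$qc, run$sites, seq_len(nrow(run$qc)) %in% keep,
                 file.path(out_dir, "site_qc.tsv"))
    write_sumstats_tsv(run$scan, run$sites[keep, , drop = FALSE],
                       run$qc[keep, , drop = FALSE], run$effects,
                       file.path(out_dir, "sumstats.tsv"))
    write_loci_tsv(run$loci, run$sites[keep, , drop = FALSE],
                   file.path(out_dir, "loci.tsv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }

  message(sprintf("[pipeline] total %.1fs",
                  as.numeric(Sys.time() - t_all, units = "secs")))
  run$manifest <- structure(manifest, class = "pipeline_manifest")
  structure(run, class = "pipeline_run")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline_manifest (seed ", x$seed, ", preset ", x$preset, ")\n",
      sep = "")
  for (k in names(x$counts)) cat(sprintf("  %-22s %s\n", k, x$counts[[k]]))
  if (!is.null(x$failed_stage))
    cat("  FAILED at stage:", x$failed_stage, "-", x$error, "\n")
  invisible(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  print(x$manifest)
  invisible(x)
}
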