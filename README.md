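# ulcgwas

Genotype imputation and association testing for ultra-low-coverage
whole-genome sequencing (ulcWGS) cohorts.

When sequencing coverage drops below 0.1× — as in preimplantation genetic
testing (PGT), where a trophectoderm biopsy yields ~0.04× per embryo — no
individual sample carries enough reads to call its own genotypes. What a
large cohort does carry, collectively, is enough information to (i) discover
the population's SNVs and their allele frequencies from pooled reads, and
(ii) impute each sample's genotypes by modelling its two chromosomes as
mosaics of a small set of ancestral haplotypes. `ulcgwas` implements that
analysis chain end to end, plus the benchmarking and association machinery
around it, and a synthetic-cohort generator so every stage is testable
without any external data.

## What is implemented

**Population SNV calling** (`estimate_af`, `determine_alt`, `lrt_call`,
`call_population`). Pooled across samples, the reads at a site follow the
two-allele mixture likelihood

    L(f) = prod_r [ f·P(b_r | alt) + (1−f)·P(b_r | ref) ],
    P(b | a) = 1 − e_r  if b = a,  e_r/3 otherwise,

maximized over the alt-allele frequency `f ∈ [0,1]` by golden-section search
(the log-likelihood is concave). Sites are called by the likelihood-ratio
statistic `Λ = 2(log L(f̂) − log L(0))` against χ²(1); the alternate allele
is the non-reference base with the highest maximized likelihood, with a
multi-allelic flag when a second base also passes the test. BED exclusion
regions (problematic-alignment or low-mappability intervals) are applied as
a generic region filter.

**Genotype imputation** (`hmm_params`, `em_fit`, `genotype_posteriors`,
`impute_region`). A diploid Li-and-Stephens copying model with `K` ancestral
haplotypes: sites are binned into grids (default 10 kbp), the hidden state
is an ordered pair of ancestral haplotypes, ancestry switches between
adjacent grids with probability `ρ = 1 − exp(−nGen·r·d)`, and each read is
emitted with probability `½(B(k₁)+B(k₂))`,
`B(k) = θ[k,m]·P(b|alt) + (1−θ[k,m])·P(b|ref)`. The emission parameters θ
are fitted by EM (forward-backward E-step in C++, with exact collapsing of
read-free grid gaps; annealed K-splitting initialization; MAP M-step with a
Beta pseudo-read prior). Output per sample × site is the posterior
`(p₀,p₁,p₂)` over alt-allele count, the dosage `p₁+2p₂`, and per site the
IMPUTE2-style INFO score. Long regions are imputed in 5-Mbp windows with
500-kbp overlap and stitched by nearest window center.

**Site QC** (`site_qc`, `apply_filters`, `hwe_exact_test`,
`accuracy_vs_truth`). Exact conditional Hardy-Weinberg test on argmax hard
calls, minor-allele frequency from mean dosage, and the filter combination
used for association input (`INFO ≥ 0.4`, `HWE p > 1e−6`, `MAF ≥ 0.01`,
known-variant membership). Accuracy against truth comes in two flavours:
hard-call concordance (genotype accuracy) and non-reference-presence
concordance (allele accuracy).

**Association** (`score_test`, `effect_size`, `compute_pcs`,
`genomic_control`). Quantitative-trait score test on genotype dosages:
with null-model residuals `r` and dosage vector `e`, `U = eᵀr/σ̂²`,
`V = eᵀPe/σ̂²`, `U²/V ~ χ²(1)`; a site is tested only when at least
`minHigh = 15` samples have a high-credibility genotype. Effect sizes come
from OLS of the phenotype on covariates plus dosage; covariates are an
intercept, top dosage principal components, and clinical records; genomic
control is `λ_GC = median(χ²)/0.4549`.

**Risk loci** (`ld_matrix`, `find_independent`, `find_leads`,
`candidate_snps`, `define_loci`, `map_genes_positional`). FUMA-style
clumping: independent significant SNPs (greedy by p, mutual `r² < 0.6`),
lead SNPs (`r² < 0.1`), candidate SNPs (`r² ≥ 0.6` to an independent SNP and
`p < 0.05`), iterative merging of lead regions within 250 kbp into genomic
risk loci, and positional gene mapping within 10 kbp.

**Benchmarking** (`run_grid`, `fit_accuracy_model`, `predict_accuracy`,
`bonferroni_threshold`). The coverage × sample-size accuracy grid with
held-out truth samples, and the linear expected-accuracy surface
`acc = a·c + b·s + c₀` fitted to it.

**Synthetic cohorts** (`generate_panel`, `sample_cohort`,
`simulate_pileups`, `simulate_covariates`, `simulate_phenotype`). A
founder-mosaic haplotype panel with tunable LD, sibling-structured diploid
cohorts with WGA-kit × platform batch labels, Poisson read pileups with
per-batch error rates, and a z-scored quantitative phenotype with additive
causal, clinical-covariate, and batch terms.

## Worked example

The `"desk"` preset simulates one densely genotyped 150-kbp locus in 1744
embryos at 0.04× with a single causal SNP (β = 0.35 on the z-scale at
MAF ≈ 0.3) and runs the whole chain:

```r
library(ulcgwas)
run <- run_pipeline(pipeline_config("desk"), seed = 1)
print(run$manifest)
#> pipeline_manifest (seed 1, preset desk)
#>   n_sites_simulated      2000
#>   n_samples              1744
#>   n_reads                139113
#>   n_sites_called         1293
#>   n_sites_imputed        1293
#>   n_sites_filtered       1156
#>   n_sites_tested         1122
#>   n_significant          578
#>   n_loci                 1
run$loci
#>   locus_id chrom start    end lead       lead_p n_independent n_candidates
#> 1        1     1   205 149862  210 1.709837e-24            17          801
```

Of 2000 simulated sites, 1293 are discovered by pooled-read calling, 1156
survive the INFO/HWE/MAF filters, and the scan finds one genomic risk locus.
The planted causal SNP (position 770) is genome-wide significant
(p = 2.6e−23 against the scan's Bonferroni threshold 4.5e−05) and lies
inside the locus. The 578 significant SNPs are the causal SNP's LD
neighbours across the locus — a single strong association spread over one
LD block, which is also why `λ_GC` is far above 1 in this single-locus
design (genomic control assumes most sites are null and unlinked).

Outputs can be written to standard formats (`out_dir =` gives VCF for calls
and imputed genotypes with `GT:GP:DS`, TSV for QC, summary statistics, and
loci, plus a YAML run manifest). A thin CLI with `run-all` and `benchmark`
subcommands is installed under `inst/scripts/ulcgwas`.

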