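---
title: "Models and design choices in ulcgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in ulcgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The problem

At ultra-low coverage (here ~0.04× per sample, as produced by
preimplantation genetic testing of embryo biopsies) a sample's reads touch
only a few percent of polymorphic sites, once each. Individual genotype
calling is impossible; the information lives in the cohort. The chain is:
pooled-read SNV discovery → haplotype-model genotype imputation →
site-level quality filtering → dosage-based association → LD-based locus
definition, with a coverage × sample-size benchmark harness around the
imputation step.

## Pooled-read allele-frequency estimation and calling

Reads at one site, pooled over all samples, are modelled as draws from a
two-allele mixture: a read comes from an alt-carrying chromosome with
probability `f` and is then observed correctly with probability `1 − e`
(substituted uniformly to one of the other three bases otherwise, hence
`P(b|a) = e/3` off-allele). The per-read error `e` derives from Phred
quality (`e = 10^(−Q/10)`, floored at 1e−4, capped at 0.75). The
log-likelihood in `f` is concave, so a golden-section search (tolerance
1e−6) with an explicit comparison against both boundaries finds the MLE;
monomorphic pileups return exactly `f̂ = 0` or `1`.

Calling uses `Λ = 2(ℓ(f̂) − ℓ(0))` against χ²(1). The true null
distribution at the boundary is the mixture `½χ²₀ + ½χ²₁`; using plain
χ²(1) is conservative and standard. The default calling level is
`alpha = 1e−6` (configurable; the source studies do not print theirs). The
alternate allele is chosen by maximized likelihood across the three
non-reference bases, ties broken lexicographically (A < C < G < T) for
determinism; a second base passing the per-allele LRT flags the site
multi-allelic, and such sites are excluded downstream (bi-allelic
restriction). Both mappability-style filters are expressed as generic
0-based half-open BED exclusion regions; the specific reference resources
are not bundled.

## The diploid ancestral-haplotype HMM

Each sample's two chromosomes are modelled as mosaics of `K` ancestral
haplotypes. Sites are binned into grids of `grid_size` bp (default 10 kbp);
all sites in a grid share the hidden ordered pair `(k₁, k₂)`; each
haplotype independently switches ancestry between adjacent grids with
probability `ρ = 1 − exp(−nGen · r · d)` where `d` is the physical gap,
`r` the per-bp recombination rate (default 1e−8), and `nGen` the assumed
generations since founding. Each read at site `m` is emitted with
probability `½(B(k₁)+B(k₂))`, `B(k) = θ[k,m]·P(b|alt) + (1−θ[k,m])·P(b|ref)`
— reads are conditionally independent given the state, which is the
standard approximation for this model family.

Defaults follow the large-cohort settings of the method this reimplements:
`K = 20`, `nGen = 2000`, `grid_size = 10000`, 5-Mbp windows with 500-kbp
overlap. The desk-scale preset lowers `K` and sets `nGen = 100` to match
the synthetic generator's founding depth (see below): `nGen · r` should be
the population's actual per-bp ancestry-switch rate, and the generator's is
`n_meioses · recomb_rate`.

**Fitting.** EM with a forward-backward E-step over the ordered `K × K`
state space. Two exact computational devices keep this fast: the transition
kernel `T = s·I + (1−s)·1πᵀ` is diagonal-plus-rank-one, so propagation
costs `O(K²)` instead of `O(K³)`; and grids without reads have emission 1,
so runs of empty grids are collapsed by composing survival probabilities
(`T` compositions stay in the same family), making the per-iteration cost
scale with covered grids only. The M-step updates `θ[k,m]` from the
expected per-read ancestry/allele assignments — exact EM for the per-read
emission model — plus a Beta pseudo-read prior of weight `theta_prior`
(default 1 read) centered on the population allele frequency. The prior
stabilizes thinly covered fits and washes out as depth grows; the tracked
objective (log-likelihood + log prior) is nondecreasing across iterations.

Direct EM at the target `K` reliably lands in symmetric local optima at
ultra-low depth, so fitting is annealed: start at `K = 2` haplotypes
(Beta-perturbed around the population AF, seed-controlled), run EM, split
the highest-occupancy haplotypes into perturbed children, refit, and repeat
until the target `K`. In testing this matches the fit quality of an oracle
initialized at the true haplotype cluster centers. EM stops at
`n_em_iters` (default 30) or relative objective change below `em_tol`
(1e−6); `pi` stays uniform and no per-sample rates are updated.

**Posteriors.** Per sample and site, the genotype posterior marginalizes
the diploid ancestry state (forward-backward) and the two allele draws
given the site's reads under a shared-allele likelihood; with no reads the
triple is the ancestry-weighted product of Bernoulli(θ) draws. Dosage is
`p₁ + 2p₂`; the estimated allele frequency is `θ̂ = Σ dosage / 2N`; the
IMPUTE2-style INFO score is
`1 − Σᵢ(fᵢ − eᵢ²) / (2N θ̂(1−θ̂))` with `eᵢ = p₁+2p₂`, `fᵢ = p₁+4p₂`,
defined as 1 when `θ̂ ∈ {0,1}` and clamped to `[0,1]`. It is exactly 1 for
point-mass posteriors and exactly 0 when every posterior equals the
Hardy-Weinberg prior.

**Windows.** Long regions are imputed in overlapping windows; in overlap
zones a site's posterior comes from the window whose center is nearer,
ties to the left window. Every site must fall in some window.

## Site QC

The Hardy-Weinberg test is the exact conditional test (enumeration of
heterozygote counts at fixed allele totals, summing configurations no more
probable than the observed one) computed on argmax hard calls; the argmax
tie rule prefers the lower genotype. Hard calls rather than dosages make
the test well-defined and enumeration-checkable. MAF is taken from mean
dosage (smoother than hard calls at ultra-low coverage). The association
input filter is the four-condition combination: known-variant membership,
`MAF ≥ 0.01`, `INFO ≥ 0.4`, `HWE p > 1e−6`.

Accuracy against truth is reported two ways over the same denominator:
genotype accuracy (hard call equals truth) and allele accuracy
(non-reference presence agrees), so allele accuracy ≥ genotype accuracy by
construction. Benchmarks evaluate each truth sample on the intersection of
called sites and that sample's own variant sites, mirroring how a
known-genotype reference sample is scored against its variant catalogue.

## Association and loci

The phenotype is z-scored (mean 0, SD 1, denominator N−1). The score test
fits the null linear model once; per site,
`U = eᵀr/σ̂²`, `V = (eᵀe − eᵀX(XᵀX)⁻¹Xᵀe)/σ̂²`, `χ² = U²/V` on 1 df, with
dosages (posterior-mean genotypes) as `e`. A site is tested only when at
least `minHigh = 15` samples have max posterior ≥ `high_cutoff = 0.9`;
dosages inside the covariate span are flagged untested. Effect sizes are
the dosage coefficient of OLS on covariates plus dosage. Genomic control
uses the median-based `λ_GC = median(χ²)/qchisq(0.5, 1)`; LD-score-based
intercept estimation is out of scope (it needs an external LD reference).
Multiple testing is Bonferroni only.

Principal components are computed from the dosage matrix restricted to
`MAF ≥ 0.05`, centered by `2θ̂` and scaled by `sqrt(2θ̂(1−θ̂))`, with
deterministic sign fixing. A caution that matters at small scale: PCs of a
dosage matrix spanning a single short locus capture the local haplotype
structure — including any causal variant — rather than batch or ancestry
structure, and will absorb the association signal. The desk preset
therefore runs with `n_pcs = 0`; PC correction is meaningful when dosages
span many independent loci (as in the full-scale setting, where 8 PCs are
the intended default).

Risk-locus definition follows the standard clumping rules: independent
significant SNPs greedily by ascending p with mutual `r² < 0.6`; lead SNPs
among them with `r² < 0.1`; candidate SNPs with `r² ≥ 0.6` to an
independent SNP and `p < 0.05`; per-lead regions spanning their candidates,
merged iteratively within 250 kbp (a public default for the otherwise
unstated merge rule) to an order-independent fixed point. LD is computed
from the analysis cohort's own dosages, standing in for an external
reference panel. Positional gene mapping reports genes within 10 kbp of a
candidate SNP.

## The synthetic generator, and what it does not emulate

The haplotype panel is a founder-mosaic copying process: `n_founders`
founder haplotypes drawn site-wise from an allele-frequency spectrum
(default skewed low, Beta(0.8, 2.4) truncated to [0.02, 0.98], so alt is
usually minor), and each panel haplotype copies founders with ancestry
switches at per-bp rate `recomb_rate × n_meioses` (default 1e−8 × 100).
`n_meioses` plays the role of generations since founding, which is why the
desk imputation preset sets `nGen = 100`. This gives tunable LD with exact
ground truth; it is not a coalescent and has no mutation, gene conversion,
or variable recombination maps.

Cohorts are sibling-structured: each family draws two parental haplotype
pairs and every sibling inherits one haplotype per pair (no within-family
meiotic recombination — panel LD already carries the linkage structure).
Batch labels cross 3 WGA kits with 4 platforms; the default error profile
makes the semiconductor platforms an order of magnitude noisier, planting
a realistic batch confounder. Pileups are Poisson(coverage) per site with
uniform-substitution errors. The phenotype is additive causal effects plus
clinical-covariate effects (2 Gaussian + 6 Bernoulli records under their
clinical names), platform shifts, and Gaussian noise, then z-scored; a
helper chooses the residual SD for unit total variance so planted effects
are on the z-scale. The known-variant flag emulates catalogue membership
and is MAF-aware in the pipeline (common variants are nearly always
catalogued).

One structural difference from real data drives the desk-scale designs:
synthetic reads exist only at panel sites, so a sample's information per
window is `coverage × n_sites` reads, whereas a real 0.04× genome spreads
reads over all bases and touches thousands of sites per window. Desk
experiments therefore use densely sited regions so that per-sample read
counts match the information regime of the real setting; a consequence is
that passing desk-scale tests demonstrates the machinery's correctness and
its qualitative trends, not genome-scale accuracy values.

## Experiment designs in the test suite

Problem sizes are the package's own choices, selected so each designed
experiment is informative at interactive runtimes:

* **Coverage × sample-size benchmark**: a 4-founder, 2-Mbp, 2000-site
  panel with `K = 4`, truth coverages {0.01, 0.04, 0.1} × cohort sizes
  {500, 2000}, 8 held-out truth samples per grid point, averaged over three
  replicate cohorts (single-replicate rows wobble by about ±0.05 at the
  smallest size; the trend assertions use a ±0.03 band). The 4-founder
  panel holds reads-per-site-per-ancestral-haplotype comparable to the
  full-scale setting at its smallest cohort.
* **INFO sweep and filter benefit**: a 6-founder panel — filters only help
  when imputation quality varies across sites, and the 4-founder panel is
  uniformly easy. The filter comparison is evaluated cohort-wide on
  variant entries (truth is known for every synthetic sample), where the
  systematic benefit dominates sampling noise; sweep accuracies are
  asserted on cutoffs with at least 500 evaluable entries, since empty
  high-INFO bins have no defined accuracy at desk scale.
* **End-to-end recovery**: the desk preset — one densely genotyped 150-kbp
  locus (2000 sites, 6 founders, `K = 6`), 1744 samples at 0.04×, one
  causal SNP with β = 0.35 at MAF ≈ 0.3. The locus machinery necessarily
  returns a single merged locus on this geometry; multi-block clumping is
  exercised separately in the loci tests. Genomic control is strongly
  inflated in these runs because half the region is in LD with a true
  signal; the calibration of `λ_GC` itself is checked on iid null
  statistics.
* **Calibration**: the score-test type-I experiment uses a 16-founder,
  50-Mbp, weak-LD panel (N = 1000, 2000 sites) so the nominal rate is
  estimated on many effectively independent tests.

## Numerical choices and degenerate inputs

Golden-section tolerance 1e−6 with explicit boundary comparison; χ²(1)
for the boundary LRT (conservative); lexicographic alt-allele tie-break;
lower-genotype argmax tie-break; left-window stitching tie-break;
greedy-by-p selections tie-broken by position; forward-backward
renormalized per grid (scaling-stable); emissions are strictly positive
because error probabilities are bounded away from 0 and 1; empty pileups
return a prior-only model with a warning; monomorphic sites get HWE p = 1
and INFO 1 at `θ̂ ∈ {0,1}`; posterior triples are validated to sum to 1 on
VCF export (4-decimal round-trip).

## Limitations

* The generator omits WGA amplification waveforms, PCR duplicates,
  alignment artifacts, copy-number events, and FASTQ-level realism.
* Sibling relatedness is exploited implicitly by imputation but not
  corrected for in association (no kinship model); with causal sharing it
  also perturbs hard-call Hardy-Weinberg tests, and occasionally removes a
  well-imputed common site.
* Reference-panel seeding of the HMM is omitted (its benefit vanishes for
  the large-cohort regime this targets).
* Haploid/pseudo-haploid modes, chromosome X, indels, and LD-score
  regression are out of scope.
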