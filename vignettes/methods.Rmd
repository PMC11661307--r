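---
title: "Models and methods in snqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in snqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`snqtl` maps genetic regulation of gene expression at cell-type resolution
from single-nucleus RNA-seq: pseudobulk cis-eQTL mapping with single-causal
fine-mapping, empirical-Bayes multivariate shrinkage with a composite
cell-type-specificity test, Bayesian colocalization with disease GWAS,
dynamic (pseudotime-interaction) eQTL detection with a negative-binomial
mixed model, and trans-eQTL mapping with cis-mediation analysis. This
vignette describes the models, their assumptions, the tunable parameters,
and the numerical and design choices, in the order the pipeline runs them.

## The synthetic cohort

Real single-nucleus eQTL cohorts are large (thousands of donors, millions
of nuclei) and access-controlled. The package therefore ships a seeded
generator (`sim_config()`, `simulate_genotypes()`, `make_ground_truth()`,
`simulate_nuclei()`, `simulate_gwas()`) whose output has the statistical
structure the analyses assume, with known ground truth:

* **Genotypes.** Dosages are drawn in Hardy-Weinberg equilibrium at a MAF
  sampled uniformly from `maf_range` (default 0.1-0.5). Two subpopulations
  with shifted allele frequencies (`ancestry_maf_shift`, default 0.1)
  emulate ancestry structure so that the genotype-PC adjustment is
  exercised; an AR(1) haplotype correlation (`ld_rho`, default 0.25) gives
  each gene's variant panel local LD. Genes sit every 3 Mb on two synthetic
  chromosomes, so 1 Mb cis windows never overlap between genes and
  cross-chromosome pairs always satisfy the 5 Mb trans rule without a
  genome build.
* **Counts.** Each nucleus's count for gene $j$ is negative binomial with
  log mean
  $\alpha_j + \delta_{j,c} + \beta_j G + \beta_{t,j}\,t +
  \beta_{gt,j}\,G\,t + u_{j,d} + \mathrm{pool}_{j,p} + \log s_n$,
  dispersion $\theta$ (`nb_dispersion`, default 8; `Inf` gives Poisson) and
  a per-gene donor random intercept $u_{j,d} \sim N(0, \sigma_u^2)$
  (`donor_re_sd`, default 0.3). The library-size factor $s_n$ is log-normal
  with cell-type-specific means, reflecting the fact that detection tracks
  read depth. The number of nuclei a donor contributes to a cell type is
  itself negative-binomial (`nuclei_mean`, `nuclei_size`); the distribution
  of nuclei per donor is not identified by published summaries, so this is
  a documented, configurable default, and donors can contribute zero nuclei
  to a cell type.
* **Pseudotime** is generated directly as donor age scaled to $[0,1]$ plus
  nucleus-level jitter (`pseudotime_jitter`, default 0.15). Trajectory
  inference from the expression itself is out of scope; the dynamic module
  consumes pseudotime as an input, so the generator supplies one anchored
  on age the way supervised maturation trajectories are.
* **Effects.** Sharing patterns (`sharing_pattern()`) assign each gene a
  cis effect active in one cell type (specific), all (shared), a subset, or
  none; the default mix is 30% specific / 20% shared-all / 10%
  shared-subset / 40% null with per-allele log-mean effect 0.5. A fraction
  of non-null genes (`dynamic_fraction`, default 0.15) receives a
  genotype-by-pseudotime interaction (`dynamic_beta`, default 0.8)
  restricted to the gene's active cell types. Mediation chains route
  variant → cis gene → trans gene across chromosomes with path
  coefficients `trans_a` = 0.6 and `trans_b` = 1.0; chains are grouped in
  threes onto a shared source variant so that a trans-regulatory hub
  (≥ 3 targets) exists at desk scale. These chain strengths are chosen so
  that a 200-donor cohort — two orders of magnitude smaller than the
  consortium datasets this design emulates — retains power to clear the
  two-stage Sidak/BH trans correction; with the weaker effects typical of
  real trans signals, detection at this sample size would be essentially
  zero, which is the regime the full-size studies escape only through
  sample size.
* **GWAS.** An independent cohort (default 5,000) with the same allele
  frequencies and LD yields marginal summary statistics for a quantitative
  trait whose causal variants are either the cis causal variant of
  selected genes (`shared`) or a different variant in the same window
  (`distinct`), giving colocalization a positive and a negative control.

What the generator deliberately does **not** emulate: long-range LD and
realistic haplotype structure, ambient RNA and doublets, cell-type
misassignment, batch effects beyond a donor-level pool shift, and
non-linear trajectory effects. Passing tests on this cohort therefore
demonstrate correctness of the estimators under their assumed models, not
robustness to every artefact of real tissue data.

## Pseudobulk construction and normalization

Counts are summed per donor within each cell type (`pb_aggregate()`);
donors without nuclei in a cell type are absent rather than zero-filled,
so downstream sample sizes vary by cell type. `pb_normalize()` fits, per
gene, a Poisson working model with a log library-depth offset and the
requested donor covariates (default: sample pool and mitochondrial
fraction) and emits Pearson residuals, which are then standardized to unit
variance per gene. Two choices deserve note:

* The count model behind the Pearson residual is a per-gene Poisson GLM
  with log-depth offset. Donor-level pseudobulk counts are large and the
  residual is standardized afterwards, so the working-model family has
  little influence; the function is the single place to swap in another
  family.
* Residuals are re-standardized to unit variance per gene before eQTL
  mapping. This puts effect sizes on the standardized-expression scale,
  which is also the scale the fine-mapping and colocalization prior
  (`prior_sd = 0.15`, below) assumes.

Genes nonzero in fewer than `min_donors = 20` donors in a cell type are
dropped there — a practical expression filter, configurable.

Hidden expression factors (technical and biological confounders not in the
covariate list) are estimated as principal components of the normalized
residuals, and the number of factors is chosen by eQTL yield
(`hidden_factor_sweep()`): map cis-eQTLs with the top $f$ components as
covariates for each $f$ in a grid and keep the $f$ with the most eGenes,
ties to the smallest $f$. PCA stands in for more elaborate latent-factor
engines: the selection-by-yield step, which is what matters operationally,
is preserved, and the default demo grid (0, 5, 10) keeps the sweep cheap.
At the generator's defaults the confounding is fully captured by the
modelled covariates, so the sweep typically selects 0 factors — the tests
exercise the non-trivial case by planting an unmodelled batch effect.

## Cis-eQTL mapping

`map_cis()` regresses residual expression on allele dosage for every
variant within 1 Mb of the TSS, with the top 5 genotype PCs (and any
hidden factors) as fixed covariates; p-values are two-sided t-tests.
PC-adjusted OLS is the desk-scale stand-in for a multi-ancestry linear
mixed model: the two-subpopulation simulation exercises exactly the
stratification this adjustment must absorb. Monomorphic variants are
skipped; cell types with fewer than `min_donors = 30` donors are skipped;
lead-variant ties break to the smaller genomic position (deterministic).

eGene calling (`egene_calling()`) Bonferroni-adjusts each gene's lead
p-value by its number of cis variants, then applies Benjamini-Hochberg
across genes within a cell type at FDR 5%. The gene-level correction
inside large eQTL engines is not publicly specified; Bonferroni-then-BH is
a conservative, standard stand-in and is documented as such.

Fine-mapping (`finemap_abf()`) assumes a single causal variant per gene
and uses Wakefield approximate Bayes factors with prior effect SD
$W^{1/2} = 0.15$ on standardized expression, so PIPs are normalized ABFs,
credible sets are PIP-sorted prefixes reaching 95%, and `max_cpp()` gives
each variant its best credible-set PIP across genes. Replication is
summarized by Storey's $\pi_1$ (`storey_pi0()` with the conventional
$\lambda$ grid 0.05-0.95 and a 3-df smoothing spline evaluated at
$\lambda = 0.95$). `ocr_bin_density()` counts functional elements in 10 kb
bins across a 2 Mb window centered on lead variants; an element straddling
a bin boundary counts in every bin it overlaps.

## Multivariate shrinkage and the composite specificity test

Lead-variant effects across cell types are shrunk jointly with an
empirical-Bayes mixture-of-normals model (`fit_prior()`,
`posterior_panel()`): $\hat\beta_j \sim N(\beta_j, S_j)$,
$\beta_j \sim \sum_k w_k N(0, \Sigma_k)$, with canonical covariance
templates (null, identity, per-cell-type singletons, equal effects,
correlated-shared at $\rho = 0.5$) expanded over a geometric scale grid.
Genes untested in a cell type enter with coefficient 0 and SE $10^6$, so
they carry essentially no likelihood and their posterior is driven by
cross-cell-type sharing.

Numerical choices:

* The component log-likelihoods do not depend on the weights, so they are
  computed once (genes sharing an SE row share a Cholesky factorization)
  and the EM reduces to two matrix-vector products per iteration;
  convergence is declared when the penalized log-likelihood gain drops
  below $10^{-6}$.
* The scale grid runs from the **median observed SE** to twice the largest
  observed effect (8 points). Effects smaller than the measurement noise
  are statistically indistinguishable from zero, so they are absorbed by
  the null component rather than by a near-null normal; without this lower
  bound, vanishing-scale components are likelihood-equivalent to the null
  and the EM splits the null mass arbitrarily among them.
* A mild null-biased penalty (Dirichlet weight 10 on the null component,
  the convention of empirical-Bayes shrinkage software) resolves the
  remaining tie in favour of the null.
* Residual errors are treated as independent across cell types (identity
  error correlation); estimating a dense error correlation is out of
  scope. Data-driven (PCA-based) prior covariances are likewise not
  implemented — the canonical set covers the sharing patterns the
  generator can produce.
* The prior is fitted on the lead-variant panel plus a random background
  panel of 2,000 variant-gene pairs (`background_panel()`); consortium
  analyses use hundreds of thousands, and the count scales with data size.

The posterior for each gene is a mixture over components of conjugate
normal posteriors; for singular $\Sigma_k$ the formulas
$\mu_k = \Sigma_k(\Sigma_k + S_j)^{-1}\hat\beta_j$,
$V_k = \Sigma_k - \Sigma_k(\Sigma_k + S_j)^{-1}\Sigma_k$ remain valid and
coordinates with zero prior variance carry a point mass at zero. The local
false sign rate of an entry is
$\mathrm{lfsr} = \min[P(\beta \le 0 \mid \hat\beta), P(\beta \ge 0 \mid
\hat\beta)]$ with point masses counted in both tails, and
$p = 1 - \mathrm{lfsr}$ is a conservative posterior probability that the
effect is non-zero with the estimated sign.

The composite test treats these per-cell-type probabilities as
independent: the probability that a gene's effect is non-zero in every
cell type of set 1 and zero in every cell type of set 2 is
$\prod_{i \in 1} p_i \prod_{i \in 2} (1 - p_i)$ (`composite_specific()`),
and the probability of an effect in at least one member of a family is
$1 - \prod (1 - p_i)$ (`composite_any()`). The independence assumption is
taken as given — no joint-posterior correction is attempted — which makes
the arrangement probabilities exactly complementary: summed over all $2^C$
disjoint arrangements they equal 1, a property the tests verify by
enumeration. `specificity_scan()` evaluates every single-cell-type
arrangement (and any requested family) per gene and reports the **maximum**
over arrangements, calling a gene specific when that maximum exceeds 0.5;
maximizing per gene (rather than thresholding each arrangement
independently) is the unambiguous reading we adopted and document here.

## Colocalization

`coloc_abf()` implements pairwise Bayesian colocalization over a shared
variant window: Wakefield log-ABFs per trait (same $W = 0.15^2$ prior,
traits standardized to unit variance), hypothesis sums over single-causal
configurations (H0 none, H1/H2 one trait, H3 two distinct variants, H4 one
shared variant), priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. All
configuration sums use log-sum-exp, so $|z|$ far above 30 cannot overflow.
With fewer than two variants H3 is undefined; the result is computed and
flagged `degenerate`. `harmonize()` intersects panels on position, flips
signs for swapped alleles, and drops strand-ambiguous (A/T, C/G) variants.
`coloc_scan()` applies this per gene and cell type over the cis window and
reports PP4 against the 0.5 and 0.8 conventions.

## Dynamic eQTLs

`fit_nb_glmm()` models per-nucleus counts of one gene in one cell type as
negative binomial with log mean linear in pseudotime, dosage and their
interaction, fixed covariates age, sex and mitochondrial rate, a per-donor
random intercept for the repeated nuclei of each donor, and the nucleus
library size as a **log offset** by default. The offset is the standard
count-model convention; `libsize_as_covariate = TRUE` estimates a free
coefficient instead for fidelity with descriptions that list library size
among the covariates. The Wald z-test on the interaction coefficient is
the dynamic-eQTL test. Fitting uses Laplace-approximate ML via `glmmTMB`
(dispersion estimated per gene, matching the behaviour of per-gene
`glmer.nb` fits); pseudotime is already on $[0,1]$, which keeps the
interaction well scaled.

Boundary handling: when the fitted donor variance is near zero the profile
likelihood is flat down to the boundary and the optimizer can stop at a
small spurious variance that perturbs every coefficient at the $10^{-2}$
level. Following the singular-fit convention, a variance component (donor
variance; then inverse dispersion) is set to its boundary when the
likelihood ratio against the boundary is below the 5% critical value of
the boundary-corrected null ($0.5\chi^2_0 + 0.5\chi^2_1$, i.e.
$2\Delta\ell < 2.71$), so data simulated in the Poisson limit collapse
cleanly to a Poisson GLM while genuinely supported components (donor SD
0.3 gives likelihood ratios in the hundreds) are never touched.

`dynamic_scan()` fits the model at each (gene, cell type) lead variant and
applies BH within cell type at FDR 5%; non-converged fits are flagged, not
dropped. Scanning lead variants only (rather than every cis variant) is a
deliberate scope choice: the lead is the best-supported regulatory signal
per gene and keeps the per-gene cost to one mixed-model fit.
`coloc_enrichment()` compares the overlap of dynamic eGenes with
colocalized genes against 100 rounds of size-matched random draws from the
gene universe, reporting the fold enrichment and the resampling SE; the
null mean agrees with the hypergeometric expectation, which the tests
check in closed form.

## Trans-eQTLs and mediation

`map_trans()` tests candidate variants (cis-eSNPs plus GWAS-significant
variants — an input list, since the real candidate sets are data-bound)
against all genes more than 5 Mb away or on another chromosome, with the
same PC covariates as cis mapping. Genes with mappability below 0.8 are
excluded, as are candidate variants inside the configured MHC interval
(default `chr6:25000000-34000000` on the human reference; the synthetic
chromosomes use the flag only through tests). Correction is two-stage:
per gene, the Sidak correction $1 - (1 - \min p)^k$ with $k = 10^5$ fixed
by convention rather than the realized test count (`--sidak-k`
overridable), computed via `log1p`/`expm1` so minima near $10^{-12}$
survive; then BH across all genes and cell types at FDR 5%
(`trans_significance()`). `find_hubs()` groups significant pairs by
(variant, cell type) and reports variants with at least three targets.

Mediation (`mediate()`) restricts to trans-eSNPs in LD $r^2 \ge 0.75$
(computed from the study genotypes — a reference panel would be used only
when study genotypes are unavailable) with the lead cis variant of a
candidate mediator gene within 1 Mb. The indirect effect is the product of
coefficients $a b$ ($a$: SNP on mediator expression; $b$: mediator on
trans gene adjusting for the SNP) with the Sobel standard error
$\sqrt{b^2 SE_a^2 + a^2 SE_b^2}$ — the standard product-of-coefficients
form; more elaborate estimators are out of scope. BH controls the FDR
across mediation tests and Storey's $\pi_1$ over the mediation p-values
estimates the overall mediated fraction.

## Pipeline, determinism, and problem sizes

`run_pipeline()` wires the ten stages in dependency order, derives every
stage's seed deterministically from the global seed and the stage name,
writes each output table with a header line naming the producing stage and
the configuration hash, and records seeds and row counts in a JSON
manifest; two runs with the same configuration produce identical manifests
up to the timestamp. A stage whose dependency is disabled fails fast
naming the missing stage. The demo configuration — 200 donors, 100 genes,
25 variants per gene, 5 cell types, roughly 10,000 nuclei, a 5,000-sample
GWAS cohort, 12 dynamic-model fits — runs in about a minute and is the
scale at which all distributional checks in the test suite were
calibrated; the dynamic-calibration simulation uses 100 donors with ~12
nuclei per donor and 500 genes, a size at which the interaction Wald test
is demonstrably near-nominal. A thin command-line wrapper
(`inst/cli/snqtl.R`) exposes `simulate` and `run-all` (with `--stages`
subsetting) over these functions.

## Known limitations

* The single-causal-variant assumption in fine-mapping and colocalization
  ignores allelic heterogeneity; multi-signal extensions are out of scope.
* The composite test's independence assumption makes its probabilities
  exact as a transformation of the per-cell-type posteriors, but those
  posteriors share the fitted prior, so the probabilities are conservative
  summaries rather than calibrated joint posteriors.
* PC-adjusted OLS handles discrete population structure well but not
  cryptic relatedness; a mixed model would be needed for family data.
* The Wald test of the dynamic interaction is asymptotic in the number of
  donors; below roughly 100 donors it runs warm (the calibration
  simulations document the operating characteristics at 100).
* Trans-eQTL power at desk scale exists only because the generator plants
  strong chains; real trans architectures need consortium-scale cohorts.
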