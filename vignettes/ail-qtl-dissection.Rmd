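---
title: "Dissecting a polygenic QTL region in an advanced intercross line"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a polygenic QTL region in an advanced intercross line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ailqtl)
```

## The problem

A single strong QTL peak often hides a composite of linked functional
alleles, haplotype effects and epistatic interactions. This package
implements the analysis toolkit for dissecting such a region in a
multigenerational advanced intercross line (AIL): a pedigree founded by
crossing two divergently selected lines (here, high- and low-body-weight
chicken lines) and then intercrossed for many generations so that
accumulated recombination sharpens mapping resolution. The phenotype
throughout is 8-week body weight (grams), and the analyses are designed for
cohorts of roughly 3,000 phenotyped birds genotyped at a dense
single-chromosome marker panel.

Five complementary views of the region are provided:

1. **Mean-effect association (GWAS).** Per marker $j$, ordinary least
   squares of $y = \mu\mathbf{1} + S\beta_S + g\beta_g + A_j a_j +
   \varepsilon$, where $S$ is a male indicator, $g$ a generation factor and
   $A_j$ the count of alternative alleles. Conditional scans add previously
   selected markers as covariates to test whether peaks are statistically
   independent.
2. **Variance-heterogeneity association (vGWAS).** The Brown-Forsythe test:
   within each genotype class the absolute deviation from the class median,
   $y^*_{ij} = |y_{ij} - \varphi_j|$, is analyzed by one-way ANOVA. Loci
   whose genotype classes differ in *spread* rather than mean are candidate
   participants in epistasis or carriers of multiple linked functional
   alleles.
3. **Haplotype and ancestry-class association.** Haplotype blocks are
   detected by the D′ confidence-interval rule; within a block, haplotype
   dosages (0/1/2 copies of each non-reference haplotype) replace the
   single-marker dosage in the same fixed-effects model, with a joint F test.
   Externally produced ancestry (donor-breed) labels can be substituted for
   haplotype labels to exploit historical recombination.
4. **NOIA epistasis decomposition.** The natural and orthogonal interactions
   model builds, from observed genotype-class frequencies
   $(p_{11}, p_{12}, p_{22})$, additive and dominance contrasts that are
   orthogonal under those frequencies, plus Kronecker-product interaction
   columns (aa, ad, da, dd) for marker pairs. Orthogonality makes estimates
   invariant to model reduction, and the intercept is the reference point
   $R = p_{11}G_{11} + p_{12}G_{12} + p_{22}G_{22}$.
5. **Candidate prioritization.** Association strength is combined with
   minor-allele frequency, a top-percentile conservation (PhyloP) filter and
   sequence-ontology categories parsed from the VCF `ANN` field.

A configurable simulator generates synthetic AIL cohorts with known truth
for all of these signal types, and every statistical routine is validated
against independent oracles on such data.

## Model details and conventions

**Genotype coding.** Calls are counts of the alternative allele
$\{0, 1, 2\}$ taken from the VCF REF/ALT, never re-polarized by frequency.
Only biallelic SNPs are analyzed; indels and multi-allelic records are
skipped and counted. Missing calls propagate as `NA` with case-wise
deletion per marker; no imputation is performed (imputed input is expected
where relevant).

**Covariates.** Sex enters as a binary indicator and generation as an
unordered factor, following the fixed-effects model above. For vGWAS and
NOIA the phenotype is instead normalized once per cohort: a z-score within
each (sex, generation) cell using the sample SD, which removes those fixed
effects exactly. Normalization requires at least two phenotyped birds and a
positive SD per cell and fails loudly otherwise.

**Degenerate fits.** Noise-free fits (zero residual variance) are reported
with `p = 0` and an explicit `degenerate` flag rather than erroring, so
exact recovery tests are expressible. Collinear designs (a marker
conditioned on itself or a perfect-LD proxy) flag `rank_deficient` with
undefined effect. Brown-Forsythe classes below `min_class_n` (default 10)
are dropped with the degrees of freedom adjusted; a test where all
deviations are constant reports F = 0, p = 1, `degenerate`.

**Stepwise selection** alternates forward selection (best p below
`alpha_in`) and backward elimination (worst p above `alpha_out`), both
defaulting to 0.05, with ties broken by smaller p then lower map position;
sex and generation are always retained. An AIC mode is available because
the threshold criterion is a genuinely open choice — published tables of
this kind have retained markers at p ≈ 0.10, which a pure 0.05 rule would
drop. The reported ANOVA is sequential (type I) with a single residual mean
square, matching how such tables print one residual line.

**LSD letters.** Pairwise comparisons use the pooled within-group variance
$\sum (n_i - 1) s_i^2 / \sum (n_i - 1)$ and $t$ statistics with
$\sum (n_i - 1)$ degrees of freedom. The compact letter display is computed
by insert-and-absorb, whose resulting partition is invariant to group input
order; letter *names* follow input order (first group's class is "a"), the
convention used when such tables are printed genotype-by-genotype.

**Haplotype blocks.** A pair is in strong LD when the likelihood-profile
confidence interval of D′ has lower bound ≥ 0.70 and upper bound ≥ 0.98;
strong recombination evidence is an upper bound < 0.90. A candidate run of
markers is a block when its end pair is strong and ≥ 95% of its informative
pairs are strong; non-overlapping blocks are taken greedily, longest first.
Markers below 5% MAF are excluded from block building; haplotypes rarer
than 1% are pooled into `OTHER`. These thresholds are exposed because the
defaults of the original toolkits vary between versions. Block detection
requires phased input (from the simulator or an upstream phasing/imputation
step); statistical phasing is deliberately out of scope.

**NOIA numerics.** The single-locus additive contrast is
$x_a(g) = g - (p_{12} + 2p_{22})$ and the dominance contrast
$(-2p_{12}p_{22},\; 4p_{11}p_{22},\; -2p_{11}p_{12}) /
(p_{11} + p_{22} - (p_{11} - p_{22})^2)$; both are orthogonal to each other
and to the mean under the observed frequencies (checked to $10^{-12}$ in
the tests). When the dominance denominator vanishes (a genotype class
absent) the design degrades to additive-only with a flag. Observed sample
frequencies — not Hardy-Weinberg expectations — parameterize the design, so
single-locus in-sample orthogonality is exact. Two-locus interaction
columns are products of the marginal contrasts, i.e. orthogonal under the
*product* of marginal frequencies (a linkage-equilibrium reference). When
the two loci are in LD the joint in-sample Gram matrix is not exactly
diagonal; consequently the reference point equals the sample mean of the
normalized phenotype exactly for single-locus fits and only approximately
for linked pairs. This deviation is inherent to the orthogonal
parameterization and is left as a diagnostic rather than corrected. Empty
joint-genotype cells make interaction columns collinear; the affected
effects are flagged inestimable.

**Conditional (stratified) scans** split the cohort by genotype at a
conditioning marker and rescan each stratum. Because the phenotype is
already normalized within sex-generation cells, the within-stratum model is
intercept-plus-marker by default; `refit_covariates = TRUE` refits sex and
generation inside each stratum for users who prefer that. Strata below
`min_class_n = 10` are omitted with a flag. The accompanying 3×3 grid of
(mean, SD, count) against a focal marker is the summary used to visualize
masking epistasis, where a focal signal present in some strata vanishes in
another.

**Prioritization.** The conservation threshold is the nearest-rank top-`q`
value (default top 5%) computed over the analyzed region's markers by
default; an explicit genome-wide threshold can be supplied instead, since
which universe the percentile refers to is ambiguous in practice. MAF is
computed from analysis-cohort genotypes when available, in preference to
annotation-file frequencies. The filter keeps MAF > 0.1 and conservation at
or above the threshold, sorted by association p with positional
tie-breaks.

## The simulator: what it emulates and what it does not

`sim_config()` defaults define the study conditions: two founder lines of
20 birds each with alternative-allele frequencies drawn independently per
line from Uniform(0.05, 0.95) (divergent at many markers, shared at
others), an F1 of 40, intercross generations F2–F18 of 175 birds each
(~2,975 phenotyped; founders and F1 are not phenotyped), and 2,000 markers
evenly spaced on one 100-cM chromosome. Meiosis follows the Haldane model
(Poisson crossovers, no interference); mating is random within generation
with full-sib avoidance and no selection after the founders. Phenotypes are
built from an intercept of 850 g, a male effect of 120 g, a mild +2
g/generation trend (so the generation covariate is non-degenerate), any
configured additive/dominance effects, explicit 3×3 epistatic genotype-value
grids (the most general two-locus specification, from which NOIA ground
truth is derivable), variance-heterogeneity loci as multipliers on a 90 g
residual SD, and Gaussian noise.

The simulator reproduces the *statistical structure* the methods target —
LD that decays with map distance and generation, Mendelian-consistent
pedigrees, divergent founder haplotypes, mean and variance effects,
masking epistasis. It does not emulate sequencing (coverage, imputation
error), selection within the AIL, crossover interference, or real
linkage-map irregularities. Passing tests therefore demonstrate
correctness and calibration of the estimators under a clean AIL design,
not robustness to imputation artifacts.

## Validation strategy and problem sizes

The test suite validates every estimator against an independent oracle:
the association model against explicit normal-equations algebra, the
Brown-Forsythe test against a textbook Levene-with-median implementation,
the NOIA design against closed-form solutions of the orthogonality
constraints, and block finding against exhaustive application of the pair
rules on small panels.

Statistical guarantees are measured on simulated cohorts at chosen sizes:
type-I error of both scans on a null cohort at the full default scale
(2,000 markers, ~3,000 birds), averaged over 40 independent phenotype
redraws because LD among the 2,000 markers makes a single panel's
rejection fraction highly variable while per-marker p-values remain exactly
uniform given the panel; additive-effect recovery over 500 replicates at
n = 400; NOIA (a, d, aa) recovery over 300 replicates at n = 3,000 with
per-replicate truth obtained by exactly decomposing the generating
genotype-value grid at the realized genotype frequencies; haplotype-effect
recovery over 200 replicates at n = 400; vGWAS power for a
(1, 1, 2)-multiplier variance locus at n ≈ 3,000 over 100 phenotype
redraws on a 100-marker panel; and one masking-epistasis cohort (~2,250
birds) for the stratified-scan pattern. These sizes are the package's
standing choices for a reproducible desk-scale validation.

## Known limitations

- Fixed-effects OLS only: no kinship/mixed-model correction, consistent
  with the intended AIL design where generation structure is modeled
  explicitly. Residual relatedness within generations is ignored.
- No statistical phasing; haplotype analyses require phased input.
- NOIA is limited to second-order interactions and the statistical
  (frequency-adjusted) parameterization; the functional parameterization is
  not implemented.
- Scans report raw p-values; a Bonferroni column is emitted for interaction
  networks but no multiplicity filtering is applied anywhere.
- The D′ confidence interval uses a profile-likelihood grid with allele
  frequencies fixed at their estimates, the standard construction for
  block-building; it is not a full joint interval.
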