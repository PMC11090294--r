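# ailqtl

Dissection of polygenic QTL regions in advanced intercross lines (AILs).

A strong association peak is often not one signal: linked functional
alleles, haplotype effects and epistasis can hide behind a single additive
scan. `ailqtl` provides the toolkit used to take such a region apart in a
multigenerational intercross of two divergently selected lines — the
motivating system is the chicken *Growth1* body-weight QTL on chromosome 1,
mapped in the Virginia high/low body-weight selection lines with ~3,000
phenotyped birds from intercross generations F2–F18. It is aimed at
quantitative geneticists analyzing experimental crosses.

## What it computes

For phenotype *y* (8-week body weight, grams), sex indicator *S*,
generation factor *g* and marker dosage *A<sub>j</sub>* (count of
alternative alleles):

- **GWAS** — per-marker OLS of
  *y = 1μ + Sβ<sub>S</sub> + gβ<sub>g</sub> + A<sub>j</sub>a<sub>j</sub> + ε*,
  plus conditional scans (selected markers as covariates), stepwise marker
  selection, sequential ANOVA tables, per-genotype summaries and compact
  LSD letter displays.
- **vGWAS** — the Brown-Forsythe variance-heterogeneity test: one-way ANOVA
  of |y − class median| across genotype classes, on phenotypes normalized
  within sex-generation cells.
- **Haplotype association** — D′ confidence-interval block detection,
  haplotype-dosage regression with a joint F test, and the same model over
  externally supplied ancestry (donor-breed) labels.
- **NOIA epistasis** — the natural and orthogonal interactions model with
  frequency-adjusted additive/dominance contrasts, Kronecker two-locus
  interaction columns (aa, ad, da, dd), pairwise interaction networks, and
  genotype-stratified conditional scans for masking epistasis.
- **Prioritization** — candidate filtering by minor-allele frequency,
  top-percentile conservation (PhyloP) and sequence-ontology category
  (`ANN` field), sorted by association p-value.
- **AIL simulator** — divergent founder lines, Haldane meiosis over a
  centimorgan map, random intercross mating, and trait architectures with
  additive, dominance, epistatic-grid and variance-heterogeneity effects;
  exports phased VCF plus phenotype/pedigree/truth tables.

Standard formats are handled by established packages (VCF via `vcfR`);
genotypes are alternative-allele counts in an `ail_geno` container with a
marker map and optional phase.

## Worked example

Simulate a cohort (~1,350 phenotyped birds, 300 markers on 100 cM) with an
additive QTL at `m0080` whose effect is masked in alternative-allele
homozygotes of a variance-heterogeneity hub at `m0220`:

```r
library(ailqtl)
cfg <- sim_config(
  seed = 101, n_founders_per_line = 15, n_f1 = 30,
  n_per_generation = setNames(rep(150L, 9), 2:10),
  n_markers = 300, chrom_length_cm = 100,
  architecture = trait_architecture(
    additive = c(m0080 = -25),
    epistatic_pairs = list(list(markers = c("m0220", "m0080"),
                                grid = rbind(c(0, -20, -40),
                                             c(0, -20, -40),
                                             c(0, 0, 0)))),
    vqtl = list(m0220 = c(1, 1, 1.6)),
    residual_sd = 80))
sim <- simulate_ail(cfg)
ph  <- subset(sim$samples, generation >= 2)

scan <- gwas_scan(ph$bw8, ph, sim$geno)
head(scan[order(scan$pvalue), c("marker_id","pos","effect","se","neglog10p")], 3)
#>    marker_id     pos effect   se neglog10p
#> 80     m0080 1200000  -42.8 3.57      30.8
#> 84     m0084 1260000  -26.8 3.61      12.7
#> 77     m0077 1155000   27.7 4.19      10.3
```

The mean-effect scan localizes `m0080` (estimated −42.8 g per allele: the
−25 g additive term plus the masked epistatic contribution). The
variance scan finds the hub, which carries no mean effect:

```r
yn <- normalize_by_group(ph)
vscan <- vgwas_scan(yn, ph, sim$geno)
head(vscan[order(vscan$pvalue), c("marker_id","pos","f_bf","neglog10p")], 3)
#>     marker_id     pos  f_bf neglog10p
#> 220     m0220 3300000 24.99     10.66
#> 232     m0232 3480000 15.79      6.78
#> 215     m0215 3225000  7.61      3.29
```

Stratifying by hub genotype shows the masking pattern — the focal signal is
strong in carriers of at least one reference allele and gone in
alternative-allele homozygotes:

```r
cs <- conditional_scan(yn, ph, sim$geno, "m0220", scan_markers = "m0080")
#> stratum 0 : -log10 p at m0080 = 14.1
#> stratum 1 : -log10 p at m0080 = 25.06
#> stratum 2 : -log10 p at m0080 = 1.46
```

Per-genotype summaries with LSD letters (groups sharing a letter do not
differ at α = 0.05):

```r
gs <- genotype_group_summary(yn, ph, sim$geno, "m0080")
gs$letter <- lsd_letters(gs)
gs
#>   genotype   mean   sd count letter
#> 1       RR  0.484 0.90   314      a
#> 2       RA -0.024 0.97   686      b
#> 3       AA -0.387 0.94   350      c
```

See the vignette (`vignettes/ail-qtl-dissection.Rmd`) for the models,
conventions and validation strategy.

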