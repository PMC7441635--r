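# xkin — expected and realized relationship matrices for the X chromosome

X-linked loci break the assumptions behind the standard tools of
quantitative genetics. Males are hemizygous: they receive their single X
from their dam and transmit it intact — no recombination, no Mendelian
sampling — to every daughter and to no son. A pedigree numerator matrix
**A** or an autosomal genomic relationship matrix (GRM) therefore
misstates covariances between relatives at X-specific loci: a sire and
his son share *nothing* on the X, two full sisters share 0.75 instead of
0.5, and a male's relationship with himself is 0.5, not 1.

`xkin` is for quantitative geneticists and breeders who want to model the
X properly — to estimate its contribution to trait variance, run
(SS)GBLUP-style predictions that include X markers, or QC genotype /
pedigree data. It provides, as matched S4 objects with accessors:

* **S** — the pedigree-based X relationship matrix (Fernando–Grossman
  recursion), its sparse inverse, a `{0,k}` male-coding rescaling, and a
  metafounder variant **S**^γ for unknown base populations
  (`buildS`, `buildSInverse`, `rescaleS`, `buildSMetafounders`);
* **G**^X — the genomic matrix from sex-aware gene content (0/1 males,
  0/1/2 females), centered by *p*/2*p*, divided by 2Σ*pq*, with explicit
  dosage-compensation scaling *k* and a rare-allele-weighted variant
  (`buildGX`, `buildGAuto`, `estimateAlleleFreqX`);
* **H**^X — the single-step matrix combining genotyped and ungenotyped
  individuals, its sparse-plus-correction inverse, gene-content
  prediction for ungenotyped individuals, and moment-matched blending
  `αS + βG^X` to restore positive definiteness
  (`buildHX`, `buildHXInverse`, `predictGeneContent`, `blendGRM`);
* **P**^r — expected relationships for pseudo-autosomal (PAR) loci,
  which vary with the male genetic distance *r* to the pseudo-autosomal
  boundary because sires transmit the Y-side haplotype to sons and the
  X-side haplotype to daughters with probability 1−*r* (`buildPPar`);
* REML machinery — exact profile REML for the heritability of gene
  content (≈ 1 under the correct matrix: a sharp QC statistic;
  `remlSingleKinship`, `h2Scan`) and bivariate (male-trait /
  female-trait) REML that *estimates* the dosage-compensation factor
  *k* = √(2σ²ₘ/σ²f) instead of assuming it
  (`bivariateReml`, `solveK`, `snpBlup`);
* diagnostics — correlation rescaling, relationship-class summaries,
  matrix–matrix correlations, SVD dimensionality, high-relationship
  proportions (`toCorrelation`, `classifyPairs`, `classSummary`,
  `matrixCorrelation`, `svdDimensionality`,
  `highRelationshipProportions`);
* a gene-dropping simulator (`simulatePedigree`, `geneDropX`,
  `geneDropPar`, `geneDropAutosome`, `simulatePhenotypes`,
  `transmissionProfile`) that serves as the Monte-Carlo oracle for every
  formula above: the empirical covariance of gene content over many
  dropped loci must equal (matrix × 2*pq*) entrywise.

A thin command-line interface (`exec/xkin`) exposes the main operations
(`make-s`, `make-gx`, `make-h`, `h2-gene-content`, `estimate-k`,
`simulate`, ...) for shell pipelines.

## Worked example

```r
library(xkin)

ped <- preparePedigree(data.frame(
  id   = c("sire", "dam", "son", "dau1", "dau2"),
  sire = c(0, 0, "sire", "sire", "sire"),
  dam  = c(0, 0, "dam",  "dam",  "dam"),
  sex  = c("M", "F", "M", "F", "F")))

round(relValues(buildS(ped)), 2)
#>      sire dam  son dau1 dau2
#> sire  0.5 0.0 0.00 0.50 0.50
#> dam   0.0 1.0 0.50 0.50 0.50
#> son   0.0 0.5 0.50 0.25 0.25
#> dau1  0.5 0.5 0.25 1.00 0.75
#> dau2  0.5 0.5 0.25 0.75 1.00
```

Sire and son: 0. Male diagonals: 0.5. Full sisters: 0.75 (they share the
sire's X automatically). On the correlation scale
(`toCorrelation`), dam/son becomes 0.5/√0.5 = 0.71 and the full-sister
pair stays 0.75:

```r
round(relValues(toCorrelation(buildS(ped))), 2)
#>      sire  dam  son dau1 dau2
#> sire 1.00 0.00 0.00 0.71 0.71
#> dam  0.00 1.00 0.71 0.50 0.50
#> son  0.00 0.71 1.00 0.35 0.35
#> dau1 0.71 0.50 0.35 1.00 0.75
#> dau2 0.71 0.50 0.35 0.75 1.00
```

The heritability of gene content shows why the distinction matters.
Gene-drop 30 X loci through a 4-generation pedigree (200 individuals) and
fit each locus's gene content as a trait, once with **S** and once with
**A**:

```r
cfg  <- simConfig(generations = 4, nMales = 6, nFemales = 44,
                  nLoci = 30, p = 0.3, seed = 42)
ped2 <- simulatePedigree(cfg)
drop <- geneDropX(ped2, cfg)

attr(h2Scan(drop$genotypes, buildS(ped2)), "summary")
#>   nLoci    meanH2     minH2 nBelow095 nBelow099
#> 1    30 0.9874788 0.9506877         0        14
attr(h2Scan(drop$genotypes, buildA(ped2)), "summary")
#>   nLoci    meanH2     minH2 nBelow095 nBelow099
#> 1    30 0.9346081 0.7959547        19        25
```

Under **S** every locus estimates ≈ 1 (mean 0.987, none below 0.95): the
matrix describes X covariances exactly, so gene content is a trait of
heritability 1. Under **A** the mean drops to 0.935 with 19 of 30 loci
below 0.95 — the autosomal matrix cannot describe X inheritance. This is
the package's core claim in one screen: **S** and **G**^X^ are the
compatible pair for the X, and can be merged into **H**^X^ for
single-step applications.

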