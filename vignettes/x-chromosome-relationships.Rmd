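---
title: "Relationship matrices for the X chromosome: models, choices and limits"
author: "xkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relationship matrices for the X chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xkin)
```

## The problem

X-linked loci do not follow autosomal inheritance: males are hemizygous,
receive their single X from their dam, and pass it intact (no
recombination, no Mendelian sampling) to every daughter and to no son.
Standard pedigree relationship matrices (the numerator matrix **A**) and
standard genomic relationship matrices therefore misdescribe covariances
between relatives at X-specific loci. `xkin` implements the matched pair
of expected and realized relationship matrices for the X — the
pedigree-based **S** and the marker-based **G**^X^ — together with the
machinery that combines them: the single-step matrix **H**^X^, the
metafounder variant **S**^γ^, the pseudo-autosomal matrix **P**^r^, REML
estimation of the heritability of gene content (a quality-control
statistic), and bivariate REML estimation of the dosage-compensation
factor *k*.

## Gene content and the S matrix

Gene content at a biallelic X-specific locus is coded 0/1 in males and
0/1/2 in females — the number of biological copies of the reference
allele. With allele frequency $p$ ($q = 1-p$), gene-content variance is
$pq$ in males and $2pq$ in females. On a pedigree, the covariance of gene
content between individuals is $\mathrm{Var}(\mathbf{m}) = \mathbf{S}\,2pq$
where **S** follows the X-specific recursion:

* male $i$ with dam $d$: $S_{ix} = \tfrac12 S_{dx}$, diagonal $S_{ii} = \tfrac12$
  always (no sire contribution);
* female $i$ with sire $s$, dam $d$: $S_{ix} = S_{sx} + \tfrac12 S_{dx}$,
  diagonal $S_{ii} = 1 + S_{sd}$;
* unknown parents contribute 0 (base males 0.5, base females 1 on the
  diagonal).

Hallmarks worth remembering: a sire and his son have relationship 0; a
dam and her son 0.5 (correlation $0.5/\sqrt{0.5} \approx 0.71$); two full
sisters 0.75; two full brothers equal two maternal half-brothers at 0.25.
`toCorrelation()` rescales any relationship matrix by
$\sqrt{\smash[b]{m_{ii} m_{jj}}}$ so that males (diagonal 0.5) and
females (diagonal 1) are comparable.

The sparse inverse accumulates per-individual contributions with
regression coefficients 0.5 on the dam (males) or (1, 0.5) on sire and
dam (females) and Mendelian-sampling variance
$v_i = S_{ii} - \mathbf{b}'\mathbf{S}_{pp}\mathbf{b}$
(equal to $0.5 - 0.25\,S_{dd}$ for both sexes with known parents), giving
at most 9 stored triplets per individual.

## The genomic matrix G^X^ and dosage compensation

Centered gene content $\mathbf{Z}$ subtracts $p$ from male and $2p$ from
female genotypes; then

$$\mathbf{G}^X = \frac{\mathbf{Z}\mathbf{Z}'}{2\sum_j p_j q_j},$$

which refers all relationships to the genetic variance of an ideal female
population. Under the generating ("base") frequencies the male diagonal
averages 0.5, the female diagonal 1 and the overall mean 0, matching
**S**. Sample frequencies (the only option with real data) shrink
relationships slightly downward; the package exposes sample, base, and
fixed-0.5 frequency sources and never mixes the centering and denominator
vectors. A per-locus $2p_jq_j$ weighting variant (more weight to rare
alleles) is available with `weighted = TRUE`.

Dosage compensation scales male allelic effects by a factor $k$ relative
to females: $k = 1$ (none), $k = \sqrt2$ (equal genotypic variance across
sexes), $k = 2$ (full compensation: equal means, doubled male variance).
`buildGX(..., k = )` folds any $k$ into the male rows. Instead of
assuming $k$, `bivariateReml()` estimates it: phenotypes of the two sexes
are treated as two traits with genetic covariance
$\Sigma \circ \mathbf{G}^X$ (per-sex intercepts and residuals), and under
a cross-sex genetic correlation of 1,
$\Sigma = \sigma^2_u\begin{pmatrix} k^2/2 & k/\sqrt2 \\ k/\sqrt2 & 1 \end{pmatrix}$,
so `solveK()` returns $k = \sqrt{2\sigma^2_m/\sigma^2_f}$ and flags
consistency with the covariance-based readout
$\sqrt2\,\sigma_{mf}/\sigma^2_f$. The components are reported on the
variance-equalized GRM scale (male blocks multiplied by $\sqrt2$ per male
so each sex's diagonal averages 1); this is the scale on which the
$k^2/2$ structure holds — on the raw-G component scale the variance ratio
returns $k\sqrt2$ instead of $k$.

Two genuinely open design points were settled as follows. The restricted
likelihood is maximized directly (Nelder–Mead over a Cholesky
parameterization of $\Sigma$, which enforces positive semidefiniteness,
plus log residual variances) rather than by EM/AI iterations: the
likelihood is evaluated exactly through a low-rank Woodbury
representation built on a pivoted Cholesky factor of **G**^X^, each
evaluation costing $O(r^3)$ with $r = \mathrm{rank}(\mathbf{G}^X)$, and
the result is deterministic given data and starting values (half the
phenotypic variance per component, zero covariance). Second, for
sex-specific traits the module refuses to estimate $k$: with phenotypes
in one sex only, $k$ (equivalently the male coding) is irrelevant.

`snpBlup()` provides the equivalent marker-effect model (ridge solution
of the mixed-model equations with male design rows scaled by $k$); its
fitted genotypic values match GBLUP with `buildGX(k)` at the matched
variance ratio, a property the tests verify to 1e-6.

## Heritability of gene content

Treating gene content itself as a trait with covariance
$\mathbf{S}\,2pq$ gives a sharp quality-control statistic: fitted with
the *correct* relationship matrix, the heritability of gene content is 1;
fitted with **A** it is systematically lower, because **A** misstates X
covariances. `remlSingleKinship()` fits the one-kinship-plus-identity
model by an exact 1-D profile search over the variance ratio on the log
scale in $[10^{-6}, 10^6]$ after a single eigendecomposition — no
iterative convergence tuning; boundary optima are flagged but are genuine
restricted-likelihood maxima (the gene-content model has essentially zero
residual variance). `h2Scan()` applies it per locus with MAF filtering
computed on the analyzed subset, which matters for males-only runs.

At the problem sizes used in the tests (a 5-generation, 400-individual
pedigree, 50 gene-dropped loci), the mean estimate under **S** is ≈ 0.995
with every locus above 0.95; under **A** estimates are systematically
lower, though REML sampling noise at this sample size can invert the
ordering at isolated loci by ~0.01 — the tests therefore assert the
systematic gap (≥ 95% of loci strictly lower, no inversion beyond 0.02)
rather than a literal per-locus inequality. Recoding males {0,1}→{0,2}
without touching **S** degrades the fit; rescaling **S** (male-male block
× $k^2$, male-female × $k$, `rescaleS()`) restores it.

## Single step: combining S and G^X^

With individuals split into ungenotyped (1) and genotyped (2), centered
gene content of ungenotyped individuals is predicted as
$\hat{\mathbf{z}}_1 = \mathbf{S}_{12}\mathbf{S}_{22}^{-1}\mathbf{z}_2$
with conditional variance
$(\mathbf{S}_{11} - \mathbf{S}_{12}\mathbf{S}_{22}^{-1}\mathbf{S}_{21})2pq$,
and the single-step matrix assembles as

$$\mathbf{H}^X = \begin{pmatrix}
\mathbf{S}_{11} - \mathbf{S}_{12}\mathbf{S}_{22}^{-1}\mathbf{S}_{21}
 + \mathbf{S}_{12}\mathbf{S}_{22}^{-1}\mathbf{G}^X\mathbf{S}_{22}^{-1}\mathbf{S}_{21}
 & \mathbf{S}_{12}\mathbf{S}_{22}^{-1}\mathbf{G}^X \\
\mathbf{G}^X\mathbf{S}_{22}^{-1}\mathbf{S}_{21} & \mathbf{G}^X
\end{pmatrix},\qquad
(\mathbf{H}^X)^{-1} = \mathbf{S}^{-1} +
\begin{pmatrix} 0 & 0 \\ 0 & (\mathbf{G}^X)^{-1} - \mathbf{S}_{22}^{-1}\end{pmatrix}.$$

**G**^X^ is frequently rank deficient — individuals sharing an entire X
are common because males carry one copy transmitted without
recombination — so the inverse requires blending first. `blendGRM()`
first puts both matrices on the variance-equalized scale (male blocks ×
$\sqrt2$ per male), moves **G**^X^ by the exact two-equation linear
adjustment $a + b\,\mathbf{G}$ that matches its mean diagonal and overall
mean to those of **S** (an exact solve, not a least-squares fit over
entries — deterministic and reproducing the moment-matching intent), then
forms $\alpha\mathbf{S} + \beta\mathbf{G}^{X*}$ with $\beta = 1-\alpha$
by default (both weights are exposed since the convexity constraint is a
choice, not a law) and transforms back. $\alpha$ of 0.05–0.10 restores
positive definiteness on all simulator presets. A condition number above
1e10 makes `buildHXInverse()` refuse the genotyped block as numerically
singular.

## The pseudo-autosomal region

PAR loci are diploid in both sexes and use autosomal GRM rules, but their
*expected* relationships carry a sex-gradient anchored at the
pseudo-autosomal boundary (PAB): sires transmit the Y-side (paternal)
haplotype to sons and the X-side (maternal) haplotype to daughters with
probability $1-r$, where $r$ is the male recombination fraction to the
PAB; dams transmit either haplotype with probability ½. One subtlety:
the source theory's displayed transmission equations give *identical*
weights for sons and daughters, which contradicts the surrounding
description and the empirical transmission figure; `xkin` implements the
description (daughters receive the sire's maternal haplotype with
probability $1-r$), and the gene-dropping oracle confirms the resulting
**P**^r^. `buildPPar()` runs a gametic-IBD recursion over two gametes per
individual; at $r = 0.5$ the gradient vanishes and $\mathbf{P}^{0.5}
= \mathbf{A}$ exactly, which the tests assert to machine precision.
Distances in cM are converted with Haldane's map function
$c = (1 - e^{-2d/100})/2$ — the simplest closure consistent with
probabilistic (no-interference) crossover modeling; the source conflates
distance and probability, and Haldane is the standard resolution.

## Metafounders

When base allele frequencies are unavailable, **G**^X^ can be built with
$p = 0.5$ and **S** replaced by the metafounder variant **S**^γ^: one
male-line and one female-line pseudo-ancestor per genetic group absorb
unknown-parent slots, and their self/cross relationships γ (supplied by
the user, not estimated — the source provides construction rules, not
estimates) seed the recursion. The seeding consistent with
$\mathrm{Var}(\mathbf{m}) = \mathbf{S}2pq$ is
$S(a,b) = \gamma_{g_a g_b}\, w_a w_b$ with $w = 0.5$ for male-line and
$w = 1$ for female-line metafounders (so a male-line diagonal starts at
$\gamma/4$, a female-line one at $\gamma$); descendants then follow the
ordinary recursion, and γ = 0 reproduces **S** exactly. The exact γ
parameterization was an open point; the implementation accepts a full
symmetric γ matrix across groups and was validated against a
gene-dropping oracle in which founder gametes are drawn from a pool with
per-locus frequency $0.5 \pm \sqrt{\gamma/8}$ — a construction whose
first two moments match the seeding exactly.

## The simulator as oracle

`simulatePedigree()`, `geneDropX()`, `geneDropPar()` and
`geneDropAutosome()` emulate exactly the inheritance model the matrices
encode: founder alleles at configurable base frequencies, hemizygous
males, intact sire-to-daughter X transmission, Haldane crossovers on a
configurable female map, and PAR male meiosis started at the PAB on the
haplotype matching the offspring's sex. Per-meiosis gamete origins are
recorded (`transmissionProfile()` reproduces the four sex-specific
transmission curves), and phenotypes can be simulated under any $(k,
r_G, h^2)$. Every expected-relationship formula is validated by the
covariance oracle: the empirical covariance of gene content over many
independently dropped loci must equal (matrix × $2pq$) entrywise.

Two simulator conventions matter for interpretation. First, loci are
dropped *independently* when no map is supplied (inter-locus
recombination ½), which is what makes the Monte-Carlo standard errors of
the covariance oracle valid; `geneDropPar(independent = TRUE)` provides
the same guarantee on the PAR by giving every locus its own meiosis.
Second, PAR transmission is conditioned on the offspring's recorded sex —
distributionally equivalent to determining sex by which sire gamete (X-
or Y-bearing) is transmitted, but applicable to pedigrees whose sexes are
fixed inputs.

What the simulator does **not** emulate: genotyping error, missing-data
patterns, linkage disequilibrium beyond what the pedigree and map induce,
selection, non-random mating, mutation, or the ascertainment of real SNP
arrays. Passing oracle tests therefore demonstrates internal consistency
of formulas and code under the stated inheritance model, not robustness
to real-data artifacts.

## Numerical and statistical conventions

* **Monte-Carlo tolerances.** "Within 3 standard errors entrywise" is
  enforced with a multiplicity allowance: across the ~465 distinct
  entries of a 30 × 30 comparison, ~1.3 exceedances of 3 SE are expected
  for a *correct* implementation, so the tests allow the binomial 0.5%
  quota and cap the worst standardized deviation at 4.5 SE (chance
  probability ≈ 3e-3 at these entry counts).
* **Problem sizes.** Oracle drops use 1.2–2.0 × 10⁵ loci on 30-individual
  pedigrees; the heritability scans use a 400-individual, 5-generation
  pedigree with 50 loci; dosage-compensation recovery uses 50 replicates
  of 600–2000 individuals at 120–300 loci. These sizes make Monte-Carlo
  standard errors small relative to the effects being checked while
  keeping the full suite within ordinary desktop runtimes.
* **Degenerate inputs.** Monomorphic loci are dropped with a logged
  count (they carry no variance and break the weighted GRM); missing
  genotypes are imputed to the per-locus mean of the same sex before
  centering (keeping E[**Z**] = 0 per sex — the choice is ours, the
  source is silent); male heterozygote calls on X-specific loci are
  errors; a {0,2} male coding is auto-halved on input with a notice.
* **Symmetry and PSD.** All matrices are symmetrized by averaging with
  the transpose after block algebra; numerical rank counts singular
  values above 1e-10 × max; REML refuses singular kinship matrices with
  advice to blend.
* **Reproducibility.** Every simulator entry point takes its seed from
  the configuration and re-seeds deterministically (distinct offsets per
  operation), so runs are bit-reproducible given the configuration.

## Known limitations

* The bivariate model covers two sexes and the X only; joint autosome +
  X multi-trait models are a documented extension, not implemented.
* No LD pruning, Hardy–Weinberg tests or call-rate QC: array QC is
  data-specific and out of scope; inputs are assumed filtered.
* Binary PLINK (.bed) and VCF ingestion are not implemented; `.raw`
  exports and plain TSV are.
* Haplotype phasing and imputation beyond mean-fill are out of scope.
* `buildPPar()` is dense and quadratic in pedigree size; it is intended
  for research-scale pedigrees (thousands, not millions).
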