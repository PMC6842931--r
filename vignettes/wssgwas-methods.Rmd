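---
title: "Weighted single-step GWAS: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Traits recorded repeatedly on breeding animals — semen quality traits of AI
bulls are the motivating case — are evaluated with an animal model in which
only part of the population is genotyped. Single-step genomic BLUP (ssGBLUP)
combines the pedigree and the marker panel in one evaluation, so ungenotyped
animals contribute phenotypic information through their relatives. Weighted
single-step GWAS (WssGWAS) then converts the genomic breeding values of the
genotyped animals into per-SNP effects, re-weights SNPs by their apparent
variance, re-solves, and summarizes the result as the percentage of additive
genetic variance explained by sliding windows of adjacent SNPs.

This package implements that pipeline end to end, together with a synthetic
data generator so every stage can be exercised and tested without access to
any proprietary bull data.

## The model

For one trait the repeatability animal model is

$$y = X\beta + Za + Wp + e,$$

with $\beta$ the fixed effects (year-season, station, collection-interval
class, collection-number class, and age in months as a covariate), $a \sim
N(0, H\sigma^2_a)$ the additive genetic effects of *all* pedigree animals,
$p \sim N(0, I\sigma^2_p)$ the permanent-environment effects of animals with
records, and $e \sim N(0, I\sigma^2_e)$. Variance components are *inputs*
(`variance_components()`): estimating them (REML) is out of scope, and the
synthetic defaults ($\sigma^2_a = 1, \sigma^2_p = 1, \sigma^2_e = 3$, i.e.
$h^2 = 0.2$ and repeatability $0.4$) sit in the range reported for bull
fertility traits.

The single-step relationship matrix enters only through its inverse,

$$H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
\end{pmatrix},$$

where $A$ is the pedigree numerator relationship matrix, $A_{22}$ its
genotyped block, and $G = ZDZ'q$ the genomic relationship matrix built from
markers coded 0/1/2, centered by twice the allele frequency, with SNP-weight
diagonal $D$ and scaling $q = 1/\sum_i 2p_i(1-p_i)$ (VanRaden's first
method). $A^{-1}$ is assembled sparsely by Henderson's rules with
Meuwissen–Luo inbreeding coefficients; the dense $A$ (tabular method) is
used only for $A_{22}$ and as an independent oracle in the tests.

The mixed-model equations are solved by a direct sparse factorization
(Cholesky, LU fallback); the reported `convergence` is the relative residual
of the solved system, typically at machine precision for desk-scale
problems.

## The weighting loop

1. Set $D = I$.
2. Build $G = ZDZ'q$, blend with $A_{22}$, assemble $H^{-1}$.
3. Solve the mixed-model equations for all animals' GEBVs.
4. Backsolve SNP effects from the genotyped animals' GEBVs:
   $\hat u = q\,D\,Z' G^{-1} \hat a_g$.
5. Update weights $d_i = \hat u_i^2 \, 2p_i(1 - p_i)$.
6. Normalize so $\sum_i d_i$ equals the SNP count (the iteration-1 total),
   keeping the implied genetic variance constant.
7. Return to step 2.

Two design points deserve emphasis:

* **The backsolve constant equals $q$.** With $G = ZDZ'q$, the choice
  $\hat u = q D Z' G^{-1} \hat a_g$ is the unique scaling under which
  $Z\hat u = \hat a_g$ exactly (when $G$ is unblended and invertible): it is
  the standard BLUP conversion of animal solutions to marker solutions. The
  tests verify this identity to 1e-8.
* **"One iteration" means one reweighting pass**, i.e. two solves: the first
  with $D = I$, the second with the updated weights. `n_iter` is
  configurable; the default is 2 because further iterations increasingly
  concentrate weight on a few regions and overfit them.

### A note on the singularity of raw G

Centering $Z$ by the *observed* allele frequencies makes every column of $Z$
sum to zero, so $G\mathbf{1} = 0$: the raw $G$ is always singular, whatever
the panel. The pipeline therefore blends $G \leftarrow (1-\alpha)G + \alpha
A_{22}$ with $\alpha = 0.05$ by default, which is also common practice for
numerical stability. The exact projection identity $Z\hat u = \hat a_g$ is
still testable: supply base-population frequencies to `snp_weights(freqs=)`
(in simulations, the generating founder frequencies), under which unblended
$G$ is full rank whenever there are more SNPs than genotyped individuals.
The identity tests and the acceptance script do exactly that; the analysis
path keeps observed frequencies plus blending.

## Window variance partition

For each within-chromosome window of `window_size = 10` adjacent SNPs
(sliding by `step = 1`), the per-individual window genetic value $g =
\sum_{j} z_j \hat u_j$ is computed over the genotyped individuals and its
sample variance is expressed as a percentage of $\sigma^2_a$ — the
*configured* component, not the empirical variance of $Z\hat u$, so the
percentages are comparable across runs. Windows never span chromosomes;
a chromosome shorter than the window yields one truncated window with a
warning.

Because dense sliding produces near-copies of each peak, `top_windows()`
greedily prunes: walking down the ranking, a window is dropped if it shares
at least one SNP with an already selected window, so the reported top-10 are
distinct regions. Summary classes follow the conventional bands (>1%,
0.5–1%, 0.1–0.5%, <0.1%), with band edges assigned to the lower band — the
boundary convention is ours, and `classify_windows()` reports both the count
share and the variance share per band because either summary is defensible.
Cross-trait overlaps are closed-interval intersections on the same
chromosome (adjacency is not overlap), merged transitively.

## Quality control

SNPs are removed when call rate < 0.90, minor allele frequency < 0.01, or
the 1-df chi-square goodness-of-fit p-value against Hardy–Weinberg
proportions < 1e-6. The HWE threshold is read as a p-value bound, the
universal convention for this chip-QC triple. All three filters are
evaluated jointly on the input matrix, so the report attributes each SNP to
every filter it fails and the counts reconcile: passes plus the union of
failures equal the input count. Missing calls that survive QC are mean
imputed (dosage $2p$) with a warning — reference-panel imputation is out of
scope. Phenotype error filtering keeps records inside the traits' legal
ranges (VE 0–30 ml, SC 0–40 ×10⁹/ml, MS 0–1; the product traits NSP and
NMSP non-negative and bounded by the product of their factors' bounds).

## The synthetic generator

`sim_config()` defines the study conditions; `simulate_dataset()` draws
them. The generator emulates:

* a discrete-generation pedigree (founders with unknown parents, matings of
  one male and one female from the previous generation);
* unlinked biallelic SNPs gene-dropped through the pedigree — founder
  alleles Bernoulli at per-SNP frequencies uniform on `maf_range`, each
  offspring receiving one uniformly chosen allele per parent per locus;
* a sparse QTL architecture: causal SNPs sampled among markers with
  realized MAF ≥ 0.05 (a genuinely monomorphic or QC-failing "QTL" would
  make the effect scaling and the truth bookkeeping meaningless), effects
  either normal or scaled to equal per-QTL variance shares
  (`qtl_equal_var`), with the remainder of $\sigma^2_a$ as a
  pedigree-structured polygenic term (parent average plus Mendelian
  sampling with variance $(1/2 - (F_s+F_d)/4)\sigma^2_{poly}$);
* repeated records per bull with five systematic effects drawn once per
  level from $N(0, 0.5^2)$, ages uniform on 24–120 months with slope 0.01
  per month, and a baseline of 10 so values sit inside the VE legal range.

The default preset — 80 founders plus 3 generations of 70 matings × 2
offspring (500 animals), 2,000 SNPs on 5 chromosomes of 100 Mb, 20 QTLs
carrying half of $\sigma^2_a$, 30% of animals ungenotyped, 5–60 records per
animal — runs the full pipeline in a couple of seconds, which is why the
test suite and the acceptance script use it (the recovery benchmark uses 3
QTLs of 15% each, 10–20 replicate seeds).

**What the generator does not emulate:** chip-scale linkage disequilibrium
(the only LD is within-family cosegregation), selection, assortative
mating, genotyping error, and X-chromosome inheritance. Passing tests
therefore demonstrate the machinery — relationship algebra, solving,
backsolving, weighting, window partition — not the field behaviour of the
method on a real LD structure, where windows borrow signal from flanking
markers.

## Known limitations

* **Power is MAF-dependent.** A QTL carrying a large variance share at a
  low allele frequency is strongly shrunk by the uniform-$D$ GBLUP prior,
  and one reweighting pass does not rescue it: in the recovery benchmark,
  misses concentrate at QTL MAF below ~0.15. This mirrors the method, not a
  defect of the implementation.
* Variance components are assumed known; mis-specified ratios bias the
  shrinkage and hence the window percentages.
* Reference-level fixed-effect coding with an intercept is used for
  identifiability; raw fixed-effect solutions are therefore
  parameterization-dependent, and only estimable functions (level
  contrasts, GEBVs) should be interpreted.
* The top-10 pruning rule (drop on any shared SNP) is one reasonable
  convention; published tables may prune differently or not at all.

## Numerical conventions

Blending default $\alpha = 0.05$ toward $A_{22}$; solver: sparse Cholesky
with LU fallback, relative-residual reported; ties in window ranking broken
by chromosome then start position; topological sorting of pedigrees is
canonical (parents before offspring) and cycles are a hard error naming a
member; all simulator stages derive their RNG streams from one integer seed
and restore the caller's RNG state.
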