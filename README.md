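# wssgwas

Weighted single-step genome-wide association (WssGWAS) for repeated-record
traits in populations where only part of the animals are genotyped — the
situation of semen-quality evaluation in AI bull studs, where thousands of
ejaculate records exist per bull but genotypes cover a subset of the
pedigree.

The package implements, in plain R on top of `Matrix` sparse algebra:

* the repeatability animal model `y = Xβ + Za + Wp + e` with
  `a ~ N(0, H σ²a)`, `p ~ N(0, I σ²p)`, `e ~ N(0, I σ²e)`, solved through
  Henderson's mixed-model equations;
* the single-step relationship inverse
  `H⁻¹ = A⁻¹ + [0 0; 0 G⁻¹ − A22⁻¹]`, with `A⁻¹` assembled sparsely by
  Henderson's rules using Meuwissen–Luo inbreeding and `G = ZDZ′q` the
  (optionally A22-blended) genomic relationship matrix from 0/1/2 marker
  codes centered by allele frequency, `q = 1/Σ 2pᵢ(1−pᵢ)`;
* the WssGWAS loop: backsolve SNP effects `û = q·D·Z′G⁻¹·â_g` from the
  genotyped animals' GEBVs, reweight `dᵢ = ûᵢ²·2pᵢ(1−pᵢ)`, normalize so
  Σd stays equal to the SNP count, rebuild `G` and `H⁻¹`, re-solve (default:
  one reweighting pass, i.e. two solves);
* variance partition into 10-SNP sliding windows:
  `pct_i = Var(Σ_j z_j û_j) / σ²a × 100%` over genotyped individuals, with
  ranked, overlap-pruned top regions, >1% / 0.5–1% / 0.1–0.5% / <0.1% class
  summaries, cross-trait overlap detection and Manhattan-style plots;
* chip QC (call rate < 0.90, MAF < 0.01, HWE chi-square p < 1e-6) and
  trait-range error filtering (VE 0–30, SC 0–40, MS 0–1, products bounded);
* a synthetic-data generator (discrete-generation pedigree, gene-dropped
  unlinked SNPs, sparse QTL architecture, repeated records with five
  systematic effects) so the whole pipeline runs and is tested without any
  external data.

Results come back as tibbles; fitted objects have `tidy()` / `glance()`
methods and window tables have an `autoplot()` Manhattan plot.

## Worked example

A synthetic study at the default desk scale — 500 animals over 3
generations, 2,000 SNPs on 5 chromosomes, 3 QTLs each carrying 15% of the
additive variance, 30% of animals ungenotyped:

```r
library(wssgwas)

cfg <- wss_config(
  sim = sim_config(n_qtl = 3, qtl_variance_fraction = 0.45,
                   qtl_equal_var = TRUE, seed = 11),
  seed = 11
)
run <- run_pipeline(cfg)
#> [data] 500 animals, 350 genotyped, 2000 SNPs, 15902 records
#> VE: kept 15902 of 15902 records (range 0-30)
#> [qc] 1999 of 2000 SNPs pass
#> [wssgwas] 2 iteration(s), MME residual 1.84e-15
#> [windows] 1954 windows; top region explains 6.47% of sigma2_a

run
#> <wss_run> trait VE (synthetic mode)
#>   SNPs passing QC: 1999
#>   records: 15902
#>   top region: chr5 58.35-60.6 Mb, 6.47% of additive variance

run$top_windows[1:3, c("chromosome", "start_bp", "end_bp", "pct_variance", "rank")]
#>   chromosome start_bp   end_bp pct_variance  rank
#> 1          5 58353984 60598368         6.47     1
#> 2          5 49127072 51371456         1.82     2
#> 3          4 82792832 85037216         1.29     3
```

The top-ranked region on chromosome 5 explains 6.47% of σ²a — a 15% QTL
seen through GBLUP shrinkage at 350 genotyped animals. The simulator keeps
the generating truth, so accuracy is directly measurable:

```r
gids <- rownames(run$data$genotypes$calls)
cor(run$fit$gebv[gids], run$data$truth$true_bv[gids])
#> [1] 0.748
```

`autoplot(run$windows)` draws the Manhattan-style window plot;
`tidy(run$gwas)` returns per-SNP effects and weights for both iterations;
`overlap_across_traits()` merges top regions shared between traits. File
mode (`wss_config(mode = "files", paths = ...)`) reads pedigree, genotype,
map and phenotype text files with the same layouts the simulator writes, so
synthetic and real analyses are interchangeable.

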