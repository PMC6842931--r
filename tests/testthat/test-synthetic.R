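test_that("pedigree simulation honours counts, structure and seed", {
  cfg0 <- sim_config(n_founders = 10, n_generations = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 10)
  expect_true(all(is.na(ped0$sire_id)))

  # 10 founders + 2 generations x 5 matings x 2 offspring = 30 animals
  cfg <- sim_config(n_founders = 10, n_generations = 2, n_matings = 5,
                    offspring_per_mating = 2, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 30)
  # discrete generations: non-founder parents precede offspring
  expect_s3_class(ped, "wss_pedigree")
  expect_identical(simulate_pedigree(cfg), ped) # determinism
  expect_false(identical(simulate_pedigree(sim_config(
    n_founders = 10, n_generations = 2, n_matings = 5,
    offspring_per_mating = 2, seed = 2)), ped))
})

test_that("gene dropping is Mendelian-consistent and tracks founder MAF", {
  cfg <- sim_config(n_founders = 200, n_generations = 1, n_matings = 30,
                    n_snps = 50, n_chromosomes = 2,
                    maf_range = c(0.5, 0.5), seed = 5)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  expect_identical(g, simulate_genotypes(ped, cfg)) # determinism

  # founder allele frequencies ~ Binomial(2 * 200, 0.5) / 400: the mean over
  # SNPs and the across-SNP spread must both match the binomial expectation
  founders <- is.na(ped$sire_id)
  freq <- colMeans(g$calls[founders, ]) / 2
  se <- sqrt(0.25 / (2 * sum(founders)))
  expect_lt(abs(mean(freq) - 0.5), 4 * se / sqrt(length(freq)))
  expect_gt(stats::sd(freq) / se, 0.7)
  expect_lt(stats::sd(freq) / se, 1.4)

  # Mendelian consistency at every locus: child call within parental bounds
  ix <- wssgwas:::ped_indices(ped)
  for (i in which(ix$sire > 0 & ix$dam > 0)) {
    s <- g$calls[ix$sire[i], ]
    d <- g$calls[ix$dam[i], ]
    o <- g$calls[i, ]
    lo <- pmax(0, (s == 2) + (d == 2)) # forced transmitted alt alleles
    hi <- 2 - ((s == 0) + (d == 0)) # forced transmitted ref alleles
    expect_true(all(o >= lo & o <= hi))
    # in particular: loci where both parents are 0-coded force a 0 call
    expect_true(all(o[s == 0 & d == 0] == 0))
  }
})

test_that("phenotype generator reduces to y = mean + a under degenerate noise", {
  cfg <- sim_config(
    n_founders = 20, n_generations = 1, n_matings = 10, n_snps = 60,
    n_chromosomes = 1, n_qtl = 5, qtl_variance_fraction = 1,
    varcomp = variance_components(1, 1e-18, 1e-18),
    records_per_animal = c(1, 1), fixed_effect_sd = 0, age_slope = 0,
    trait_mean = 0, seed = 9
  )
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, g, cfg)
  y <- sim$phenotypes$value[match(ped$animal_id, sim$phenotypes$bull_id)]
  expect_equal(y, unname(sim$truth$true_bv), tolerance = 1e-6)
})

test_that("simulated additive variance matches sigma2_a across seeds", {
  vars <- vapply(1:20, function(s) {
    cfg <- sim_config(n_founders = 60, n_generations = 2, n_matings = 40,
                      n_snps = 100, n_chromosomes = 1, n_qtl = 10,
                      records_per_animal = c(1, 2), seed = s)
    ped <- simulate_pedigree(cfg)
    g <- simulate_genotypes(ped, cfg)
    stats::var(simulate_phenotypes(ped, g, cfg)$truth$true_bv)
  }, numeric(1))
  se <- stats::sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - 1), 3 * se + 1e-12)
})

test_that("repeated records of one bull differ only by residual noise", {
  cfg <- sim_config(n_founders = 100, n_generations = 1, n_matings = 50,
                    n_snps = 50, n_chromosomes = 1, n_qtl = 5,
                    records_per_animal = c(2, 2), fixed_effect_sd = 0,
                    age_slope = 0, seed = 21)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, g, cfg)$phenotypes
  d <- ph |>
    dplyr::group_by(bull_id) |>
    dplyr::summarise(diff = diff(value)[1], .groups = "drop")
  # Var(y1 - y2) = 2 sigma2_e; chi-square CI on the sample variance
  n <- nrow(d)
  ratio <- stats::var(d$diff) / (2 * cfg$varcomp$sigma2_e)
  expect_gt(ratio, qchisq(0.0005, n - 1) / (n - 1))
  expect_lt(ratio, qchisq(0.9995, n - 1) / (n - 1))
})

test_that("midparent regression recovers the simulated heritability", {
  # offspring BV on midparent BV has slope 1 (BVs, not phenotypes);
  # regression of offspring phenotype deviation on midparent BV ~ 1 as well
  slopes <- vapply(1:10, function(s) {
    cfg <- sim_config(n_founders = 80, n_generations = 2, n_matings = 60,
                      n_snps = 100, n_chromosomes = 1, n_qtl = 10,
                      records_per_animal = c(1, 1), seed = s)
    ped <- simulate_pedigree(cfg)
    g <- simulate_genotypes(ped, cfg)
    truth <- simulate_phenotypes(ped, g, cfg)$truth
    ix <- wssgwas:::ped_indices(ped)
    off <- which(ix$sire > 0 & ix$dam > 0)
    mid <- (truth$true_bv[ix$sire[off]] + truth$true_bv[ix$dam[off]]) / 2
    unname(stats::coef(stats::lm(truth$true_bv[off] ~ mid))[2])
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1), 3 * se)
})

test_that("masking removes individuals from genotypes only", {
  cfg <- sim_config(n_founders = 50, n_generations = 1, n_matings = 25,
                    n_snps = 40, n_chromosomes = 1, seed = 2)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  expect_equal(mask_genotypes(g, 0, seed = 1)$genotypes$calls, g$calls)
  mk <- mask_genotypes(g, 0.3, seed = 1)
  expect_equal(nrow(mk$genotypes$calls), 70)
  expect_equal(length(mk$ungenotyped_ids), 30)
  expect_identical(mask_genotypes(g, 0.3, seed = 1), mk)
  expect_error(mask_genotypes(g, 1, seed = 1), "fraction")
})

test_that("total phenotypic variance decomposes as the components promise", {
  cfg <- sim_config(n_founders = 150, n_generations = 2, n_matings = 100,
                    n_snps = 100, n_chromosomes = 1, n_qtl = 10,
                    records_per_animal = c(3, 3), fixed_effect_sd = 0.5,
                    age_slope = 0, seed = 31)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, g, cfg)$phenotypes
  vc <- cfg$varcomp
  fixed_var <- 4 * cfg$fixed_effect_sd^2 # four independent class effects
  expected <- fixed_var + vc$sigma2_a + vc$sigma2_p + vc$sigma2_e
  expect_lt(abs(stats::var(ph$value) / expected - 1), 0.2)
})
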