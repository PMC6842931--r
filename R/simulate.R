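#' Configuration for the synthetic breeding-population generator
#'
#' Defines a desk-scale population with the statistical structure the
#' single-step repeatability model assumes: a multi-generation pedigree with
#' discrete generations, unlinked biallelic SNPs gene-dropped through the
#' pedigree, a sparse set of QTLs among the SNPs, repeated records per bull
#' driven by five systematic effects (year-season, station, collection
#' interval class, collection-number class, age in months), an additive
#' genetic term, a permanent-environment term and a residual.
#'
#' The default preset (500 animals over 3 generations, 2,000 SNPs on 5
#' chromosomes, 20 QTLs explaining half the additive variance, 30%
#' ungenotyped animals, 5-60 records per animal, h2 = 0.2 and repeatability
#' 0.4) is sized so the full pipeline runs in minutes.
#'
#' @param n_founders founder animals (generation 0).
#' @param n_generations number of discrete offspring generations.
#' @param n_matings matings per generation.
#' @param offspring_per_mating full sibs per mating.
#' @param n_snps,n_chromosomes markers, spread evenly over autosomes.
#' @param maf_range founder allele-frequency range (uniform draw per SNP).
#' @param n_qtl number of causal SNPs among the markers.
#' @param qtl_variance_fraction share of `sigma2_a` carried by the QTLs
#'   (remainder is a pedigree-structured polygenic term).
#' @param qtl_equal_var if `TRUE`, each QTL contributes an equal share of the
#'   QTL variance; otherwise effects are drawn normal.
#' @param varcomp [variance_components()] used for simulation.
#' @param records_per_animal integer range `c(min, max)` of records per bull.
#' @param n_levels named integer vector of class counts for the factors
#'   `year_season`, `station`, `interval_class`, `collection_class`.
#' @param fixed_effect_sd SD of the per-level fixed effects (trait units).
#' @param age_range age covariate range in months (uniform per record).
#' @param age_slope regression of the trait on age (units per month).
#' @param trait trait label written into the phenotype table.
#' @param trait_mean baseline added to every record so simulated values sit
#'   inside the trait's legal range.
#' @param ungenotyped_fraction share of animals whose genotypes are masked.
#' @param seed integer seed; every generator stage derives its stream from it.
#' @return list of class `wss_sim_config`.
#' @export
sim_config <- function(n_founders = 80,
                       n_generations = 3,
                       n_matings = 70,
                       offspring_per_mating = 2,
                       n_snps = 2000,
                       n_chromosomes = 5,
                       maf_range = c(0.05, 0.5),
                       n_qtl = 20,
                       qtl_variance_fraction = 0.5,
                       qtl_equal_var = FALSE,
                       varcomp = variance_components(1, 1, 3),
                       records_per_animal = c(5, 60),
                       n_levels = c(year_season = 10, station = 5,
                                    interval_class = 3, collection_class = 3),
                       fixed_effect_sd = 0.5,
                       age_range = c(24, 120),
                       age_slope = 0.01,
                       trait = "VE",
                       trait_mean = 10,
                       ungenotyped_fraction = 0.3,
                       seed = 42) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_matings = as.integer(n_matings),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    maf_range = maf_range,
    n_qtl = as.integer(n_qtl),
    qtl_variance_fraction = qtl_variance_fraction,
    qtl_equal_var = isTRUE(qtl_equal_var),
    varcomp = varcomp,
    records_per_animal = as.integer(records_per_animal),
    n_levels = n_levels,
    fixed_effect_sd = fixed_effect_sd,
    age_range = age_range,
    age_slope = age_slope,
    trait = trait,
    trait_mean = trait_mean,
    ungenotyped_fraction = ungenotyped_fraction,
    seed = as.integer(seed)
  )
  if (cfg$n_founders < 2) abort("n_founders must be >= 2")
  if (cfg$n_generations < 0) abort("n_generations must be >= 0")
  if (cfg$n_generations > 0 &&
      (cfg$n_matings < 1 || cfg$offspring_per_mating < 1)) {
    abort("n_matings and offspring_per_mating must be >= 1")
  }
  if (cfg$n_qtl > cfg$n_snps) abort("n_qtl must be <= n_snps")
  if (cfg$qtl_variance_fraction < 0 || cfg$qtl_variance_fraction > 1) {
    abort("qtl_variance_fraction must be in [0, 1]")
  }
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    abort("maf_range must satisfy 0 < low <= high <= 0.5")
  }
  if (cfg$ungenotyped_fraction < 0 || cfg$ungenotyped_fraction >= 1) {
    abort("ungenotyped_fraction must be in [0, 1)")
  }
  if (!inherits(cfg$varcomp, "wss_varcomp")) {
    abort("varcomp must come from variance_components()")
  }
  if (cfg$records_per_animal[1] < 1 ||
      cfg$records_per_animal[1] > cfg$records_per_animal[2]) {
    abort("records_per_animal must be an increasing positive range")
  }
  if (!cfg$trait %in% SEMEN_TRAITS) {
    abort(paste0("trait must be one of ", paste(SEMEN_TRAITS, collapse = ", ")))
  }
  class(cfg) <- "wss_sim_config"
  cfg
}

#' Simulate a discrete-generation pedigree
#'
#' Founders (generation 0) have unknown parents and alternating sexes. Each
#' later generation consists of `n_matings` matings, each sampled as one male
#' and one female from the previous generation (no self-mating by
#' construction), producing `offspring_per_mating` full sibs. Deterministic
#' under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return a [pedigree()] with an extra `sex` column.
#' @export
simulate_pedigree <- function(cfg) {
  with_seed(cfg$seed, {
    nf <- cfg$n_founders
    ids <- sprintf("F%04d", seq_len(nf))
    sex <- rep(c("M", "F"), length.out = nf)
    sire <- rep(NA_character_, nf)
    dam <- rep(NA_character_, nf)
    prev_ids <- ids
    prev_sex <- sex
    for (g in seq_len(cfg$n_generations)) {
      males <- prev_ids[prev_sex == "M"]
      females <- prev_ids[prev_sex == "F"]
      if (length(males) == 0 || length(females) == 0) {
        abort("a generation has no animals of one sex; increase sizes")
      }
      n_off <- cfg$n_matings * cfg$offspring_per_mating
      sires_g <- sample(males, cfg$n_matings, replace = TRUE)
      dams_g <- sample(females, cfg$n_matings, replace = TRUE)
      off_ids <- sprintf("G%d_%04d", g, seq_len(n_off))
      off_sex <- rep(c("M", "F"), length.out = n_off)
      ids <- c(ids, off_ids)
      sex <- c(sex, off_sex)
      sire <- c(sire, rep(sires_g, each = cfg$offspring_per_mating))
      dam <- c(dam, rep(dams_g, each = cfg$offspring_per_mating))
      prev_ids <- off_ids
      prev_sex <- off_sex
    }
    ped <- pedigree(ids, sire, dam, sort = FALSE)
    ped$sex <- sex
    ped
  })
}

#' Simulate unlinked biallelic genotypes by gene dropping
#'
#' Founder allele frequencies are drawn uniformly from `maf_range` per SNP;
#' founder alleles are Bernoulli draws at those frequencies. Every
#' non-founder receives one allele from each parent, the transmitted allele
#' chosen uniformly per locus (Mendelian gene dropping). Loci are unlinked:
#' the only linkage disequilibrium is the within-family cosegregation the
#' pedigree itself induces. Positions are evenly spaced on equal-length
#' chromosomes.
#'
#' @param ped a sorted pedigree (all parents present).
#' @param cfg a [sim_config()].
#' @return a [geno_matrix()] over all pedigree animals.
#' @export
simulate_genotypes <- function(ped, cfg) {
  ped <- assert_sorted_pedigree(ped)
  ix <- ped_indices(ped)
  n <- nrow(ped)
  m <- cfg$n_snps
  with_seed(cfg$seed + 1L, {
    p0 <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    H1 <- matrix(0L, n, m)
    H2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      s <- ix$sire[i]
      d <- ix$dam[i]
      if (s == 0L && d == 0L) {
        H1[i, ] <- rbinom(m, 1L, p0)
        H2[i, ] <- rbinom(m, 1L, p0)
      } else {
        pick <- function(par) {
          if (par == 0L) return(rbinom(m, 1L, p0)) # unknown parent: population allele
          sel <- rbinom(m, 1L, 0.5) == 1L
          ifelse(sel, H1[par, ], H2[par, ])
        }
        H1[i, ] <- pick(s)
        H2[i, ] <- pick(d)
      }
    }
    calls <- H1 + H2
    rownames(calls) <- ped$animal_id
    per_chr <- diff(round(seq(0, m, length.out = cfg$n_chromosomes + 1L)))
    chrom <- rep(seq_len(cfg$n_chromosomes), times = per_chr)
    chr_len <- 1e8 # 100 Mb autosomes
    pos <- unlist(lapply(per_chr, function(k) {
      spacing <- floor(chr_len / (k + 1L))
      spacing * seq_len(k)
    }))
    map <- tibble(
      snp_id = sprintf("snp%05d", seq_len(m)),
      chrom = as.integer(chrom),
      pos_bp = as.numeric(pos)
    )
    geno_matrix(calls, map)
  })
}

#' Simulate repeated phenotype records and the generating truth
#'
#' QTL columns are sampled without replacement among the SNPs and their
#' effects scaled so the QTL genetic values carry
#' `qtl_variance_fraction * sigma2_a` of variance across animals; the
#' remainder of the additive variance is a pedigree-structured polygenic term
#' (founders `N(0, sigma2_poly)`, offspring = parent average plus Mendelian
#' sampling with variance `(1/2 - (F_s + F_d)/4) sigma2_poly`). Each record
#' is `trait_mean + sum(fixed-class effects) + age_slope * age + a_i + p_i +
#' e`, with `p_i ~ N(0, sigma2_p)` per animal and `e ~ N(0, sigma2_e)` per
#' record; class labels are uniform, ages uniform on `age_range`, record
#' counts uniform on `records_per_animal`.
#'
#' @param ped sorted pedigree.
#' @param g genotypes covering all pedigree animals (mask afterwards with
#'   [mask_genotypes()]).
#' @param cfg a [sim_config()].
#' @return list with `phenotypes` (tibble in [read_phenotypes()] layout) and
#'   `truth` (class `wss_truth`: `qtl_indices`, `qtl_effects`, `true_bv`,
#'   `true_pe`, `varcomp_used`, `seed`).
#' @export
simulate_phenotypes <- function(ped, g, cfg) {
  ped <- assert_sorted_pedigree(ped)
  if (!identical(rownames(g$calls), ped$animal_id)) {
    abort("genotypes must cover all pedigree animals in pedigree order")
  }
  vc <- cfg$varcomp
  with_seed(cfg$seed + 2L, {
    n <- nrow(ped)
    m <- ncol(g$calls)
    Z <- center_genotypes(g)

    # QTLs are drawn among markers still common in the realized population
    # (MAF >= 0.05): a causal variant carrying a sizeable share of sigma2_a
    # at a rare allele would need an implausibly large effect
    p_real <- colMeans(g$calls) / 2
    candidates <- which(pmin(p_real, 1 - p_real) >= 0.05)
    if (length(candidates) < cfg$n_qtl) {
      abort("fewer polymorphic SNPs (realized MAF >= 0.05) than n_qtl")
    }
    qtl_idx <- sort(sample(candidates, cfg$n_qtl))
    qvar <- cfg$qtl_variance_fraction * vc$sigma2_a
    if (cfg$n_qtl > 0 && qvar > 0) {
      if (cfg$qtl_equal_var) {
        per <- qvar / cfg$n_qtl
        colv <- apply(Z[, qtl_idx, drop = FALSE], 2L, stats::var)
        beta <- sample(c(-1, 1), cfg$n_qtl, replace = TRUE) * sqrt(per / colv)
      } else {
        beta <- rnorm(cfg$n_qtl)
      }
      g_qtl <- as.numeric(Z[, qtl_idx, drop = FALSE] %*% beta)
      v <- stats::var(g_qtl)
      if (v == 0) abort("QTL genetic values are constant; resimulate")
      sc <- sqrt(qvar / v)
      beta <- beta * sc
      g_qtl <- g_qtl * sc
    } else {
      qtl_idx <- integer(0)
      beta <- numeric(0)
      g_qtl <- numeric(n)
    }

    s2_poly <- (1 - cfg$qtl_variance_fraction) * vc$sigma2_a
    a_poly <- numeric(n)
    if (s2_poly > 0) {
      ix <- ped_indices(ped)
      FF <- inbreeding(ped)
      for (i in seq_len(n)) {
        s <- ix$sire[i]
        d <- ix$dam[i]
        if (s == 0L && d == 0L) {
          a_poly[i] <- rnorm(1, 0, sqrt(s2_poly))
        } else {
          fs <- if (s > 0L) FF[s] else -1
          fd <- if (d > 0L) FF[d] else -1
          mvar <- (0.5 - 0.25 * (fs + fd)) * s2_poly
          pa <- 0.5 * ((if (s > 0L) a_poly[s] else 0) +
                         (if (d > 0L) a_poly[d] else 0))
          a_poly[i] <- pa + rnorm(1, 0, sqrt(mvar))
        }
      }
    }
    true_bv <- setNames(g_qtl + a_poly, ped$animal_id)
    true_pe <- setNames(rnorm(n, 0, sqrt(vc$sigma2_p)), ped$animal_id)

    lev_effects <- lapply(cfg$n_levels, function(k) {
      rnorm(k, 0, cfg$fixed_effect_sd)
    })
    rec_choices <- seq(cfg$records_per_animal[1], cfg$records_per_animal[2])
    n_rec <- rec_choices[sample.int(length(rec_choices), n, replace = TRUE)]
    rec_animal <- rep(seq_len(n), times = n_rec)
    total <- length(rec_animal)
    labels <- lapply(names(cfg$n_levels), function(f) {
      sample.int(cfg$n_levels[[f]], total, replace = TRUE)
    })
    names(labels) <- names(cfg$n_levels)
    age <- runif(total, cfg$age_range[1], cfg$age_range[2])
    fixed_part <- Reduce(`+`, lapply(names(labels), function(f) {
      lev_effects[[f]][labels[[f]]]
    }))
    y <- cfg$trait_mean + fixed_part + cfg$age_slope * age +
      true_bv[rec_animal] + true_pe[rec_animal] +
      rnorm(total, 0, sqrt(vc$sigma2_e))

    pheno <- tibble(
      bull_id = ped$animal_id[rec_animal],
      trait = cfg$trait,
      value = as.numeric(y),
      year_season = paste0("ys", labels$year_season),
      station = paste0("st", labels$station),
      interval_class = paste0("iv", labels$interval_class),
      collection_class = paste0("cc", labels$collection_class),
      age_months = age
    )
    truth <- structure(list(
      qtl_indices = qtl_idx,
      qtl_effects = beta,
      qtl_snp_ids = g$map$snp_id[qtl_idx],
      true_bv = true_bv,
      true_pe = true_pe,
      varcomp_used = vc,
      seed = cfg$seed
    ), class = "wss_truth")
    list(phenotypes = pheno, truth = truth)
  })
}

#' Mask a fraction of individuals as ungenotyped
#'
#' Removes a uniformly sampled subset of individuals from the genotype
#' matrix; they stay in the pedigree and phenotype table, which is exactly
#' the situation the single-step H matrix handles.
#'
#' @param g a [geno_matrix()].
#' @param fraction share of individuals to mask, in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `genotypes` (masked `wss_geno`) and `ungenotyped_ids`.
#' @export
mask_genotypes <- function(g, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) {
    abort("fraction must be in [0, 1): at least one genotyped animal must remain")
  }
  n <- nrow(g$calls)
  n_mask <- round(fraction * n)
  with_seed(seed, {
    masked <- if (n_mask > 0) sort(sample.int(n, n_mask)) else integer(0)
    keep <- setdiff(seq_len(n), masked)
    list(
      genotypes = geno_matrix(g$calls[keep, , drop = FALSE], g$map),
      ungenotyped_ids = rownames(g$calls)[masked]
    )
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: pedigree, gene-dropped genotypes, phenotypes with
#' truth, and genotype masking, all from one config.
#'
#' @param cfg a [sim_config()].
#' @return list with `pedigree`, `genotypes` (masked), `genotypes_full`,
#'   `ungenotyped_ids`, `phenotypes`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ped <- simulate_pedigree(cfg)
  geno_full <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, geno_full, cfg)
  masked <- mask_genotypes(geno_full, cfg$ungenotyped_fraction,
                           seed = cfg$seed + 3L)
  list(
    pedigree = ped,
    genotypes = masked$genotypes,
    genotypes_full = geno_full,
    ungenotyped_ids = masked$ungenotyped_ids,
    phenotypes = sim$phenotypes,
    truth = sim$truth,
    config = cfg
  )
}

#' Write the generating truth to sidecar delimited files
#'
#' @param truth a `wss_truth`.
#' @param bv_path per-animal TSV (`animal_id`, `true_bv`, `true_pe`).
#' @param qtl_path per-QTL TSV (`snp_index`, `snp_id`, `effect`).
#' @return `bv_path`, invisibly.
#' @export
write_truth <- function(truth, bv_path, qtl_path) {
  readr::write_tsv(tibble(
    animal_id = names(truth$true_bv),
    true_bv = unname(truth$true_bv),
    true_pe = unname(truth$true_pe)
  ), bv_path)
  readr::write_tsv(tibble(
    snp_index = truth$qtl_indices,
    snp_id = truth$qtl_snp_ids,
    effect = truth$qtl_effects
  ), qtl_path)
  invisible(bv_path)
}
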