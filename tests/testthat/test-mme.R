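test_that("design matrices map records to animals and drop reference levels", {
  ped <- pedigree(c("s", "d", "b1", "b2"),
                  c(NA, NA, "s", "s"), c(NA, NA, "d", "d"))
  ph <- toy_pheno(c("b1", "b1", "b2"), c(1, 2, 3),
                  ys = c("y1", "y2", "y1"), st = c("s1", "s2", "s2"))
  des <- suppressWarnings(build_design(ph, ped))
  expect_equal(dim(des$Z_a), c(3L, 4L))
  expect_equal(Matrix::rowSums(des$Z_a), rep(1, 3), ignore_attr = TRUE)
  # intercept + (2-level year_season) + (2-level station) + age; the two
  # single-level factors are dropped with a warning
  expect_equal(ncol(des$X), 4L)
  warns <- testthat::capture_warnings(build_design(ph, ped))
  expect_length(warns, 2)
  expect_match(warns, "single level", all = TRUE)
  # recordless animals keep zero columns in Z_a
  expect_equal(unname(Matrix::colSums(des$Z_a)), c(0, 0, 2, 1))
  # W is records x animals-with-records
  expect_equal(dim(des$W), c(3L, 2L))
  expect_error(build_design(toy_pheno("ghost", 1), ped), "not in the pedigree")
})

test_that("pedigree BLUP solutions match the dense GLS oracle", {
  set.seed(42)
  ped <- random_pedigree(30, 7)
  n_rec <- sample(1:4, 30, replace = TRUE)
  bulls <- rep(ped$animal_id, n_rec)
  ph <- toy_pheno(bulls, rnorm(length(bulls), 10),
                  age = runif(length(bulls), 24, 120),
                  ys = sample(c("y1", "y2", "y3"), length(bulls), TRUE),
                  st = sample(c("s1", "s2"), length(bulls), TRUE))
  vc <- variance_components(1, 0.8, 2)
  des <- suppressWarnings(build_design(ph, ped))
  fit <- solve_mme(des, build_A_inverse(ped), vc)

  A <- build_A(ped)
  oracle <- gls_blup(des$y, des$X, des$Z_a, des$W, A, vc)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-6)
  expect_equal(unname(fit$gebv), oracle$a, tolerance = 1e-6)
  expect_equal(unname(fit$pe), oracle$p, tolerance = 1e-6)
  expect_lt(fit$convergence, 1e-8)
})

test_that("single-step fit with G = A22 at blend 0 equals pedigree BLUP", {
  set.seed(8)
  ped <- random_pedigree(30, 8)
  bulls <- rep(ped$animal_id, 2)
  ph <- toy_pheno(bulls, rnorm(length(bulls), 10),
                  age = runif(length(bulls), 24, 120),
                  ys = sample(c("y1", "y2"), length(bulls), TRUE))
  vc <- variance_components(1, 1, 3)
  des <- suppressWarnings(build_design(ph, ped))
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped)
  gids <- sample(ped$animal_id, 12)
  A22 <- extract_A22(A, gids)
  H <- build_H_inverse(Ainv, A22, A22, gids)
  fit_ss <- solve_mme(des, H, vc)
  fit_ped <- solve_mme(des, Ainv, vc)
  expect_equal(fit_ss$gebv, fit_ped$gebv, tolerance = 1e-6)
  oracle <- gls_blup(des$y, des$X, des$Z_a, des$W, A, vc)
  expect_equal(unname(fit_ss$gebv), oracle$a, tolerance = 1e-6)
})

test_that("noiseless fixed-effect data are recovered with zero GEBVs", {
  ped <- random_pedigree(20, 3)
  bulls <- rep(ped$animal_id, 2)
  set.seed(1)
  age <- runif(length(bulls), 24, 120)
  ys <- sample(c("y1", "y2"), length(bulls), TRUE)
  beta_star <- c(`(Intercept)` = 5, y2 = 2, age = 0.1)
  y <- 5 + 2 * (ys == "y2") + 0.1 * age
  ph <- toy_pheno(bulls, y, age = age, ys = ys)
  vc <- variance_components(1, 1, 1e-8)
  des <- suppressWarnings(build_design(ph, ped))
  fit <- solve_mme(des, build_A_inverse(ped), vc)
  expect_equal(unname(fit$beta), unname(beta_star), tolerance = 1e-4)
  expect_lt(max(abs(fit$gebv)), 1e-4)
})

test_that("animal and PE solutions stay finite and jointly stable when confounded", {
  # one record per animal: a and p are separable only through shrinkage;
  # their sum must be stable across very different sigma2_p values
  ped <- random_pedigree(25, 5)
  set.seed(2)
  ph <- toy_pheno(ped$animal_id, rnorm(25, 10))
  des <- suppressWarnings(build_design(ph, ped))
  Ainv <- build_A_inverse(ped)
  f1 <- solve_mme(des, Ainv, variance_components(1, 1e4, 1))
  f2 <- solve_mme(des, Ainv, variance_components(1, 1e6, 1))
  expect_true(all(is.finite(f1$gebv)) && all(is.finite(f1$pe)))
  sum1 <- f1$gebv[names(f1$pe)] + f1$pe
  sum2 <- f2$gebv[names(f2$pe)] + f2$pe
  expect_equal(sum1, sum2, tolerance = 1e-3)
})

test_that("GEBVs are invariant to a constant shift in the records", {
  ped <- random_pedigree(25, 6)
  set.seed(3)
  ph <- toy_pheno(rep(ped$animal_id, 2), rnorm(50, 10))
  des <- suppressWarnings(build_design(ph, ped))
  Ainv <- build_A_inverse(ped)
  vc <- variance_components(1, 1, 2)
  f1 <- solve_mme(des, Ainv, vc)
  des2 <- des
  des2$y <- des$y + 100
  f2 <- solve_mme(des2, Ainv, vc)
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-8)
  expect_equal(unname(f2$beta["(Intercept)"] - f1$beta["(Intercept)"]), 100,
               tolerance = 1e-8)
})

test_that("GEBV accuracy grows with the number of records per animal", {
  acc <- function(recs, seed) {
    cfg <- sim_config(n_founders = 30, n_generations = 2, n_matings = 20,
                      n_snps = 100, n_chromosomes = 1, n_qtl = 5,
                      records_per_animal = c(recs, recs), seed = seed)
    dat <- simulate_dataset(cfg)
    qc <- qc_filter_snps(dat$genotypes)
    ph <- suppressMessages(filter_phenotypes(dat$phenotypes, "VE"))
    gw <- run_wssgwas(dat$pedigree, qc$genotypes, ph, cfg$varcomp,
                      n_iter = 1, blend_alpha = 0.05)
    gids <- rownames(qc$genotypes$calls)
    cor(gw$final_fit$gebv[gids], dat$truth$true_bv[gids])
  }
  low <- vapply(1:10, function(s) acc(1, s), numeric(1))
  high <- vapply(1:10, function(s) acc(8, s), numeric(1))
  expect_true(all(high > 0))
  expect_gt(mean(low), 0)
  expect_gt(mean(high), mean(low))
})

test_that("reliability proxy reports record counts and flags recordless animals", {
  ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
  ph <- toy_pheno(c("o", "o"), c(1, 2))
  des <- suppressWarnings(build_design(ph, ped))
  fit <- solve_mme(des, build_A_inverse(ped), variance_components(1, 1, 1))
  rel <- reliability_proxy(fit, ph)
  expect_equal(nrow(rel), 3)
  expect_equal(rel$n_records[rel$animal_id == "o"], 2L)
  expect_true(all(rel$recordless[rel$animal_id %in% c("s", "d")]))
})
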