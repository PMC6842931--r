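toy_windows_input <- function(n_ind = 50, m = 15, seed = 1, chrom = NULL) {
  set.seed(seed)
  calls <- sapply(runif(m, 0.2, 0.5), function(p) rbinom(n_ind, 2, p))
  rownames(calls) <- sprintf("i%03d", seq_len(n_ind))
  map <- tibble::tibble(
    snp_id = sprintf("s%02d", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    pos_bp = as.numeric(seq_len(m) * 1e5)
  )
  g <- geno_matrix(calls, map)
  list(geno = g, Z = center_genotypes(g), map = map)
}

test_that("sliding windows have the right count, span and zero baseline", {
  tw <- toy_windows_input()
  # 15 SNPs, size 10, step 1 -> 6 windows on one chromosome
  w <- window_variance(tw$Z, rep(0, 15), sigma2_a = 1, map = tw$map)
  expect_equal(nrow(w), 6)
  expect_true(all(w$pct_variance == 0))
  expect_true(all(w$end_snp - w$start_snp + 1 == 10))
  expect_equal(w$start_bp, tw$map$pos_bp[w$start_snp])
  expect_equal(w$end_bp, tw$map$pos_bp[w$end_snp])

  # windows never span chromosomes
  tw2 <- toy_windows_input(m = 24, chrom = rep(1:2, each = 12))
  w2 <- window_variance(tw2$Z, rnorm(24), sigma2_a = 1, map = tw2$map)
  expect_equal(nrow(w2), 6)
  expect_true(all(tw2$map$chrom[w2$start_snp] == tw2$map$chrom[w2$end_snp]))

  # short chromosome: one truncated window, with a warning
  tw3 <- toy_windows_input(m = 14, chrom = c(rep(1L, 10), rep(2L, 4)))
  expect_warning(w3 <- window_variance(tw3$Z, rnorm(14), sigma2_a = 1,
                                       map = tw3$map),
                 "truncated")
  expect_equal(sum(w3$chromosome == 2), 1)
  expect_equal(w3$n_snps[w3$chromosome == 2], 4L)
})

test_that("window variance equals the brute-force variance of summed values", {
  tw <- toy_windows_input(n_ind = 300, m = 15, seed = 3)
  u <- rep(0, 15)
  u[7] <- 0.8 # single causal SNP inside every window that covers column 7
  s2a <- 2
  w <- window_variance(tw$Z, u, sigma2_a = s2a, map = tw$map)
  covering <- w$start_snp <= 7 & w$end_snp >= 7
  direct <- stats::var(tw$Z[, 7] * 0.8) / s2a * 100
  expect_equal(w$pct_variance[covering], rep(direct, sum(covering)))
  # and the observed variance tracks the HWE expectation 2p(1-p) s^2
  p <- mean(tw$geno$calls[, 7]) / 2
  expect_equal(direct, 2 * p * (1 - p) * 0.64 / s2a * 100, tolerance = 0.1)
  # within-window SNP reordering leaves the window variance unchanged
  tw1 <- toy_windows_input(n_ind = 100, m = 10, seed = 4)
  u1 <- rnorm(10, 0, 0.3)
  w1 <- window_variance(tw1$Z, u1, sigma2_a = s2a, map = tw1$map)
  perm <- sample(10)
  w1p <- window_variance(tw1$Z[, perm], u1[perm], sigma2_a = s2a,
                         map = tw1$map)
  expect_equal(w1p$pct_variance, w1$pct_variance, tolerance = 1e-12)
})

test_that("top windows rank, tie-break and prune overlapping regions", {
  tw <- toy_windows_input(n_ind = 200, m = 30, seed = 5)
  set.seed(6)
  u <- rnorm(30, 0, 0.05)
  u[12] <- 1.5
  w <- window_variance(tw$Z, u, sigma2_a = 1, map = tw$map)
  t1 <- top_windows(w, n = 1)
  expect_equal(t1$pct_variance, max(w$pct_variance))
  expect_equal(t1$rank, 1L)
  # pruned selections never share a SNP
  t5 <- top_windows(w, n = 5)
  if (nrow(t5) > 1) {
    for (i in 2:nrow(t5)) {
      expect_true(all(t5$start_snp[1:(i - 1)] > t5$end_snp[i] |
                        t5$end_snp[1:(i - 1)] < t5$start_snp[i] |
                        t5$chromosome[1:(i - 1)] != t5$chromosome[i]))
    }
  }
  # unpruned: n larger than the list returns the whole list
  expect_equal(nrow(top_windows(w, n = 1000, prune = FALSE)), nrow(w))
})

test_that("variance classes partition the windows with lower-edge closure", {
  w <- tibble::tibble(
    chromosome = 1L, start_snp = 1:6, end_snp = 2:7,
    start_bp = 1:6 * 1e5, end_bp = 2:7 * 1e5, n_snps = 2L,
    var_window = 0, pct_variance = c(0, 0.1, 0.3, 0.5, 1, 2)
  )
  cl <- classify_windows(w)
  expect_equal(sum(cl$n_windows), nrow(w))
  expect_equal(cl$n_windows[cl$class == ">1%"], 1L) # only 2 (1 is lower edge)
  expect_equal(cl$n_windows[cl$class == "0.5-1%"], 1L) # only 1
  expect_equal(cl$n_windows[cl$class == "0.1-0.5%"], 2L) # 0.3 and 0.5
  expect_equal(cl$n_windows[cl$class == "<0.1%"], 2L) # 0 and 0.1
  expect_equal(sum(cl$prop_windows), 1)
  expect_equal(sum(cl$prop_variance), 1)
  # all-zero effects: everything lands below 0.1%
  w0 <- dplyr::mutate(w, pct_variance = 0)
  cl0 <- classify_windows(w0)
  expect_equal(cl0$n_windows[cl0$class == "<0.1%"], nrow(w0))
})

test_that("cross-trait overlap merges intersecting regions only", {
  mk <- function(chrom, s, e, pct) tibble::tibble(
    chromosome = chrom, start_snp = 1L, end_snp = 10L,
    start_bp = s, end_bp = e, n_snps = 10L, var_window = 0,
    pct_variance = pct, rank = 1L
  )
  # identical windows in two traits: one region, two traits
  ov <- overlap_across_traits(list(VE = mk(5, 1e6, 2e6, 3),
                                   SC = mk(5, 1e6, 2e6, 2)))
  expect_equal(length(unique(ov$region)), 1)
  expect_equal(unique(ov$n_traits), 2L)
  expect_setequal(ov$trait, c("VE", "SC"))

  # disjoint chromosomes: nothing overlaps
  expect_equal(nrow(overlap_across_traits(list(VE = mk(1, 1e6, 2e6, 3),
                                               SC = mk(2, 1e6, 2e6, 2)))), 0)
  # adjacency without intersection is not overlap
  expect_equal(nrow(overlap_across_traits(list(VE = mk(1, 1e6, 2e6, 3),
                                               SC = mk(1, 2e6 + 1, 3e6, 2)))),
               0)
  # transitive merging across three traits
  ov3 <- overlap_across_traits(list(VE = mk(3, 1e6, 2e6, 3),
                                    SC = mk(3, 1.5e6, 2.5e6, 2),
                                    MS = mk(3, 2.4e6, 3e6, 1)))
  expect_equal(length(unique(ov3$region)), 1)
  expect_equal(unique(ov3$n_traits), 3L)
  expect_equal(unique(ov3$start_bp), 1e6)
  expect_equal(unique(ov3$end_bp), 3e6)
})

test_that("manhattan export orders windows on a strictly increasing coordinate", {
  tw <- toy_windows_input(m = 24, chrom = rep(1:2, each = 12))
  w <- window_variance(tw$Z, rnorm(24), sigma2_a = 1, map = tw$map)
  f <- withr::local_tempfile()
  out <- manhattan_export(w, f)
  expect_equal(nrow(out), nrow(w))
  expect_true(all(diff(out$cum_bp) > 0))
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$cum_bp, out$cum_bp)
  p <- autoplot(w)
  expect_s3_class(p, "ggplot")
})

test_that("non-overlapping windows nearly partition the total genetic variance", {
  # unlinked loci (independent individuals): covariances across windows ~ 0
  tw <- toy_windows_input(n_ind = 400, m = 100, seed = 9)
  set.seed(10)
  u <- rnorm(100, 0, 0.1)
  w <- window_variance(tw$Z, u, sigma2_a = 1, window_size = 10, step = 10,
                       map = tw$map)
  expect_equal(nrow(w), 10)
  total <- stats::var(as.numeric(tw$Z %*% u))
  expect_lt(abs(sum(w$var_window) - total) / total, 0.1)
})
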