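# Shared fixtures and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random pedigree with mixed known/unknown parents; parents are always
# earlier animals, so the construction order is already topological.
random_pedigree <- function(n, seed, p_both = 0.7, p_one = 0.3) {
  set.seed(seed)
  ids <- sprintf("a%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    u <- runif(1)
    if (u < p_both) {
      pair <- sample(i - 1L, 2L)
      sire[i] <- ids[pair[1L]]
      dam[i] <- ids[pair[2L]]
    } else if (u < p_both + p_one) {
      sire[i] <- ids[sample(i - 1L, 1L)]
    }
  }
  ped <- wssgwas::pedigree(ids, sire, dam, sort = FALSE)
  ped
}

# Dense GLS oracle for the repeatability animal model with a ~ N(0, K s2a):
# textbook BLUE/BLUP through V = s2a Z K Z' + s2p W W' + s2e I. Independent
# of the sparse MME path (no Henderson equations, no K inverse).
gls_blup <- function(y, X, Za, W, K, vc) {
  X <- as.matrix(X)
  Za <- as.matrix(Za)
  W <- as.matrix(W)
  V <- vc$sigma2_a * Za %*% K %*% t(Za) +
    vc$sigma2_p * tcrossprod(W) +
    vc$sigma2_e * diag(length(y))
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  list(
    beta = as.numeric(beta),
    a = as.numeric(vc$sigma2_a * K %*% crossprod(Za, Vi %*% r)),
    p = as.numeric(vc$sigma2_p * crossprod(W, Vi %*% r))
  )
}

# Gini coefficient of a nonnegative vector (weight concentration measure)
gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

# small synthetic config used across tests (fast: ~150 animals, 400 SNPs)
small_sim <- function(seed, ...) {
  wssgwas::sim_config(
    n_founders = 30, n_generations = 3, n_matings = 20,
    offspring_per_mating = 2, n_snps = 400, n_chromosomes = 2,
    n_qtl = 3, qtl_variance_fraction = 0.45, qtl_equal_var = TRUE,
    records_per_animal = c(3, 10), seed = seed, ...
  )
}

# toy phenotype table: one row per (animal, record); default ages vary so
# the age covariate is never collinear with the intercept
toy_pheno <- function(bulls, values, age = NULL,
                      ys = "y1", st = "s1", iv = "i1", cc = "c1") {
  age <- age %||% seq(30, 120, length.out = length(bulls))
  tibble::tibble(
    bull_id = bulls, trait = "VE", value = values,
    year_season = rep_len(ys, length(bulls)),
    station = rep_len(st, length(bulls)),
    interval_class = rep_len(iv, length(bulls)),
    collection_class = rep_len(cc, length(bulls)),
    age_months = rep_len(age, length(bulls))
  )
}

# QTL hit helper: does any selected window contain the QTL snp (matched by id)?
qtl_hits <- function(top, map, qtl_snp_ids) {
  vapply(qtl_snp_ids, function(sid) {
    k <- match(sid, map$snp_id)
    if (is.na(k)) return(FALSE)
    any(top$chromosome == map$chrom[k] &
          top$start_snp <= k & top$end_snp >= k)
  }, logical(1))
}
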