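#' Backsolve SNP effects from genotyped animals' GEBVs
#'
#' Converts the animal-level additive solutions of genotyped animals into
#' per-SNP effects via `u = q D Z' G^-1 a_g`, where `Z` is the centered
#' marker matrix, `D` the SNP-weight diagonal and `q` the G scaling factor
#' (the conversion constant lambda equals `q`, the only choice under which
#' `Z u = a_g` holds exactly for the unblended `G = Z D Z' q`).
#'
#' @param a_g named GEBV vector of the genotyped animals (order of `Z` rows).
#' @param Z centered marker matrix of the genotyped animals.
#' @param w the [snp_weights()] used to build `G`.
#' @param G the (possibly blended) genomic relationship matrix used in the
#'   solve, ids matching `Z` rows.
#' @return numeric vector of SNP effects, one per column of `Z`.
#' @export
backsolve_snp_effects <- function(a_g, Z, w, G) {
  if (length(a_g) != nrow(Z)) abort("length(a_g) must equal nrow(Z)")
  if (!all(dim(G) == nrow(Z))) abort("G must be square over the Z rows")
  if (!is.null(names(a_g)) && !is.null(rownames(G))) {
    a_g <- a_g[rownames(G)]
  }
  Ginv_a <- tryCatch(solve(G, a_g), error = function(e) {
    abort(paste0("G is singular in the backsolve (", conditionMessage(e), ")"))
  })
  as.numeric(w$q * w$d * crossprod(Z, Ginv_a))
}

#' SNP weights from effects: d_i = u_i^2 * 2 p_i (1 - p_i)
#'
#' @param u_hat SNP effects.
#' @param freqs per-SNP allele frequencies in (0, 1).
#' @return raw (unnormalized) weight vector.
#' @export
update_weights <- function(u_hat, freqs) {
  if (length(u_hat) != length(freqs)) abort("u_hat and freqs lengths differ")
  if (any(freqs <= 0 | freqs >= 1)) abort("freqs must be strictly in (0, 1)")
  u_hat^2 * 2 * freqs * (1 - freqs)
}

#' Normalize SNP weights to keep the total genetic variance constant
#'
#' Rescales the raw weights so their sum equals the SNP count `m`, the total
#' under the first iteration's `D = I`.
#'
#' @param d_raw nonnegative weights.
#' @return normalized weights summing to `length(d_raw)`.
#' @export
normalize_weights <- function(d_raw) {
  s <- sum(d_raw)
  if (!is.finite(s) || s <= 0) {
    abort("all SNP weights are zero; no genetic signal to reweight")
  }
  d_raw * length(d_raw) / s
}

#' Weighted single-step GWAS: iterate solve, backsolve, reweight
#'
#' Runs the weighting loop: iteration 1 solves the single-step mixed model
#' with `D = I`, backsolves the genotyped animals' GEBVs into SNP effects and
#' computes weights `d_i = u_i^2 2 p_i (1 - p_i)`; each further iteration
#' normalizes the weights, rebuilds `G` and `H^-1`, re-solves and
#' re-backsolves. The default `n_iter = 2` performs one reweighting pass
#' (two solves), the usual choice when further iterations start overfitting
#' large-effect regions.
#'
#' @param ped pedigree covering all animals.
#' @param geno QC-passed [geno_matrix()] of the genotyped animals.
#' @param pheno filtered phenotype tibble of one trait.
#' @param vc [variance_components()].
#' @param n_iter number of solve/backsolve iterations (>= 1).
#' @param blend_alpha blending of G toward A22 (see [build_G()]).
#' @param fixed,covariates model columns, see [build_design()].
#' @return object of class `wss_gwas`: list with `iterations` (each holding
#'   `u_hat`, the weights `d` used in its solve, the updated normalized
#'   weights `d_next`, and the `wss_fit`), `final_fit`, `snp_map`, `freqs`,
#'   `Z` (centered markers), and a config echo.
#' @export
run_wssgwas <- function(ped, geno, pheno, vc, n_iter = 2, blend_alpha = 0.05,
                        fixed = c("year_season", "station",
                                  "interval_class", "collection_class"),
                        covariates = "age_months") {
  if (n_iter < 1) abort("n_iter must be >= 1")
  ped <- assert_sorted_pedigree(ped)
  genotyped_ids <- rownames(geno$calls)
  A <- build_A(ped)
  A22 <- extract_A22(A, genotyped_ids)
  Ainv <- build_A_inverse(ped)
  design <- build_design(pheno, ped, fixed = fixed, covariates = covariates)

  w <- snp_weights(geno)
  Z <- center_genotypes(geno, w$freqs)
  iterations <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    G <- build_G(geno, w, blend_alpha = blend_alpha, A22 = A22)
    Hinv <- build_H_inverse(Ainv, A22, G, genotyped_ids)
    fit <- solve_mme(design, Hinv, vc)
    a_g <- fit$gebv[genotyped_ids]
    u_hat <- backsolve_snp_effects(a_g, Z, w, G)
    d_next <- normalize_weights(update_weights(u_hat, w$freqs))
    iterations[[it]] <- list(iteration = it, u_hat = u_hat, d = w$d,
                             d_next = d_next, fit = fit)
    w <- snp_weights(geno, d = d_next)
  }
  structure(list(
    iterations = iterations,
    final_fit = iterations[[n_iter]]$fit,
    u_hat = iterations[[n_iter]]$u_hat,
    snp_map = geno$map,
    freqs = snp_weights(geno)$freqs,
    Z = Z,
    config = list(n_iter = n_iter, blend_alpha = blend_alpha,
                  vc = vc, n_genotyped = length(genotyped_ids),
                  n_animals = nrow(ped), n_snps = ncol(geno$calls))
  ), class = "wss_gwas")
}

#' @exportS3Method base::print
print.wss_gwas <- function(x, ...) {
  cat("<wss_gwas> ", x$config$n_iter, " iteration(s), ",
      x$config$n_snps, " SNPs, ", x$config$n_genotyped, "/",
      x$config$n_animals, " animals genotyped\n", sep = "")
  invisible(x)
}

#' Tidy per-SNP effects and weights across iterations
#'
#' @param x a `wss_gwas` from [run_wssgwas()].
#' @param ... unused.
#' @return tibble with `iteration`, `snp_id`, `chrom`, `pos_bp`, `u_hat`,
#'   `weight` (the normalized weight computed *from* that iteration's
#'   effects).
#' @method tidy wss_gwas
#' @export
tidy.wss_gwas <- function(x, ...) {
  purrr::map_dfr(x$iterations, function(itr) {
    tibble(
      iteration = itr$iteration,
      snp_id = x$snp_map$snp_id,
      chrom = x$snp_map$chrom,
      pos_bp = x$snp_map$pos_bp,
      u_hat = itr$u_hat,
      weight = itr$d_next
    )
  })
}

#' One-row summary of a WssGWAS run
#' @param x a `wss_gwas`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance wss_gwas
#' @export
glance.wss_gwas <- function(x, ...) {
  tibble(
    n_iter = x$config$n_iter,
    n_snps = x$config$n_snps,
    n_genotyped = x$config$n_genotyped,
    n_animals = x$config$n_animals,
    blend_alpha = x$config$blend_alpha,
    convergence = x$final_fit$convergence
  )
}

#' Write per-iteration SNP effects and weights as TSV
#'
#' @param x a `wss_gwas`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_effects <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
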