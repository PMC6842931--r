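#' Design matrices for the repeatability animal model
#'
#' Builds `y = X b + Z_a a + W p + e` from a filtered phenotype table:
#' `X` holds an intercept, reference-level (first level dropped) dummy
#' columns for each fixed factor and the age covariate; `Z_a` maps each
#' record to its animal among *all* pedigree animals (recordless ancestors
#' get zero columns but remain estimable through relationships); `W` maps
#' each record to its animal among the animals that have records.
#'
#' Factors observed at a single level carry no information under reference
#' coding and are dropped with a warning.
#'
#' @param pheno filtered phenotype tibble (one trait).
#' @param ped the pedigree covering every recorded bull.
#' @param fixed character vector of factor column names.
#' @param covariates character vector of numeric covariate column names.
#' @return list with `y`, dense `X`, sparse `Z_a` and `W`, plus
#'   `animal_ids` (pedigree order) and `record_animal_ids` (columns of `W`).
#' @export
build_design <- function(pheno, ped,
                         fixed = c("year_season", "station",
                                   "interval_class", "collection_class"),
                         covariates = "age_months") {
  ped <- assert_sorted_pedigree(ped)
  unknown <- setdiff(unique(pheno$bull_id), ped$animal_id)
  if (length(unknown) > 0) {
    abort(paste0("record(s) for animal(s) not in the pedigree: ",
                 paste(unknown, collapse = ", ")))
  }
  n_rec <- nrow(pheno)
  if (n_rec == 0) abort("no records")

  keep_fixed <- character(0)
  for (f in fixed) {
    if (!f %in% names(pheno)) abort(paste0("missing factor column: ", f))
    if (length(unique(pheno[[f]])) < 2) {
      warn(paste0("factor '", f, "' has a single level; dropped from X"))
    } else {
      keep_fixed <- c(keep_fixed, f)
    }
  }
  terms <- c(keep_fixed, covariates)
  fml <- stats::as.formula(
    paste("~", if (length(terms)) paste(terms, collapse = " + ") else "1")
  )
  df <- as.data.frame(pheno)
  for (f in keep_fixed) df[[f]] <- factor(df[[f]])
  X <- model.matrix(fml, data = df)

  animal_ids <- ped$animal_id
  Za <- Matrix::sparseMatrix(
    i = seq_len(n_rec),
    j = match(pheno$bull_id, animal_ids),
    x = 1,
    dims = c(n_rec, length(animal_ids)),
    dimnames = list(NULL, animal_ids)
  )
  rec_ids <- unique(pheno$bull_id)
  W <- Matrix::sparseMatrix(
    i = seq_len(n_rec),
    j = match(pheno$bull_id, rec_ids),
    x = 1,
    dims = c(n_rec, length(rec_ids)),
    dimnames = list(NULL, rec_ids)
  )
  list(y = pheno$value, X = X, Z_a = Za, W = W,
       animal_ids = animal_ids, record_animal_ids = rec_ids)
}

#' Variance components of the repeatability model
#'
#' @param sigma2_a additive genetic variance (trait units squared).
#' @param sigma2_p permanent-environment variance.
#' @param sigma2_e residual variance.
#' @return list of class `wss_varcomp`.
#' @export
variance_components <- function(sigma2_a, sigma2_p, sigma2_e) {
  for (v in c(sigma2_a, sigma2_p, sigma2_e)) {
    stopifnot_scalar_number(v, "variance component")
    if (v <= 0) abort("variance components must be strictly positive")
  }
  structure(list(sigma2_a = sigma2_a, sigma2_p = sigma2_p,
                 sigma2_e = sigma2_e),
            class = "wss_varcomp")
}

#' Solve Henderson's mixed-model equations for the single-step model
#'
#' Assembles and solves
#' \deqn{
#'   \begin{pmatrix} X'X & X'Z & X'W \\ Z'X & Z'Z + H^{-1}\lambda_a & Z'W \\
#'   W'X & W'Z & W'W + I\lambda_p \end{pmatrix}
#'   \begin{pmatrix} \hat b \\ \hat a \\ \hat p \end{pmatrix} =
#'   \begin{pmatrix} X'y \\ Z'y \\ W'y \end{pmatrix}
#' }
#' with \eqn{\lambda_a = \sigma^2_e/\sigma^2_a} and
#' \eqn{\lambda_p = \sigma^2_e/\sigma^2_p}, by sparse Cholesky factorization
#' (LU fallback). `H^-1` may be a plain pedigree `A^-1` (pedigree BLUP) or
#' the single-step inverse from [build_H_inverse()].
#'
#' @param design list from [build_design()].
#' @param Hinv sparse inverse relationship matrix over all pedigree animals,
#'   ids matching `design$animal_ids`.
#' @param vc a [variance_components()] object.
#' @return object of class `wss_fit`: `beta` (named), `gebv` (named vector
#'   over all pedigree animals), `pe` (named, animals with records),
#'   `convergence` (relative residual of the solved system), `vc`, `n_records`.
#' @export
solve_mme <- function(design, Hinv, vc) {
  X <- design$X
  Za <- design$Z_a
  W <- design$W
  y <- design$y
  if (!identical(rownames(Hinv), design$animal_ids)) {
    Hinv <- Hinv[design$animal_ids, design$animal_ids]
  }
  lambda_a <- vc$sigma2_e / vc$sigma2_a
  lambda_p <- vc$sigma2_e / vc$sigma2_p

  Xs <- as(X, "CsparseMatrix")
  C11 <- Matrix::crossprod(Xs)
  C12 <- Matrix::crossprod(Xs, Za)
  C13 <- Matrix::crossprod(Xs, W)
  C22 <- Matrix::crossprod(Za) + lambda_a * Hinv
  C23 <- Matrix::crossprod(Za, W)
  C33 <- Matrix::crossprod(W) + lambda_p * Matrix::Diagonal(ncol(W))
  C <- rbind(
    cbind(C11, C12, C13),
    cbind(Matrix::t(C12), C22, C23),
    cbind(Matrix::t(C13), Matrix::t(C23), C33)
  )
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(Za, y)),
           as.numeric(Matrix::crossprod(W, y)))
  if (any(!is.finite(C@x)) || any(!is.finite(rhs))) {
    abort("non-finite entries in the mixed-model equations")
  }
  Csym <- Matrix::forceSymmetric(C)
  sol <- tryCatch(
    as.numeric(Matrix::solve(Csym, rhs)),
    error = function(e) as.numeric(Matrix::solve(as(C, "generalMatrix"), rhs))
  )
  resid <- as.numeric(Csym %*% sol) - rhs
  convergence <- sqrt(sum(resid^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)

  p1 <- ncol(X)
  p2 <- ncol(Za)
  beta <- setNames(sol[seq_len(p1)], colnames(X))
  gebv <- setNames(sol[p1 + seq_len(p2)], design$animal_ids)
  pe <- setNames(sol[p1 + p2 + seq_len(ncol(W))], design$record_animal_ids)
  structure(list(beta = beta, gebv = gebv, pe = pe,
                 convergence = convergence, vc = vc,
                 lambda = c(a = lambda_a, p = lambda_p),
                 n_records = length(y)),
            class = "wss_fit")
}

#' @exportS3Method base::print
print.wss_fit <- function(x, ...) {
  cat("<wss_fit> single-step repeatability model\n",
      "  records: ", x$n_records, ", animals: ", length(x$gebv),
      " (", length(x$pe), " with records)\n",
      "  fixed effects: ", length(x$beta), " columns\n",
      "  relative residual of MME solve: ", format(x$convergence), "\n",
      sep = "")
  invisible(x)
}

#' Tidy animal solutions of a single-step fit
#'
#' @param x a `wss_fit` from [solve_mme()].
#' @param effects which solutions to return: `"animal"` (GEBV),
#'   `"fixed"`, or `"pe"` (permanent environment).
#' @param ... unused.
#' @return tibble with `term`, `level`, `estimate`.
#' @method tidy wss_fit
#' @export
tidy.wss_fit <- function(x, effects = c("animal", "fixed", "pe"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    animal = tibble(term = "animal", level = names(x$gebv),
                    estimate = unname(x$gebv)),
    fixed = tibble(term = "fixed", level = names(x$beta),
                   estimate = unname(x$beta)),
    pe = tibble(term = "pe", level = names(x$pe), estimate = unname(x$pe))
  )
}

#' One-row summary of a single-step fit
#' @param x a `wss_fit`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance wss_fit
#' @export
glance.wss_fit <- function(x, ...) {
  tibble(
    n_records = x$n_records,
    n_animals = length(x$gebv),
    n_fixed = length(x$beta),
    lambda_a = unname(x$lambda["a"]),
    lambda_p = unname(x$lambda["p"]),
    convergence = x$convergence
  )
}

#' Per-animal prediction diagnostics
#'
#' Reports each pedigree animal's record count and GEBV next to the
#' shrinkage context (animals with zero records are predicted purely through
#' relationships and are flagged).
#'
#' @param fit a `wss_fit`.
#' @param pheno the phenotype table the fit used.
#' @return tibble with `animal_id`, `n_records`, `gebv`, `pe`,
#'   `recordless` flag.
#' @export
reliability_proxy <- function(fit, pheno) {
  counts <- table(pheno$bull_id)
  n_rec <- as.integer(counts[names(fit$gebv)])
  n_rec[is.na(n_rec)] <- 0L
  tibble(
    animal_id = names(fit$gebv),
    n_records = n_rec,
    gebv = unname(fit$gebv),
    pe = unname(fit$pe[names(fit$gebv)]),
    recordless = n_rec == 0L
  )
}
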