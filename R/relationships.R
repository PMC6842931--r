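#' Numerator relationship matrix A (tabular method)
#'
#' Builds the dense pedigree relationship matrix by the tabular recursion:
#' for animal `j` with parents `s`, `d` (unknown parents contribute 0),
#' `a_ij = (a_is + a_id) / 2` for earlier-born `i` and
#' `a_jj = 1 + a_sd / 2`. The diagonal is `1 + F` with `F` the inbreeding
#' coefficient.
#'
#' @param ped a topologically sorted [pedigree()].
#' @return symmetric numeric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  ped <- assert_sorted_pedigree(ped)
  ix <- ped_indices(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal_id, ped$animal_id))
  for (j in seq_len(n)) {
    s <- ix$sire[j]
    d <- ix$dam[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      row <- numeric(j - 1L)
      if (s > 0L) row <- row + A[i, s]
      if (d > 0L) row <- row + A[i, d]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  A
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes `F_i = a_{sire(i), dam(i)} / 2` for every animal without forming
#' the dense A matrix, using the L-matrix recursion with Mendelian sampling
#' variances `d_j = 1/2 - (F_s + F_d)/4` (an unknown parent enters with
#' `F = -1`, so founders have `d = 1`). Animals with an unknown parent get
#' `F = 0`.
#'
#' @param ped a topologically sorted [pedigree()].
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  ped <- assert_sorted_pedigree(ped)
  ix <- ped_indices(ped)
  sire <- ix$sire
  dam <- ix$dam
  n <- nrow(ped)
  FF <- numeric(n)
  # F of the "unknown parent" is -1 so that d = 0.5 - 0.25*(F_s + F_d)
  # evaluates to 1 for founders and 0.75 - F_known/4 for one known parent
  f_of <- function(k) if (k == 0L) -1 else FF[k]
  L <- numeric(n)
  POINT <- integer(n)
  for (i in seq_len(n)) {
    S <- sire[i]
    D <- dam[i]
    if (S == 0L || D == 0L) {
      FF[i] <- 0
      next
    }
    if (i > 1L && S == sire[i - 1L] && D == dam[i - 1L]) {
      FF[i] <- FF[i - 1L] # full sibs share F
      next
    }
    FI <- -1
    L[i] <- 1
    j <- i
    while (j != 0L) {
      k <- j
      r <- 0.5 * L[k]
      # the linked list is kept in decreasing index order, so the
      # larger-indexed parent must be inserted first
      KS <- max(sire[k], dam[k])
      KD <- min(sire[k], dam[k])
      if (KS > 0L) {
        while (POINT[k] > KS) k <- POINT[k]
        L[KS] <- L[KS] + r
        if (KS != POINT[k]) {
          POINT[KS] <- POINT[k]
          POINT[k] <- KS
        }
        if (KD > 0L) {
          while (POINT[k] > KD) k <- POINT[k]
          L[KD] <- L[KD] + r
          if (KD != POINT[k]) {
            POINT[KD] <- POINT[k]
            POINT[k] <- KD
          }
        }
      }
      dj <- 0.5 - 0.25 * (f_of(KS) + f_of(KD))
      FI <- FI + L[j]^2 * dj
      L[j] <- 0
      ks <- POINT[j]
      POINT[j] <- 0L
      j <- ks
    }
    FF[i] <- FI
  }
  setNames(FF, ped$animal_id)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson-rule assembly of `A^-1` accounting for inbreeding: each animal
#' contributes `alpha_i = 1/d_i` (with `d_i` the Mendelian sampling variance
#' `1/2 - (F_s + F_d)/4`, adapted when a parent is unknown) to its own
#' diagonal, `-alpha_i/2` to animal-parent cells and `alpha_i/4` to
#' parent-parent cells. The dense A is never formed.
#'
#' @param ped a topologically sorted [pedigree()].
#' @return sparse symmetric `Matrix::dsCMatrix` with animal ids as dimnames.
#' @export
build_A_inverse <- function(ped) {
  ped <- assert_sorted_pedigree(ped)
  ix <- ped_indices(ped)
  FF <- inbreeding(ped)
  f_of <- function(k) ifelse(k == 0L, -1, FF[pmax(k, 1L)])
  dd <- 0.5 - 0.25 * (f_of(ix$sire) + f_of(ix$dam))
  alpha <- 1 / dd
  n <- nrow(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  js <- seq_len(n)
  add(js, js, alpha)
  for (p in list(ix$sire, ix$dam)) {
    has <- p > 0L
    add(js[has], p[has], -alpha[has] / 2)
    add(p[has], js[has], -alpha[has] / 2)
    add(p[has], p[has], alpha[has] / 4)
  }
  both <- ix$sire > 0L & ix$dam > 0L
  add(ix$sire[both], ix$dam[both], alpha[both] / 4)
  add(ix$dam[both], ix$sire[both], alpha[both] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal_id, ped$animal_id))
  Matrix::forceSymmetric(Ainv)
}

#' Pedigree relationships among genotyped animals (A22)
#'
#' Principal submatrix of A for the genotyped animals, in the order given.
#'
#' @param A dense relationship matrix from [build_A()].
#' @param genotyped_ids character vector of genotyped animal ids.
#' @return dense symmetric matrix.
#' @export
extract_A22 <- function(A, genotyped_ids) {
  missing_ids <- setdiff(genotyped_ids, rownames(A))
  if (length(missing_ids) > 0) {
    abort(paste0("genotyped id(s) not in pedigree: ",
                 paste(missing_ids, collapse = ", ")))
  }
  A[genotyped_ids, genotyped_ids, drop = FALSE]
}

#' SNP weights, allele frequencies and the G scaling factor
#'
#' Holds the diagonal `D` of SNP variance weights (initially all 1), the
#' observed allele frequencies `p_i` used to center the marker matrix, and
#' the scaling factor `q = 1 / sum(2 p_i (1 - p_i))` that puts `G = Z D Z' q`
#' on the unit-diagonal scale.
#'
#' Note that centering by the observed frequencies makes every column of `Z`
#' sum to zero, so the raw `G` always has the all-ones vector in its null
#' space; an invertible unblended `G` requires externally supplied (base
#' population) frequencies, otherwise blend toward A22 (see [build_G()]).
#'
#' @param g a QC-passed [geno_matrix()].
#' @param d optional weight vector (default all ones).
#' @param freqs optional per-SNP allele frequencies in (0, 1) (for example
#'   base-population frequencies); default: observed frequencies.
#' @return object of class `wss_snp_weights`: list with `d`, `q`, `freqs`.
#' @export
snp_weights <- function(g, d = NULL, freqs = NULL) {
  p <- freqs %||% (colMeans(g$calls, na.rm = TRUE) / 2)
  if (length(p) != ncol(g$calls)) abort("freqs must have one entry per SNP")
  if (any(p <= 0 | p >= 1)) {
    abort("monomorphic SNP present (p = 0 or 1); run qc_filter_snps() first")
  }
  m <- ncol(g$calls)
  d <- d %||% rep(1, m)
  if (length(d) != m || any(d < 0) || any(!is.finite(d))) {
    abort("weights d must be nonnegative finite, one per SNP")
  }
  structure(list(d = unname(d), q = 1 / sum(2 * p * (1 - p)),
                 freqs = unname(p)),
            class = "wss_snp_weights")
}

#' Center a marker matrix by twice the allele frequency
#'
#' @param g a [geno_matrix()].
#' @param freqs per-SNP allele frequencies (defaults to observed).
#' @return numeric matrix `Z` with columns `call - 2 p_i`.
#' @export
center_genotypes <- function(g, freqs = NULL) {
  p <- freqs %||% (colMeans(g$calls, na.rm = TRUE) / 2)
  sweep(g$calls, 2L, 2 * p, `-`)
}

#' Genomic relationship matrix G = Z D Z' q (optionally blended with A22)
#'
#' `Z` is the marker matrix centered by `2 p_i`, `D` the diagonal SNP-weight
#' matrix and `q = 1 / sum(2 p_i (1 - p_i))`. With `blend_alpha > 0` the
#' returned matrix is `(1 - blend_alpha) G_raw + blend_alpha A22`, which keeps
#' G invertible on panels with fewer individuals than SNPs.
#'
#' @param g a QC-passed [geno_matrix()].
#' @param w a [snp_weights()] object (default: `D = I`, observed frequencies).
#' @param blend_alpha blending fraction toward A22 in `[0, 1)`; 0 = raw G.
#' @param A22 pedigree relationships of the genotyped animals (required when
#'   `blend_alpha > 0`), ids matching `rownames(g$calls)`.
#' @return dense symmetric matrix with individual ids as dimnames.
#' @export
build_G <- function(g, w = NULL, blend_alpha = 0, A22 = NULL) {
  w <- w %||% snp_weights(g)
  if (blend_alpha < 0 || blend_alpha >= 1) {
    abort("blend_alpha must be in [0, 1)")
  }
  Z <- center_genotypes(g, w$freqs)
  G <- tcrossprod(Z %*% Matrix::Diagonal(x = w$d), Z) * w$q
  G <- as.matrix(G)
  dimnames(G) <- list(rownames(g$calls), rownames(g$calls))
  if (blend_alpha > 0) {
    if (is.null(A22)) abort("blend_alpha > 0 requires A22")
    A22 <- A22[rownames(G), colnames(G)]
    G <- (1 - blend_alpha) * G + blend_alpha * A22
  }
  (G + t(G)) / 2
}

#' Inverse of the single-step relationship matrix H
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`: the pedigree inverse plus a
#' correction confined to the genotyped-by-genotyped block.
#'
#' @param Ainv sparse `A^-1` over all pedigree animals ([build_A_inverse()]).
#' @param A22 pedigree relationships among genotyped animals.
#' @param G genomic relationship matrix ([build_G()]), same ids as `A22`.
#' @param genotyped_ids ids of the genotyped animals (rows of `G`).
#' @return sparse symmetric matrix over all pedigree animals, with attribute
#'   `genotyped_ids`.
#' @export
build_H_inverse <- function(Ainv, A22, G, genotyped_ids) {
  ids <- rownames(Ainv)
  if (length(genotyped_ids) == 0) {
    H <- Ainv
    attr(H, "genotyped_ids") <- character(0)
    return(H)
  }
  if (!all(genotyped_ids %in% ids)) {
    abort("genotyped ids must be a subset of the pedigree ids")
  }
  G <- G[genotyped_ids, genotyped_ids, drop = FALSE]
  A22 <- A22[genotyped_ids, genotyped_ids, drop = FALSE]
  Ginv <- tryCatch(solve(G), error = function(e) {
    abort(paste0("G is singular (", conditionMessage(e),
                 "); increase blend_alpha"))
  })
  A22inv <- tryCatch(solve(A22), error = function(e) {
    abort(paste0("A22 is singular (", conditionMessage(e),
                 "); the genotyped animals' pedigree may be too shallow"))
  })
  corr <- Ginv - A22inv
  pos <- match(genotyped_ids, ids)
  H <- as(Ainv, "CsparseMatrix")
  H <- as(H, "generalMatrix")
  Cfull <- Matrix::sparseMatrix(
    i = rep(pos, times = length(pos)),
    j = rep(pos, each = length(pos)),
    x = as.numeric(corr),
    dims = dim(Ainv), dimnames = dimnames(Ainv)
  )
  H <- Matrix::forceSymmetric(H + Cfull)
  attr(H, "genotyped_ids") <- genotyped_ids
  H
}
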