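#' Build a validated pedigree tibble
#'
#' A pedigree is a tibble with character columns `animal_id`, `sire_id` and
#' `dam_id` (`NA` for an unknown parent), topologically sorted so that every
#' parent row precedes its offspring. All relationship machinery
#' ([build_A()], [build_A_inverse()], [inbreeding()]) assumes this ordering.
#'
#' @param animal_id,sire_id,dam_id character vectors of equal length; unknown
#'   parents as `NA` (or `"0"`/`""`, which are converted).
#' @param sort if `TRUE` (default) the rows are topologically sorted;
#'   otherwise the given order is validated as already topological.
#' @return a tibble of class `wss_pedigree` with one row per animal.
#' @export
#' @examples
#' pedigree(c("o", "s", "d"), c("s", NA, NA), c("d", NA, NA))
pedigree <- function(animal_id, sire_id, dam_id, sort = TRUE) {
  animal_id <- as.character(animal_id)
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
    x
  }
  sire_id <- clean(sire_id)
  dam_id <- clean(dam_id)
  if (length(sire_id) != length(animal_id) || length(dam_id) != length(animal_id)) {
    abort("animal_id, sire_id and dam_id must have equal length")
  }
  dup <- animal_id[duplicated(animal_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate animal row(s) in pedigree: ",
                 paste(unique(dup), collapse = ", ")))
  }
  # parents that never appear as animals become founders implicitly? No:
  # the contract requires every named parent to appear as an animal.
  parents <- setdiff(stats::na.omit(c(sire_id, dam_id)), animal_id)
  if (length(parents) > 0) {
    abort(paste0("parent id(s) not present as animals: ",
                 paste(parents, collapse = ", ")))
  }
  ped <- tibble(animal_id = animal_id, sire_id = sire_id, dam_id = dam_id)
  ord <- topo_order(ped)
  if (sort) {
    ped <- ped[ord, ]
  } else {
    if (!identical(ord, seq_len(nrow(ped)))) {
      # validate the given order directly
      pos <- setNames(seq_len(nrow(ped)), ped$animal_id)
      bad <- !is.na(ped$sire_id) & pos[ped$sire_id] > seq_len(nrow(ped)) |
        !is.na(ped$dam_id) & pos[ped$dam_id] > seq_len(nrow(ped))
      if (any(bad)) {
        abort("pedigree is not topologically sorted (a parent follows its offspring)")
      }
    }
  }
  class(ped) <- c("wss_pedigree", class(tibble()))
  ped
}

# Kahn topological sort over parent -> offspring edges; errors on a cycle,
# naming one animal on it. Returns a row permutation.
topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal_id)
  si <- ifelse(is.na(ped$sire_id), 0L, idx[ped$sire_id])
  di <- ifelse(is.na(ped$dam_id), 0L, idx[ped$dam_id])
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(si[j], di[j])) {
      if (p > 0L) children[[p]] <- c(children[[p]], j)
    }
  }
  out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue) > 0) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stuck <- ped$animal_id[setdiff(seq_len(n), out)][1L]
    abort(paste0("pedigree contains a parentage cycle involving animal '",
                 stuck, "'"))
  }
  out
}

# integer sire/dam indices (0 = unknown) for a sorted pedigree
ped_indices <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$animal_id)
  list(
    sire = ifelse(is.na(ped$sire_id), 0L, unname(idx[ped$sire_id])),
    dam  = ifelse(is.na(ped$dam_id), 0L, unname(idx[ped$dam_id]))
  )
}

assert_sorted_pedigree <- function(ped) {
  if (!inherits(ped, "wss_pedigree")) {
    ped <- pedigree(ped$animal_id, ped$sire_id, ped$dam_id, sort = FALSE)
  }
  ix <- ped_indices(ped)
  j <- seq_len(nrow(ped))
  if (any(ix$sire > j) || any(ix$dam > j)) {
    abort("pedigree must be topologically sorted (parents precede offspring)")
  }
  ped
}

#' Read a three-column pedigree file
#'
#' Whitespace- or comma-delimited rows `animal sire dam`; a missing parent is
#' coded `0` or left empty. The result is topologically sorted, so the input
#' row order does not matter.
#'
#' @param path file path.
#' @return a `wss_pedigree` tibble (see [pedigree()]).
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[,[:space:]]+")
  nfield <- lengths(parts)
  if (any(nfield < 2 | nfield > 3)) {
    abort(paste0("pedigree rows must have 3 fields (animal sire dam); row ",
                 which(nfield < 2 | nfield > 3)[1L], " does not"))
  }
  get <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else "", "")
  pedigree(get(1L), get(2L), get(3L))
}

#' Write a pedigree to a three-column text file
#'
#' @param ped a `wss_pedigree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire_id[is.na(out$sire_id)] <- "0"
  out$dam_id[is.na(out$dam_id)] <- "0"
  readr::write_delim(out[, c("animal_id", "sire_id", "dam_id")], path,
                     delim = " ", col_names = FALSE)
  invisible(path)
}

#' Construct a genotype matrix object
#'
#' Couples an individuals-by-SNPs call matrix (allele dosage coding
#' `aa = 0, Aa = 1, AA = 2`, `NA` for missing) with a SNP map
#' (`snp_id`, `chrom`, `pos_bp`). Columns are stored sorted by
#' `(chrom, pos_bp)`.
#'
#' @param calls numeric matrix, rows = individuals (rownames required),
#'   entries in `{0, 1, 2, NA}` (QC may later replace missing calls by their
#'   column mean dosage).
#' @param map data frame with columns `snp_id`, `chrom` (integer), `pos_bp`
#'   (1-based integer), one row per column of `calls`.
#' @return an object of class `wss_geno`: list with elements `calls` and `map`.
#' @export
geno_matrix <- function(calls, map) {
  map <- as_tibble(map)
  if (!all(c("snp_id", "chrom", "pos_bp") %in% names(map))) {
    abort("map needs columns snp_id, chrom, pos_bp")
  }
  if (ncol(calls) != nrow(map)) {
    abort("number of genotype columns must equal number of map rows")
  }
  if (is.null(rownames(calls))) abort("calls must have individual ids as rownames")
  if (is.null(colnames(calls))) colnames(calls) <- map$snp_id
  if (!identical(colnames(calls), as.character(map$snp_id))) {
    m <- match(map$snp_id, colnames(calls))
    if (anyNA(m)) abort("SNP ids in map and genotype matrix do not match")
    calls <- calls[, m, drop = FALSE]
  }
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, ]
  calls <- calls[, ord, drop = FALSE]
  structure(list(calls = calls, map = map), class = "wss_geno")
}

#' @exportS3Method base::print
print.wss_geno <- function(x, ...) {
  cat("<wss_geno> ", nrow(x$calls), " individuals x ", ncol(x$calls),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read genotypes and a SNP map from text files
#'
#' The genotype file has one row per individual: the id followed by 0/1/2
#' calls (`NA` for missing). The map file has three columns: `snp_id`,
#' `chrom`, `pos_bp`, in the same column order as the genotype file.
#'
#' @param geno_path,map_path file paths.
#' @return a [geno_matrix()] object with SNPs sorted by `(chrom, pos_bp)`.
#' @export
read_genotypes <- function(geno_path, map_path) {
  map <- readr::read_table(map_path,
    col_names = c("snp_id", "chrom", "pos_bp"),
    col_types = readr::cols(
      snp_id = readr::col_character(),
      chrom = readr::col_integer(),
      pos_bp = readr::col_double()
    )
  )
  lines <- readLines(geno_path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  ids <- vapply(parts, `[`, "", 1L)
  m <- nrow(map)
  if (any(lengths(parts) != m + 1L)) {
    bad <- which(lengths(parts) != m + 1L)[1L]
    abort(paste0("genotype row ", bad, " ('", ids[bad], "') has ",
                 lengths(parts)[bad] - 1L, " calls; expected ", m))
  }
  calls <- matrix(NA_real_, length(ids), m, dimnames = list(ids, map$snp_id))
  for (i in seq_along(parts)) {
    v <- parts[[i]][-1L]
    x <- suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
    bad <- which(!(is.na(x) | x %in% c(0, 1, 2)))
    if (length(bad) > 0) {
      abort(paste0("invalid genotype call '", v[bad[1L]], "' for individual '",
                   ids[i], "', SNP '", map$snp_id[bad[1L]], "'"))
    }
    calls[i, ] <- x
  }
  geno_matrix(calls, map)
}

#' Write genotypes (and map) in the format [read_genotypes()] reads
#'
#' @param g a `wss_geno`.
#' @param geno_path,map_path output paths.
#' @return `geno_path`, invisibly.
#' @export
write_genotypes <- function(g, geno_path, map_path) {
  calls <- g$calls
  txt <- apply(calls, 1L, function(r) paste(ifelse(is.na(r), "NA", format(r, trim = TRUE)), collapse = " "))
  writeLines(paste(rownames(calls), txt), geno_path)
  readr::write_delim(g$map[, c("snp_id", "chrom", "pos_bp")], map_path,
                     delim = " ", col_names = FALSE)
  invisible(geno_path)
}

#' SNP quality control: call rate, MAF, Hardy-Weinberg
#'
#' Removes SNPs whose genotype call rate is below `call_rate_min`, whose minor
#' allele frequency is below `maf_min`, or whose 1-df chi-square goodness-of-fit
#' p-value against Hardy-Weinberg proportions is below `hwe_p_min`. All three
#' filters are evaluated jointly on the input matrix, so the report attributes
#' each SNP to every filter it fails. Allele frequencies use observed
#' (non-missing) calls. Missing calls surviving QC are replaced by the SNP
#' mean dosage `2p` with a warning.
#'
#' @param g a [geno_matrix()] object.
#' @param call_rate_min minimum fraction of non-missing calls (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE chi-square p-value (default 1e-6).
#' @return list with elements `genotypes` (filtered `wss_geno`) and `report`
#'   (class `wss_qc_report`: counts and per-filter SNP id lists).
#' @export
qc_filter_snps <- function(g, call_rate_min = 0.90, maf_min = 0.01,
                           hwe_p_min = 1e-6) {
  calls <- g$calls
  if (ncol(calls) == 0 || nrow(calls) == 0) abort("empty genotype matrix")
  n_obs <- colSums(!is.na(calls))
  call_rate <- n_obs / nrow(calls)
  p <- colSums(calls, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(calls)), function(j) {
    hwe_chisq_p(calls[, j])
  }, numeric(1))

  fail_cr <- call_rate < call_rate_min
  fail_maf <- maf < maf_min | n_obs == 0
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep)) abort("QC removed every SNP; nothing left to build G from")

  ids <- g$map$snp_id
  report <- structure(list(
    n_input_snps = ncol(calls),
    n_fail_callrate = sum(fail_cr),
    n_fail_maf = sum(fail_maf),
    n_fail_hwe = sum(fail_hwe),
    n_pass = sum(keep),
    fail_callrate = ids[fail_cr],
    fail_maf = ids[fail_maf],
    fail_hwe = ids[fail_hwe],
    thresholds = c(call_rate_min = call_rate_min, maf_min = maf_min,
                   hwe_p_min = hwe_p_min)
  ), class = "wss_qc_report")

  kept <- calls[, keep, drop = FALSE]
  if (anyNA(kept)) {
    n_miss <- sum(is.na(kept))
    warn(paste0("mean-imputing ", n_miss,
                " missing call(s) with per-SNP dosage 2p after QC"))
    pk <- p[keep]
    for (j in which(colSums(is.na(kept)) > 0)) {
      kept[is.na(kept[, j]), j] <- 2 * pk[j]
    }
  }
  list(genotypes = geno_matrix(kept, g$map[keep, ]), report = report)
}

# 1-df chi-square goodness of fit of genotype counts against p^2, 2pq, q^2;
# expected-zero cells are skipped (monomorphic SNPs get statistic 0, p = 1 --
# the MAF filter handles those).
hwe_chisq_p <- function(col) {
  col <- col[!is.na(col)]
  n <- length(col)
  if (n == 0) return(1)
  obs <- c(sum(col == 0), sum(col == 1), sum(col == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  nz <- expd > 0
  stat <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @exportS3Method base::print
print.wss_qc_report <- function(x, ...) {
  cat("<wss_qc_report>\n",
      "  input SNPs:      ", x$n_input_snps, "\n",
      "  fail call rate:  ", x$n_fail_callrate, "\n",
      "  fail MAF:        ", x$n_fail_maf, "\n",
      "  fail HWE:        ", x$n_fail_hwe, "\n",
      "  pass:            ", x$n_pass, "\n", sep = "")
  invisible(x)
}

#' Tidy a QC report into a per-filter tibble
#' @param x a `wss_qc_report`.
#' @param ... unused.
#' @return tibble with columns `filter`, `n_fail`.
#' @method tidy wss_qc_report
#' @export
tidy.wss_qc_report <- function(x, ...) {
  tibble(
    filter = c("call_rate", "maf", "hwe", "pass"),
    n = c(x$n_fail_callrate, x$n_fail_maf, x$n_fail_hwe, x$n_pass)
  )
}

#' Read a repeated-record phenotype table
#'
#' Delimited text with header columns `bull_id`, `trait`, `value`,
#' `year_season`, `station`, `interval_class`, `collection_class`,
#' `age_months`.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_delim(path,
    col_types = readr::cols(
      bull_id = readr::col_character(),
      trait = readr::col_character(),
      value = readr::col_double(),
      year_season = readr::col_character(),
      station = readr::col_character(),
      interval_class = readr::col_character(),
      collection_class = readr::col_character(),
      age_months = readr::col_double()
    ),
    show_col_types = FALSE
  )
}

#' Write a phenotype table in the format [read_phenotypes()] reads
#' @param pheno tibble of records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path)
  invisible(path)
}

#' Remove error records outside a trait's legal range
#'
#' Ejaculate volume (VE) must lie in 0-30 ml, sperm concentration (SC) in
#' 0-40 x 10^9/ml and progressive motility (MS) in 0-1 (a proportion).
#' The product traits NSP (= VE x SC) and NMSP (= NSP x MS) must be
#' non-negative and no larger than the product of their factors' bounds.
#'
#' @param pheno phenotype tibble (see [read_phenotypes()]).
#' @param trait one of `"VE"`, `"SC"`, `"MS"`, `"NSP"`, `"NMSP"`.
#' @return the filtered tibble (rows of `trait` within range); the number of
#'   dropped records is reported with a message.
#' @export
filter_phenotypes <- function(pheno, trait) {
  rng <- trait_range(trait)
  if (nrow(pheno) == 0) abort("empty phenotype table")
  rows <- pheno$trait == trait
  keep <- rows & !is.na(pheno$value) & pheno$value >= rng[1] & pheno$value <= rng[2]
  out <- pheno[keep, ]
  if (nrow(out) == 0) abort(paste0("no valid records remain for trait ", trait))
  inform(paste0(trait, ": kept ", nrow(out), " of ", sum(rows),
                " records (range ", rng[1], "-", rng[2], ")"))
  out
}

#' Write ranked window results as TSV
#'
#' Columns: `chromosome`, `start_Mb`, `end_Mb`, `start_snp`, `end_snp`,
#' `pct_variance`; rows ordered by rank (descending explained variance).
#'
#' @param w window tibble from [window_variance()] or [top_windows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_results <- function(w, path) {
  out <- tibble(
    chromosome = w$chromosome,
    start_Mb = w$start_bp / 1e6,
    end_Mb = w$end_bp / 1e6,
    start_snp = w$start_snp,
    end_snp = w$end_snp,
    pct_variance = w$pct_variance
  )
  if (nrow(out) > 0) {
    out <- out[order(-out$pct_variance, out$chromosome, out$start_Mb), ]
  }
  readr::write_tsv(out, path)
  invisible(path)
}
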