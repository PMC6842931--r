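#' Genetic variance explained by sliding SNP windows
#'
#' For every within-chromosome window of `window_size` consecutive SNPs
#' (advanced by `step`), computes the per-individual window genetic value
#' `g = sum_j z_j u_j` over the genotyped individuals, takes its sample
#' variance across individuals and expresses it as a percentage of the total
#' additive genetic variance `sigma2_a`. Windows never span chromosomes; a
#' chromosome holding fewer SNPs than `window_size` yields one truncated
#' window with a warning.
#'
#' @param x a `wss_gwas` from [run_wssgwas()], or a centered marker matrix
#'   (individuals x SNPs, columns sorted by map order).
#' @param u_hat SNP effects (taken from `x` when it is a `wss_gwas`).
#' @param sigma2_a total additive genetic variance (same trait units as the
#'   effects; the model's input component, not an empirical variance).
#' @param map SNP map tibble (`snp_id`, `chrom`, `pos_bp`); taken from `x`
#'   when it is a `wss_gwas`.
#' @param window_size number of adjacent SNPs per window (default 10).
#' @param step SNPs advanced between windows (default 1 = dense sliding;
#'   `step = window_size` gives non-overlapping windows).
#' @return tibble of class `wss_windows`: `chromosome`, `start_snp`,
#'   `end_snp` (global column indices, inclusive), `start_bp`, `end_bp`,
#'   `n_snps`, `var_window` (absolute variance), `pct_variance`.
#' @export
window_variance <- function(x, u_hat = NULL, sigma2_a = NULL, map = NULL,
                            window_size = 10, step = 1) {
  if (inherits(x, "wss_gwas")) {
    Z <- x$Z
    u_hat <- u_hat %||% x$u_hat
    map <- map %||% x$snp_map
    sigma2_a <- sigma2_a %||% x$config$vc$sigma2_a
  } else {
    Z <- x
  }
  if (is.null(u_hat) || is.null(map) || is.null(sigma2_a)) {
    abort("u_hat, map and sigma2_a are required")
  }
  if (sigma2_a <= 0) abort("sigma2_a must be positive")
  if (window_size < 1 || step < 1) abort("window_size and step must be >= 1")
  if (ncol(Z) != length(u_hat) || nrow(map) != length(u_hat)) {
    abort("Z columns, u_hat and map must agree in length")
  }

  # per-SNP genetic values, cumulated along columns so a window's genetic
  # value is a difference of two cumulative columns
  Zu <- sweep(Z, 2L, u_hat, `*`)
  S <- t(apply(Zu, 1L, cumsum))
  if (nrow(Zu) == 1L) S <- matrix(S, nrow = 1L)

  res <- list()
  for (chr in unique(map$chrom)) {
    cols <- which(map$chrom == chr)
    nc <- length(cols)
    if (nc < window_size) {
      warn(paste0("chromosome ", chr, " has ", nc, " SNP(s) < window size ",
                  window_size, "; using one truncated window"))
      starts <- cols[1L]
      ends <- cols[nc]
    } else {
      rel <- seq(1L, nc - window_size + 1L, by = step)
      starts <- cols[rel]
      ends <- cols[rel + window_size - 1L]
    }
    g_var <- vapply(seq_along(starts), function(k) {
      lo <- starts[k]
      hi <- ends[k]
      g <- S[, hi] - if (lo > 1L) S[, lo - 1L] else 0
      stats::var(g)
    }, numeric(1))
    res[[length(res) + 1L]] <- tibble(
      chromosome = as.integer(chr),
      start_snp = starts,
      end_snp = ends,
      start_bp = map$pos_bp[starts],
      end_bp = map$pos_bp[ends],
      n_snps = ends - starts + 1L,
      var_window = g_var,
      pct_variance = g_var / sigma2_a * 100
    )
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("wss_windows", class(tibble()))
  out
}

#' Top distinct window regions by explained genetic variance
#'
#' Ranks windows by descending `pct_variance` (ties broken by chromosome then
#' start position) and, with `prune = TRUE`, greedily drops any window that
#' shares at least one SNP with an already selected higher-ranked window, so
#' the result lists distinct regions rather than near-copies of one peak.
#'
#' @param w a `wss_windows` tibble.
#' @param n number of regions to return (default 10).
#' @param prune drop overlapping lower-ranked windows (default `TRUE`).
#' @return the selected windows with a `rank` column, ordered by rank.
#' @export
top_windows <- function(w, n = 10, prune = TRUE) {
  if (nrow(w) == 0) abort("no windows to rank")
  ord <- order(-w$pct_variance, w$chromosome, w$start_bp)
  w <- w[ord, ]
  if (prune) {
    sel <- integer(0)
    for (i in seq_len(nrow(w))) {
      if (length(sel) >= n) break
      overlaps <- any(
        w$chromosome[sel] == w$chromosome[i] &
          w$start_snp[sel] <= w$end_snp[i] &
          w$end_snp[sel] >= w$start_snp[i]
      )
      if (!overlaps) sel <- c(sel, i)
    }
    w <- w[sel, ]
  } else {
    w <- w[seq_len(min(n, nrow(w))), ]
  }
  w$rank <- seq_len(nrow(w))
  class(w) <- c("wss_windows", class(tibble()))
  w
}

#' Classify windows by explained-variance bands
#'
#' Counts windows in the four bands `>1%`, `0.5-1%`, `0.1-0.5%` and `<0.1%`.
#' Band edges belong to the lower band (a window at exactly 0.5% falls in
#' `0.1-0.5%`).
#'
#' @param w a `wss_windows` tibble.
#' @return tibble with `class`, `n_windows`, `prop_windows` (share of the
#'   window count) and `prop_variance` (share of the summed explained
#'   variance) per band.
#' @export
classify_windows <- function(w) {
  band <- as.character(cut(w$pct_variance,
                           breaks = c(-Inf, 0.1, 0.5, 1, Inf),
                           labels = c("<0.1%", "0.1-0.5%", "0.5-1%", ">1%"),
                           right = TRUE))
  labs <- c(">1%", "0.5-1%", "0.1-0.5%", "<0.1%")
  total_var <- sum(w$pct_variance)
  n_in <- vapply(labs, function(cl) sum(band == cl), 0L, USE.NAMES = FALSE)
  tibble(
    class = labs,
    n_windows = n_in,
    prop_windows = n_in / max(nrow(w), 1L),
    prop_variance = vapply(labs, function(cl) {
      if (total_var > 0) sum(w$pct_variance[band == cl]) / total_var else 0
    }, 0, USE.NAMES = FALSE)
  )
}

#' Window regions shared across traits
#'
#' Two top windows from different traits overlap when they sit on the same
#' chromosome and their base-pair intervals intersect (closed intervals;
#' mere adjacency, `end_bp + 1 == start_bp`, is not overlap). Overlapping
#' windows are merged transitively into regions.
#'
#' @param results named list of `wss_windows` tibbles, one per trait (use the
#'   pruned [top_windows()] output), or a single tibble with a `trait`
#'   column.
#' @return tibble with one row per (region, trait): `region`, `chromosome`,
#'   `start_bp`, `end_bp` (merged span), `n_traits`, `trait`,
#'   `pct_variance`. Only regions shared by at least two traits are returned.
#' @export
overlap_across_traits <- function(results) {
  if (is.data.frame(results)) {
    if (!"trait" %in% names(results)) abort("tibble input needs a trait column")
    all_w <- results
  } else {
    if (length(results) < 2) abort("need top windows for at least two traits")
    all_w <- purrr::imap_dfr(results, ~ dplyr::mutate(tibble::as_tibble(.x),
                                                      trait = .y))
  }
  n <- nrow(all_w)
  if (n == 0) return(tibble())
  # union-find over pairwise interval intersections on a chromosome
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (all_w$trait[i] != all_w$trait[j] &&
          all_w$chromosome[i] == all_w$chromosome[j] &&
          all_w$start_bp[i] <= all_w$end_bp[j] &&
          all_w$start_bp[j] <= all_w$end_bp[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  all_w$component <- vapply(seq_len(n), find, 0L)
  regions <- all_w |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      chromosome = .data$chromosome[1L],
      region_start = min(.data$start_bp),
      region_end = max(.data$end_bp),
      n_traits = dplyr::n_distinct(.data$trait),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_traits >= 2)
  if (nrow(regions) == 0) return(tibble())
  all_w[, c("component", "trait", "pct_variance")] |>
    dplyr::inner_join(regions, by = "component") |>
    dplyr::arrange(.data$chromosome, .data$region_start, .data$trait) |>
    dplyr::transmute(
      region = paste0("chr", .data$chromosome, ":",
                      .data$region_start, "-", .data$region_end),
      chromosome = .data$chromosome,
      start_bp = .data$region_start,
      end_bp = .data$region_end,
      n_traits = .data$n_traits,
      trait = .data$trait,
      pct_variance = .data$pct_variance
    )
}

#' Export windows with a cumulative genome coordinate for Manhattan plots
#'
#' @param w a `wss_windows` tibble.
#' @param path optional TSV output path.
#' @return tibble with an added `cum_bp` midpoint coordinate, ordered by
#'   `(chromosome, start_bp)`; written to `path` when given.
#' @export
manhattan_export <- function(w, path = NULL) {
  w <- dplyr::arrange(tibble::as_tibble(w), .data$chromosome, .data$start_bp)
  offsets <- w |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(chr_len = max(.data$end_bp), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$chr_len), default = 0))
  out <- dplyr::left_join(w, offsets[, c("chromosome", "offset")],
                          by = "chromosome") |>
    dplyr::mutate(cum_bp = .data$offset +
                    (.data$start_bp + .data$end_bp) / 2) |>
    dplyr::select(-"offset")
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}

#' Manhattan-style plot of window explained variance
#'
#' @param object a `wss_windows` tibble.
#' @param highlight_pct draw a reference line at this explained-variance
#'   percentage (default 1).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot wss_windows
#' @export
autoplot.wss_windows <- function(object, highlight_pct = 1, ...) {
  dat <- manhattan_export(object)
  dat$chrom_f <- factor(dat$chromosome)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cum_bp / 1e6,
                                    y = .data$pct_variance,
                                    colour = .data$chrom_f)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = highlight_pct, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "Cumulative position (Mb)",
                  y = "Genetic variance explained by window (%)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.wss_windows
#' @param w a `wss_windows` tibble.
#' @export
plot_manhattan <- function(w, highlight_pct = 1) {
  autoplot.wss_windows(w, highlight_pct = highlight_pct)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
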