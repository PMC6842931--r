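#' Build and validate a pipeline run configuration
#'
#' Fills defaults (QC thresholds call rate 0.90 / MAF 0.01 / HWE 1e-6,
#' 10-SNP windows sliding by 1, `n_iter = 2`, `blend_alpha = 0.05`,
#' top 10 regions) and checks consistency. In `"synthetic"` mode the data
#' come from [simulate_dataset()] under `sim`; in `"files"` mode from the
#' paths in `paths` (`pedigree`, `genotypes`, `map`, `phenotypes`).
#'
#' @param mode `"synthetic"` (default) or `"files"`.
#' @param trait trait to analyze (`VE`, `SC`, `MS`, `NSP`, `NMSP`).
#' @param sim a [sim_config()]; defaults to the package preset with the seed
#'   below (synthetic mode).
#' @param paths named list of input paths (files mode).
#' @param varcomp [variance_components()] used in the mixed model; defaults
#'   to the simulation components in synthetic mode.
#' @param call_rate_min,maf_min,hwe_p_min QC thresholds.
#' @param n_iter,blend_alpha weighting-loop settings (see [run_wssgwas()]).
#' @param window_size,step,top_n window settings (see [window_variance()]).
#' @param seed integer seed for the run.
#' @param out_dir output directory (created by [run_pipeline()]); `NULL`
#'   skips file output.
#' @return validated list of class `wss_run_config`.
#' @export
wss_config <- function(mode = c("synthetic", "files"),
                       trait = "VE",
                       sim = NULL,
                       paths = NULL,
                       varcomp = NULL,
                       call_rate_min = 0.90, maf_min = 0.01, hwe_p_min = 1e-6,
                       n_iter = 2, blend_alpha = 0.05,
                       window_size = 10, step = 1, top_n = 10,
                       seed = 42, out_dir = NULL) {
  mode <- match.arg(mode)
  problems <- character(0)
  if (!trait %in% SEMEN_TRAITS) {
    problems <- c(problems, paste0("unknown trait '", trait, "'; valid: ",
                                   paste(SEMEN_TRAITS, collapse = ", ")))
  }
  if (n_iter < 1) problems <- c(problems, "n_iter must be >= 1")
  if (window_size < 1) problems <- c(problems, "window_size must be >= 1")
  if (step < 1) problems <- c(problems, "step must be >= 1")
  if (top_n < 1) problems <- c(problems, "top_n must be >= 1")
  if (blend_alpha < 0 || blend_alpha >= 1) {
    problems <- c(problems, "blend_alpha must be in [0, 1)")
  }
  if (mode == "synthetic") {
    if (is.null(sim) && trait %in% SEMEN_TRAITS) {
      sim <- sim_config(trait = trait, seed = seed)
    }
    if (!is.null(sim) && !inherits(sim, "wss_sim_config")) {
      problems <- c(problems, "sim must come from sim_config()")
    } else if (!is.null(sim)) {
      varcomp <- varcomp %||% sim$varcomp
    }
  } else {
    needed <- c("pedigree", "genotypes", "map", "phenotypes")
    if (is.null(paths) || !all(needed %in% names(paths))) {
      problems <- c(problems, paste0("files mode needs paths: ",
                                     paste(needed, collapse = ", ")))
    } else {
      missing_f <- unlist(paths[needed])[!file.exists(unlist(paths[needed]))]
      if (length(missing_f) > 0) {
        problems <- c(problems, paste0("missing input file(s): ",
                                       paste(missing_f, collapse = ", ")))
      }
    }
    if (is.null(varcomp)) {
      problems <- c(problems,
                    "files mode needs varcomp (variance components are inputs)")
    }
  }
  if (!is.null(varcomp) && !inherits(varcomp, "wss_varcomp")) {
    problems <- c(problems, "varcomp must come from variance_components()")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid configuration:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  structure(list(
    mode = mode, trait = trait, sim = sim, paths = paths, varcomp = varcomp,
    call_rate_min = call_rate_min, maf_min = maf_min, hwe_p_min = hwe_p_min,
    n_iter = n_iter, blend_alpha = blend_alpha,
    window_size = window_size, step = step, top_n = top_n,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "wss_run_config")
}

#' Alias kept for symmetry with the config surface
#' @param cfg a list of [wss_config()] arguments or a `wss_run_config`.
#' @return a validated `wss_run_config`.
#' @export
validate_config <- function(cfg) {
  if (inherits(cfg, "wss_run_config")) cfg <- unclass(cfg)
  do.call(wss_config, cfg[!vapply(cfg, is.null, TRUE)])
}

#' Run the full weighted single-step GWAS pipeline
#'
#' Stages: data (simulate or read) -> phenotype error filter -> SNP QC ->
#' relationship matrices -> mixed-model solve(s) with SNP reweighting ->
#' sliding-window variance partition -> ranked regions and class summary.
#' Deterministic under the config seed. When `cfg$out_dir` is set, writes
#' `qc_report.tsv`, `solutions.tsv`, `snp_effects.tsv`, `windows.tsv`,
#' `top_windows.tsv`, `class_summary.tsv` and a `manifest.txt` config echo.
#'
#' @param cfg a [wss_config()].
#' @return list of class `wss_run`: `qc_report`, `gwas` (`wss_gwas`),
#'   `fit` (`wss_fit`), `windows`, `top_windows`, `class_summary`,
#'   `data` (inputs incl. truth in synthetic mode), `config`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "wss_run_config")) abort("cfg must come from wss_config()")
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  data <- stage("data", {
    if (cfg$mode == "synthetic") {
      simulate_dataset(cfg$sim)
    } else {
      ped <- read_pedigree(cfg$paths$pedigree)
      list(
        pedigree = ped,
        genotypes = read_genotypes(cfg$paths$genotypes, cfg$paths$map),
        phenotypes = read_phenotypes(cfg$paths$phenotypes),
        truth = NULL
      )
    }
  })
  inform(paste0("[data] ", nrow(data$pedigree), " animals, ",
                nrow(data$genotypes$calls), " genotyped, ",
                ncol(data$genotypes$calls), " SNPs, ",
                nrow(data$phenotypes), " records"))

  pheno <- stage("phenotype_filter",
                 filter_phenotypes(data$phenotypes, cfg$trait))

  qc <- stage("qc", qc_filter_snps(data$genotypes,
                                   call_rate_min = cfg$call_rate_min,
                                   maf_min = cfg$maf_min,
                                   hwe_p_min = cfg$hwe_p_min))
  inform(paste0("[qc] ", qc$report$n_pass, " of ", qc$report$n_input_snps,
                " SNPs pass"))

  gwas <- stage("wssgwas", run_wssgwas(
    ped = data$pedigree, geno = qc$genotypes, pheno = pheno,
    vc = cfg$varcomp, n_iter = cfg$n_iter, blend_alpha = cfg$blend_alpha
  ))
  inform(paste0("[wssgwas] ", cfg$n_iter, " iteration(s), MME residual ",
                format(gwas$final_fit$convergence, digits = 3)))

  windows <- stage("windows", window_variance(
    gwas, sigma2_a = cfg$varcomp$sigma2_a,
    window_size = cfg$window_size, step = cfg$step
  ))
  top <- stage("windows", top_windows(windows, n = cfg$top_n))
  classes <- stage("windows", classify_windows(windows))
  inform(paste0("[windows] ", nrow(windows), " windows; top region explains ",
                format(top$pct_variance[1], digits = 3), "% of sigma2_a"))

  run <- structure(list(
    qc_report = qc$report, gwas = gwas, fit = gwas$final_fit,
    windows = windows, top_windows = top, class_summary = classes,
    data = data, config = cfg
  ), class = "wss_run")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    readr::write_tsv(tidy(qc$report), out("qc_report.tsv"))
    readr::write_tsv(dplyr::bind_rows(tidy(gwas$final_fit, "fixed"),
                                      tidy(gwas$final_fit, "animal"),
                                      tidy(gwas$final_fit, "pe")),
                     out("solutions.tsv"))
    write_snp_effects(gwas, out("snp_effects.tsv"))
    write_window_results(windows, out("windows.tsv"))
    write_window_results(top, out("top_windows.tsv"))
    readr::write_tsv(classes, out("class_summary.tsv"))
    writeLines(manifest_lines(cfg, run), out("manifest.txt"))
  }
  run
}

# plain-text config echo sufficient to reproduce a run
manifest_lines <- function(cfg, run) {
  c(
    paste0("package: wssgwas ", as.character(utils::packageVersion("wssgwas"))),
    paste0("mode: ", cfg$mode),
    paste0("trait: ", cfg$trait),
    paste0("seed: ", cfg$seed),
    paste0("sigma2_a: ", cfg$varcomp$sigma2_a),
    paste0("sigma2_p: ", cfg$varcomp$sigma2_p),
    paste0("sigma2_e: ", cfg$varcomp$sigma2_e),
    paste0("qc: call_rate_min=", cfg$call_rate_min, " maf_min=", cfg$maf_min,
           " hwe_p_min=", cfg$hwe_p_min),
    paste0("n_iter: ", cfg$n_iter),
    paste0("blend_alpha: ", cfg$blend_alpha),
    paste0("window_size: ", cfg$window_size, " step: ", cfg$step,
           " top_n: ", cfg$top_n),
    paste0("n_animals: ", nrow(run$data$pedigree)),
    paste0("n_genotyped: ", nrow(run$data$genotypes$calls)),
    paste0("n_snps_pass: ", run$qc_report$n_pass),
    paste0("n_records: ", run$fit$n_records)
  )
}

#' @exportS3Method base::print
print.wss_run <- function(x, ...) {
  cat("<wss_run> trait ", x$config$trait, " (", x$config$mode, " mode)\n",
      "  SNPs passing QC: ", x$qc_report$n_pass, "\n",
      "  records: ", x$fit$n_records, "\n",
      "  top region: chr", x$top_windows$chromosome[1], " ",
      format(x$top_windows$start_bp[1] / 1e6, digits = 4), "-",
      format(x$top_windows$end_bp[1] / 1e6, digits = 4), " Mb, ",
      format(x$top_windows$pct_variance[1], digits = 3),
      "% of additive variance\n", sep = "")
  invisible(x)
}
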