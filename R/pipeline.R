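default_pipeline_params <- function() {
  list(min_cov = 20, min_maf = 0.02, exclude_chrom4 = FALSE,
       pseudocount = 1, n_pcs = 10, pc_alpha = 0.005,
       alpha = 0.05, hidden_alpha = 0.005, deep_min_cov = 1,
       n_perm = 10000, fdr = 0.05, min_dp = 0.02,
       focal_sample = "FOUNDER_A_r1_T1")
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- list(filter = TRUE, pca = TRUE, bb_scan = TRUE, het = TRUE,
                 hidden = FALSE, converge = TRUE, loo = TRUE)
  stages[names(config$stages)] <- config$stages
  config$stages <- stages
  params <- default_pipeline_params()
  params[names(config$params)] <- config$params
  config$params <- params
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  message("[evoltraj] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> PCA -> beta-binomial scan ->
#' heterozygosity -> hidden variation -> convergence -> leave-one-out
#' parallelism, writing every stage's tabular output plus a JSON manifest
#' (parameters, seed, package and R versions, per-file MD5 checksums) to the
#' output directory. Identical config and seed give identical outputs.
#'
#' The config (YAML file path or list) has top-level keys `seed`, `out_dir`,
#' `simulate` (arguments for [sim_config()]; omit to load data instead),
#' `input` (paths `snp_table`, `design`, and optionally `deep_table`,
#' `deep_design`), `stages` (logical toggles: filter, pca, bb_scan, het,
#' hidden, converge, loo) and `params` (min_cov, min_maf, exclude_chrom4,
#' pseudocount, n_pcs, pc_alpha, alpha, hidden_alpha, deep_min_cov, n_perm,
#' fdr, min_dp, focal_sample).
#'
#' @param config YAML path or list.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no output directory configured")
  p <- cfg$params
  # pre-flight validation
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$input$snp_table) || !file.exists(cfg$input$snp_table))
      stop("pre-flight: no simulate block and no existing input$snp_table")
    if (isTRUE(cfg$stages$hidden) &&
        (is.null(cfg$input$deep_table) || !file.exists(cfg$input$deep_table)))
      stop("pre-flight: hidden stage enabled but no deep table available")
  } else if (isTRUE(cfg$stages$hidden) &&
             !isTRUE(cfg$simulate$deep_sample)) {
    stop("pre-flight: hidden stage enabled but simulate$deep_sample is not TRUE")
  }
  if (isTRUE(cfg$stages$hidden) && !isTRUE(cfg$stages$bb_scan))
    stop("pre-flight: hidden stage requires the bb_scan stage")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  deep <- NULL; truth <- NULL
  if (!is.null(cfg$simulate)) {
    run_stage("simulate", {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      if (!is.null(sim_args$sampled_generations))
        sim_args$sampled_generations <-
          lapply(sim_args$sampled_generations, as.numeric)
      sim <- do.call(sim_config, sim_args)
      out <- simulate_experiment(sim)
      tab <- out$table; deep <- out$deep; truth <- out$truth
      add(write_tsv(truth$loci, file.path(out_dir, "truth.tsv")))
      add(write_snp_table(tab, file.path(out_dir, "snp_table.tsv"),
                          file.path(out_dir, "design.tsv")))
      add(file.path(out_dir, "design.tsv"))
      if (!is.null(deep)) {
        add(write_snp_table(deep, file.path(out_dir, "deep_table.tsv"),
                            file.path(out_dir, "deep_design.tsv")))
        add(file.path(out_dir, "deep_design.tsv"))
      }
    })
  } else {
    run_stage("load", {
      tab <- read_snp_table(cfg$input$snp_table, cfg$input$design)
      if (!is.null(cfg$input$deep_table))
        deep <- read_snp_table(cfg$input$deep_table, cfg$input$deep_design)
    })
  }

  if (isTRUE(cfg$stages$filter)) {
    tab <- run_stage("filter", filter_snps(tab, min_cov = p$min_cov,
                                           min_maf = p$min_maf,
                                           exclude_chrom4 = p$exclude_chrom4))
    if (!is.null(deep)) {
      key <- paste(tab$loci$chrom, tab$loci$pos)
      deep <- deep[paste(deep$loci$chrom, deep$loci$pos) %in% key, ]
    }
  }

  if (isTRUE(cfg$stages$pca)) {
    run_stage("pca", {
      pca <- run_pca(tab, pseudocount = p$pseudocount)
      sc <- data.frame(tab$samples,
                       pca$scores[, seq_len(min(p$n_pcs, ncol(pca$scores))),
                                  drop = FALSE])
      add(write_tsv(sc, file.path(out_dir, "pca_scores.tsv")))
      add(write_tsv(
        data.frame(pc = seq_along(pca$variance_explained),
                   variance_explained = pca$variance_explained),
        file.path(out_dir, "pca_variance.tsv")))
      lmm <- fit_pc_lmm(pca, n_pcs = p$n_pcs, alpha = p$pc_alpha)
      add(write_tsv(lmm$results, file.path(out_dir, "pc_lmm.tsv")))
    })
  }

  scan <- NULL
  if (isTRUE(cfg$stages$bb_scan)) {
    run_stage("bb_scan", {
      scan <- scan_genome(tab, alpha = p$alpha)
      add(write_tsv(scan$results, file.path(out_dir, "bb_scan.tsv")))
      add(write_tsv(data.frame(class = names(scan$class_counts),
                               n = as.integer(scan$class_counts)),
                    file.path(out_dir, "bb_classes.tsv")))
    })
  }

  if (isTRUE(cfg$stages$het)) {
    run_stage("het", {
      hs <- het_trend(tab)
      add(write_tsv(hs$per_sample, file.path(out_dir, "het_per_sample.tsv")))
      if (!is.null(hs$tests))
        add(write_tsv(hs$tests, file.path(out_dir, "het_tests.tsv")))
    })
  }

  if (isTRUE(cfg$stages$hidden)) {
    run_stage("hidden", {
      sig <- which(pmin(1, scan$results$p_interaction * scan$m) < p$hidden_alpha)
      hv <- hidden_variation_report(tab, deep, p$focal_sample, sig,
                                    n_perm = p$n_perm, seed = cfg$seed,
                                    deep_min_cov = p$deep_min_cov)
      add(write_tsv(hv$sites, file.path(out_dir, "pseudo_fixed_sites.tsv")))
      summ <- hv[c("observed_mean", "null_mean", "null_sd", "z", "p",
                   "n_le", "n_perm", "n_set", "n_background",
                   "n_pseudo_fixed_total")]
      jsonlite::write_json(summ, file.path(out_dir, "hidden_report.json"),
                           auto_unbox = TRUE, digits = NA)
      add(file.path(out_dir, "hidden_report.json"))
    })
  }

  if (isTRUE(cfg$stages$converge)) {
    run_stage("converge", {
      for (ctr in c("C2A-vs-FOUNDER_A", "A2C-vs-FOUNDER_C")) {
        cv <- convergence_scan(tab, contrast = ctr, alpha = p$alpha)
        add(write_tsv(cv$results,
                      file.path(out_dir, paste0("converge_", ctr, ".tsv"))))
      }
    })
  }

  if (isTRUE(cfg$stages$loo)) {
    run_stage("loo", {
      for (traj in c("A2C", "C2A")) {
        loo <- loo_parallelism(tab, trajectory = traj, fdr = p$fdr,
                               min_abs_dp = p$min_dp, seed = cfg$seed)
        add(write_tsv(loo$iterations,
                      file.path(out_dir,
                                paste0("loo_", traj, "_iterations.tsv"))))
        add(write_tsv(loo$tests,
                      file.path(out_dir, paste0("loo_", traj, "_tests.tsv"))))
      }
    })
  }

  manifest <- list(
    package = "evoltraj",
    version = as.character(utils::packageVersion("evoltraj")),
    r_version = as.character(getRversion()),
    seed = cfg$seed, stages = cfg$stages, params = p,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
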