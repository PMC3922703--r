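## End-to-end orchestration: simulate (or read) -> preprocess -> diversity
## -> sharing -> networks -> ordination -> biomarkers, with every artifact
## written as TSV/JSON and listed, with checksums, in a manifest.

#' Build a pipeline configuration
#'
#' @param input_dir Directory with an existing dataset (see
#'   [read_dataset()]); `NULL` to simulate instead.
#' @param sim Simulation configuration ([sim_config()]) used when
#'   `input_dir` is `NULL`.
#' @param min_intensity,min_snr Detection cutoffs.
#' @param min_abs_corr Network association threshold.
#' @param accuracy_threshold Biomarker accuracy threshold.
#' @param n_perm Permutations for group tests and MRPP.
#' @param n_iter Saturation-curve iterations.
#' @param n_bootstrap Biomarker bootstrap iterations.
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param stages Character vector of stages to run (subset of
#'   `c("preprocess", "diversity", "sharing", "network", "ordination",
#'   "biomarker")`; `preprocess` always runs).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = sim_config(),
                            min_intensity = 1000, min_snr = 2,
                            min_abs_corr = 0.8, accuracy_threshold = 0.8,
                            n_perm = 999, n_iter = 100, n_bootstrap = 30,
                            seed = 1L,
                            stages = c("preprocess", "diversity", "sharing",
                                       "network", "ordination", "biomarker")) {
  structure(list(input_dir = input_dir, sim = sim,
                 min_intensity = min_intensity, min_snr = min_snr,
                 min_abs_corr = min_abs_corr,
                 accuracy_threshold = accuracy_threshold,
                 n_perm = n_perm, n_iter = n_iter, n_bootstrap = n_bootstrap,
                 seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' mapping is passed on to [sim_config()].
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else sim_config()
  y$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), y))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a dataset, then runs detection calling and the
#' core/non-core partition, diversity statistics with group comparisons,
#' gene-sharing statistics, co-presence networks, ordination (detrended
#' correspondence analysis and MRPP), and triplet biomarker selection.
#' Every artifact is written under `outdir` and recorded, with its MD5
#' checksum, in `manifest.json`. All randomness derives from the root
#' seed via per-stage seeds recorded in the manifest.
#'
#' @param config A `"pipeline_config"` (or YAML path).
#' @param outdir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(outdir, "pipeline.log")
  logln <- function(...) cat(sprintf(...), "\n", sep = "", file = log_file,
                             append = TRUE)
  cat("", file = log_file)
  artifacts <- character(0)
  seeds <- list()
  stage_seed <- function(stage) {
    s <- derive_seed(config$seed, stage)
    seeds[[stage]] <<- s
    s
  }
  logln("root seed: %d", config$seed)
  logln("cutoffs: intensity >= %g, SNR >= %g; correlation threshold %g; accuracy threshold %g",
        config$min_intensity, config$min_snr, config$min_abs_corr,
        config$accuracy_threshold)

  ## --- input -------------------------------------------------------------
  truth <- NULL
  if (is.null(config$input_dir)) {
    sim <- config$sim
    sim$seed <- stage_seed("simulate")
    res <- simulate_dataset(sim)
    dataset <- res$dataset
    truth <- res$truth
    ddir <- file.path(outdir, "dataset")
    artifacts <- c(artifacts, write_dataset(dataset, ddir, truth))
    logln("simulated dataset: %d genes x %d samples", nrow(dataset$intensity),
          ncol(dataset$intensity))
  } else {
    dataset <- read_dataset(config$input_dir)
    logln("read dataset from %s", config$input_dir)
  }
  groups <- sample_groups(dataset)

  ## --- preprocess --------------------------------------------------------
  profile <- detection_profile(dataset, config$min_intensity, config$min_snr)
  artifacts <- c(artifacts,
    write_matrix_tsv(profile$detected * 1L, file.path(outdir, "detected.tsv")),
    write_matrix_tsv(profile$normalized, file.path(outdir, "normalized.tsv")),
    write_matrix_tsv(profile$noncore_binary, file.path(outdir, "noncore_binary.tsv")))
  part_file <- file.path(outdir, "partition.json")
  jsonlite::write_json(list(core = profile$core_genes,
                            noncore = profile$noncore_genes),
                       part_file, pretty = TRUE)
  artifacts <- c(artifacts, part_file)
  cats <- aggregate_by_category(profile, dataset$annotation)
  artifacts <- c(artifacts,
    write_matrix_tsv(cats$abundance, file.path(outdir, "category_abundance.tsv")),
    write_matrix_tsv(cats$diversity, file.path(outdir, "category_diversity.tsv")))
  logln("detected genes: %d (core %d, non-core %d)",
        length(profile$core_genes) + length(profile$noncore_genes),
        length(profile$core_genes), length(profile$noncore_genes))

  ## --- diversity ---------------------------------------------------------
  if ("diversity" %in% config$stages) {
    div <- diversity_indices(profile$normalized)
    div$group <- unname(groups[div$sample_id])
    artifacts <- c(artifacts,
      write_table_tsv(div, file.path(outdir, "diversity.tsv")))
    s <- stage_seed("diversity")
    comp <- rbind(
      cbind(level = "index",
            compare_groups(t(as.matrix(div[, c("richness", "shannon",
                                               "inverse_simpson")])),
                           groups, n_perm = config$n_perm, seed = s)),
      cbind(level = "category",
            compare_groups(cats$abundance, groups,
                           n_perm = config$n_perm, seed = s + 1L)))
    artifacts <- c(artifacts,
      write_table_tsv(comp, file.path(outdir, "group_comparisons.tsv")))
    cvr <- core_variability_ranking(profile$normalized, profile$core_genes,
                                    dataset$annotation)
    artifacts <- c(artifacts,
      write_table_tsv(cvr, file.path(outdir, "core_variability.tsv")))
  }

  ## --- sharing -----------------------------------------------------------
  if ("sharing" %in% config$stages) {
    s <- stage_seed("sharing")
    for (g in c("H", "C")) {
      gs <- names(groups)[groups == g]
      pm <- pairwise_shared_matrix(profile$detected, gs)
      artifacts <- c(artifacts,
        write_matrix_tsv(pm, file.path(outdir, sprintf("pairwise_shared_%s.tsv", g))))
      sc <- saturation_curve(profile$detected, gs, n_iter = config$n_iter,
                             seed = derive_seed(s, g))
      artifacts <- c(artifacts,
        write_table_tsv(sc, file.path(outdir, sprintf("saturation_%s.tsv", g))))
      gc <- group_core_fraction(profile$detected, gs)
      logln("group %s core: %d/%d (%.1f%%)", g, gc$n_shared, gc$n_total,
            gc$percentage)
    }
  }

  ## --- network -----------------------------------------------------------
  if ("network" %in% config$stages) {
    summaries <- list()
    for (g in c("H", "C")) {
      gs <- names(groups)[groups == g]
      core_net <- detect_modules(build_core_network(
        profile$normalized, profile$core_genes, gs,
        min_abs_corr = config$min_abs_corr,
        annotation = dataset$annotation, group = g))
      artifacts <- c(artifacts,
        write_network(core_net, file.path(outdir, sprintf("core_network_%s", g))))
      summaries[[paste0("core_", g)]] <- summarize_network(core_net)
      for (pw in c("Carbon", "AA", "Nitrogen")) {
        net <- try(detect_modules(build_noncore_subnetwork(
          profile$noncore_binary, dataset$annotation, pw, gs,
          min_abs_corr = config$min_abs_corr, group = g)), silent = TRUE)
        if (inherits(net, "try-error")) next
        artifacts <- c(artifacts,
          write_network(net, file.path(outdir, sprintf("noncore_%s_%s", pw, g))))
        summaries[[paste0("noncore_", pw, "_", g)]] <- summarize_network(net)
      }
    }
    nf <- file.path(outdir, "network_summaries.json")
    jsonlite::write_json(summaries, nf, auto_unbox = TRUE, pretty = TRUE)
    artifacts <- c(artifacts, nf)
  }

  ## --- ordination --------------------------------------------------------
  if ("ordination" %in% config$stages) {
    det_genes <- c(profile$core_genes, profile$noncore_genes)
    ab <- profile$normalized[det_genes, , drop = FALSE]
    dca <- detrended_ca(ab)
    sc <- data.frame(sample_id = rownames(dca$sample_scores),
                     axis1 = dca$sample_scores[, 1],
                     axis2 = dca$sample_scores[, 2],
                     group = unname(groups[rownames(dca$sample_scores)]),
                     row.names = NULL)
    artifacts <- c(artifacts,
      write_table_tsv(sc, file.path(outdir, "dca_scores.tsv")))
    mr <- mrpp_test(ab, groups, metric = "bray", n_perm = config$n_perm,
                    seed = stage_seed("ordination"))
    mf <- file.path(outdir, "mrpp.json")
    jsonlite::write_json(unclass(mr), mf, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, mf)
    logln("MRPP: delta %.4f, A %.4f, p %.4g", mr$delta_observed, mr$A,
          mr$p_value)
  }

  ## --- biomarker ---------------------------------------------------------
  if ("biomarker" %in% config$stages) {
    report <- select_triplets(profile$noncore_binary, groups,
                              accuracy_threshold = config$accuracy_threshold,
                              n_bootstrap = config$n_bootstrap,
                              seed = stage_seed("biomarker"))
    artifacts <- c(artifacts,
      write_table_tsv(report$selected, file.path(outdir, "triplets_selected.tsv")),
      write_table_tsv(report$triplets, file.path(outdir, "triplets_all.tsv")),
      write_table_tsv(report$gene_frequencies,
                      file.path(outdir, "gene_frequencies.tsv")))
    if (!is.null(report$exclusive_genes))
      artifacts <- c(artifacts,
        write_table_tsv(report$exclusive_genes,
                        file.path(outdir, "exclusive_genes.tsv")))
    bf <- file.path(outdir, "biomarker_provenance.json")
    jsonlite::write_json(report$provenance, bf, auto_unbox = TRUE)
    artifacts <- c(artifacts, bf)
    logln("biomarkers: %d triplets selected, %d exclusive-pattern genes",
          nrow(report$selected),
          if (is.null(report$exclusive_genes)) 0L else nrow(report$exclusive_genes))
  }

  ## --- manifest ----------------------------------------------------------
  artifacts <- unique(artifacts)
  manifest <- list(
    seed = config$seed, stage_seeds = seeds,
    thresholds = list(min_intensity = config$min_intensity,
                      min_snr = config$min_snr,
                      min_abs_corr = config$min_abs_corr,
                      accuracy_threshold = config$accuracy_threshold),
    artifacts = data.frame(
      path = sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", outdir), "/?"),
                 "", artifacts),
      md5 = unname(tools::md5sum(artifacts)),
      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
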