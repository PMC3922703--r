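## Synthetic generator emulating functional-gene-array saliva profiles:
## a gene x sample intensity matrix plus a matched signal-to-noise matrix,
## with a planted core/non-core structure, group-biased non-core presence,
## group-exclusive genes, discriminative gene triplets and co-presence
## blocks, so that every downstream stage can be tested against known truth.

.default_categories <- function() {
  data.frame(
    category = c(
      "Amino acid synthesis",
      "Amino acid transport and metabolism",
      "Central Carbon Metabolism Pathways",
      "Cofactor Biosynthesis",
      "Complex Carbohydrates",
      "Feeder Pathways to Glycolysis",
      "Respiration",
      "Nitrogen Metabolism",
      "Pyrimidine metabolism",
      "Purine metabolism",
      "Fatty Acid Metabolism",
      "Fatty Acid Biosynthesis",
      "Organic Acids",
      "Glycan Biosynthesis and Metabolism",
      "Glycosaminoglycan degradation",
      "Glycan structures - degradation",
      "Isoprenoid biosynthesis",
      "Exotic Metabolisms",
      "Phosphorus Metabolism"),
    weight = c(0.25, 0.15, 0.10, 0.08, 0.07,
               0.03, 0.03, 0.03, 0.03, 0.03,
               0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.04),
    stringsAsFactors = FALSE
  )
}

#' Map gene categories to metabolic pathway groups
#'
#' Carbon-associated covers complex carbohydrates, feeder pathways to
#' glycolysis and respiration; AA-associated covers amino acid transport and
#' metabolism plus amino acid synthesis; Nitrogen-associated covers nitrogen
#' metabolism. Everything else is "Other".
#'
#' @param category Character vector of gene category labels.
#' @return Character vector of pathway-group labels
#'   (`"Carbon"`, `"AA"`, `"Nitrogen"` or `"Other"`).
#' @export
pathway_group_of <- function(category) {
  carbon <- c("Complex Carbohydrates", "Feeder Pathways to Glycolysis", "Respiration")
  aa <- c("Amino acid transport and metabolism", "Amino acid synthesis")
  nitrogen <- "Nitrogen Metabolism"
  out <- rep("Other", length(category))
  out[category %in% carbon] <- "Carbon"
  out[category %in% aa] <- "AA"
  out[category %in% nitrogen] <- "Nitrogen"
  out
}

#' Configuration for the synthetic array generator
#'
#' Returns a validated configuration list. Defaults emulate the scale of a
#' 20-sample (10 healthy, 10 caries-active) functional-gene array study:
#' roughly 3,700 detectable genes, per-sample richness around 2,400-2,600,
#' and about 35% of a group's detected genes shared by all of its members.
#'
#' Non-core presence probabilities are drawn from a Beta distribution with
#' mean `noncore_presence_baseline` and concentration
#' `noncore_presence_conc`; per-gene group effects are symmetric shifts of
#' `group_effect` on the logit scale with random sign.
#'
#' @param n_samples_per_group Samples per host group (healthy H and
#'   caries-active C).
#' @param n_genes Total genes on the simulated array.
#' @param n_categories Number of functional gene categories.
#' @param category_weights Probability vector over categories (sums to 1).
#'   Defaults emulate the observed category shares (amino acid synthesis
#'   ~25%, amino acid transport and metabolism ~15%, ...).
#' @param category_names Category labels; length `n_categories`.
#' @param n_families Number of gene families spread over the categories.
#' @param core_fraction Proportion of genes present in every sample.
#' @param noncore_presence_baseline Mean presence probability of ordinary
#'   non-core genes.
#' @param noncore_presence_conc Beta concentration (a + b) of the non-core
#'   presence-probability distribution; small values give a wide spread with
#'   both rare and near-ubiquitous genes.
#' @param group_effect Magnitude of the per-gene logit shift of presence
#'   probability between groups (randomly signed per gene).
#' @param n_exclusive_per_group Genes present only in one group.
#' @param exclusive_presence Within-group presence probability of exclusive
#'   genes.
#' @param n_planted_triplets_per_group Discriminative gene triplets planted
#'   per group.
#' @param triplet_presence_high,triplet_presence_low Presence probability of
#'   planted triplet genes in their own / the other group.
#' @param copresence_blocks Data frame with columns `group`, `pathway`,
#'   `size` describing planted co-presence blocks (genes coupled through a
#'   per-sample latent state, yielding strongly positively associated
#'   presence profiles within the named group). Defaults plant larger
#'   blocks in the H group than in the C group, mirroring the greater
#'   non-core conservation of healthy microbiota.
#' @param block_on,block_off,block_latent_prob Presence probabilities of
#'   block genes given the latent state (on/off) and the latent Bernoulli
#'   probability.
#' @param intensity_log_mean,intensity_log_sd Lognormal parameters of
#'   positive signal intensities (drawn above the detection floor).
#' @param snr_log_mean,snr_log_sd Lognormal parameters of the
#'   signal-to-noise ratio of present genes (drawn above the SNR cutoff).
#' @param background_intensity_mean Mean background intensity of absent
#'   genes (below the detection cutoff).
#' @param background_log_sd Lognormal log-sd of background intensities.
#' @param background_snr_log_sd Lognormal log-sd of background SNR
#'   (mean 1).
#' @param detection_intensity,detection_snr Detection cutoffs the chip
#'   emulation guarantees: present genes exceed both, absent genes fall
#'   below at least one.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples_per_group = 10,
                       n_genes = 4000,
                       n_categories = 19,
                       category_weights = NULL,
                       category_names = NULL,
                       n_families = 139,
                       core_fraction = 0.175,
                       noncore_presence_baseline = 0.52,
                       noncore_presence_conc = 1.2,
                       group_effect = 0.6,
                       n_exclusive_per_group = 2,
                       exclusive_presence = 0.85,
                       n_planted_triplets_per_group = 1,
                       triplet_presence_high = 0.95,
                       triplet_presence_low = 0.05,
                       copresence_blocks = NULL,
                       block_on = 0.9,
                       block_off = 0.1,
                       block_latent_prob = 0.5,
                       intensity_log_mean = 8,
                       intensity_log_sd = 1,
                       snr_log_mean = log(4),
                       snr_log_sd = 0.5,
                       background_intensity_mean = 200,
                       background_log_sd = 0.5,
                       background_snr_log_sd = 0.3,
                       detection_intensity = 1000,
                       detection_snr = 2,
                       seed = 1L) {
  if (is.null(category_names) && is.null(category_weights) && n_categories == 19) {
    cats <- .default_categories()
    category_names <- cats$category
    category_weights <- cats$weight
  }
  if (is.null(category_names))
    category_names <- sprintf("Category %02d", seq_len(n_categories))
  if (is.null(category_weights))
    category_weights <- rep(1 / n_categories, n_categories)
  if (length(category_names) != n_categories)
    stop("'category_names' must have length n_categories", call. = FALSE)
  if (length(category_weights) != n_categories)
    stop("'category_weights' must have length n_categories", call. = FALSE)
  if (abs(sum(category_weights) - 1) > 1e-8)
    stop("'category_weights' must sum to 1", call. = FALSE)
  if (n_categories < 1) stop("'n_categories' must be >= 1", call. = FALSE)
  if (is.null(copresence_blocks)) {
    copresence_blocks <- data.frame(
      group = c("H", "H", "C", "C"),
      pathway = c("AA", "Carbon", "AA", "Carbon"),
      size = c(40L, 20L, 15L, 8L),
      stringsAsFactors = FALSE)
  }
  as_prob(c(core_fraction, noncore_presence_baseline, exclusive_presence,
            triplet_presence_high, triplet_presence_low,
            block_on, block_off, block_latent_prob),
          "presence probabilities")
  as_prob(category_weights, "category_weights")
  n_special <- 3L * n_planted_triplets_per_group + n_exclusive_per_group
  if (n_genes < n_special)
    stop("'n_genes' must be at least 3 * n_planted_triplets_per_group + ",
         "n_exclusive_per_group", call. = FALSE)
  if (n_samples_per_group < 1) stop("'n_samples_per_group' must be >= 1", call. = FALSE)
  cfg <- list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_genes = as.integer(n_genes),
    n_categories = as.integer(n_categories),
    category_weights = category_weights,
    category_names = category_names,
    n_families = as.integer(n_families),
    core_fraction = core_fraction,
    noncore_presence_baseline = noncore_presence_baseline,
    noncore_presence_conc = noncore_presence_conc,
    group_effect = group_effect,
    n_exclusive_per_group = as.integer(n_exclusive_per_group),
    exclusive_presence = exclusive_presence,
    n_planted_triplets_per_group = as.integer(n_planted_triplets_per_group),
    triplet_presence_high = triplet_presence_high,
    triplet_presence_low = triplet_presence_low,
    copresence_blocks = copresence_blocks,
    block_on = block_on,
    block_off = block_off,
    block_latent_prob = block_latent_prob,
    intensity_log_mean = intensity_log_mean,
    intensity_log_sd = intensity_log_sd,
    snr_log_mean = snr_log_mean,
    snr_log_sd = snr_log_sd,
    background_intensity_mean = background_intensity_mean,
    background_log_sd = background_log_sd,
    background_snr_log_sd = background_snr_log_sd,
    detection_intensity = detection_intensity,
    detection_snr = detection_snr,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a gene annotation table
#'
#' Assigns each simulated gene a functional category (drawn per the
#' configured category weights), a gene family nested within its category,
#' and a metabolic pathway group. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `gene_id`, `family`, `category`,
#'   `pathway_group`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "annotation"), {
    ids <- sprintf("gene_%05d", seq_len(config$n_genes))
    category <- sample(config$category_names, config$n_genes,
                       replace = TRUE, prob = config$category_weights)
    ## allocate families to categories proportional to weights (>= 1 each)
    fam_counts <- pmax(1L, round(config$category_weights *
                                   (config$n_families - config$n_categories)))
    fam_cat <- rep(config$category_names, fam_counts)
    fam_ids <- sprintf("fam_%03d", seq_along(fam_cat))
    family <- vapply(category, function(cc) {
      pool <- fam_ids[fam_cat == cc]
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, character(1), USE.NAMES = FALSE)
    data.frame(gene_id = ids, family = family, category = category,
               pathway_group = pathway_group_of(category),
               stringsAsFactors = FALSE)
  })
}

#' Construct a signal dataset container
#'
#' Bundles the paired intensity and signal-to-noise matrices with gene
#' annotation and sample metadata, checking that all indices align.
#'
#' @param intensity,snr Gene x sample numeric matrices with identical
#'   dimnames.
#' @param annotation Data frame with columns `gene_id`, `family`,
#'   `category`, `pathway_group` covering every gene.
#' @param metadata Data frame with columns `sample_id`, `group` (H/C),
#'   `dmft`, `gender`, `age` covering every sample.
#' @return An object of class `"signal_dataset"`.
#' @export
signal_dataset <- function(intensity, snr, annotation, metadata) {
  check_aligned(intensity, snr)
  if (any(intensity < 0) || any(snr < 0))
    stop("intensity and snr must be non-negative", call. = FALSE)
  if (!all(rownames(intensity) %in% annotation$gene_id))
    stop("annotation must cover every gene in the matrices", call. = FALSE)
  if (!all(colnames(intensity) %in% metadata$sample_id))
    stop("metadata must cover every sample in the matrices", call. = FALSE)
  if (!all(metadata$group %in% c("H", "C")))
    stop("sample groups must be 'H' or 'C'", call. = FALSE)
  structure(list(intensity = intensity, snr = snr,
                 annotation = annotation, metadata = metadata),
            class = "signal_dataset")
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("signal_dataset: %d genes x %d samples (%d H, %d C), %d categories\n",
              nrow(x$intensity), ncol(x$intensity),
              sum(x$metadata$group == "H"), sum(x$metadata$group == "C"),
              length(unique(x$annotation$category))))
  invisible(x)
}

#' Group labels of a signal dataset
#'
#' @param dataset A [signal_dataset()].
#' @return Named character vector mapping sample id to group (H/C).
#' @export
sample_groups <- function(dataset) {
  setNames(dataset$metadata$group, dataset$metadata$sample_id)[colnames(dataset$intensity)]
}

#' Simulate a functional-gene array dataset with known ground truth
#'
#' Generates paired intensity and SNR matrices for two host groups. Core
#' genes are present (above both detection cutoffs) in every sample;
#' non-core genes follow group-specific Bernoulli presence probabilities;
#' absent genes receive background intensity and SNR falling below at least
#' one cutoff. Group-exclusive genes, discriminative triplets and
#' co-presence blocks are planted per the configuration and reported in the
#' returned ground truth.
#'
#' @param config A [sim_config()].
#' @return List with elements `dataset` (a [signal_dataset()]) and `truth`,
#'   a list with `core_gene_ids`, `exclusive_gene_ids_by_group`,
#'   `planted_triplets_by_group`, `block_genes_by_group` and
#'   `presence_prob` (gene x group probability matrix).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  annotation <- generate_annotation(config)
  n <- config$n_samples_per_group
  samples <- c(sprintf("H%02d", seq_len(n)), sprintf("C%02d", seq_len(n)))
  groups <- rep(c("H", "C"), each = n)
  G <- config$n_genes

  with_seed(derive_seed(config$seed, "dataset"), {
    ids <- annotation$gene_id
    n_core <- round(config$core_fraction * G)
    core <- sort(sample(ids, n_core))
    pool <- setdiff(ids, core)

    take <- function(pool, k) {
      if (length(pool) < k) stop("not enough non-core genes to plant the requested structure",
                                 call. = FALSE)
      sort(sample(pool, k))
    }
    excl <- list(H = character(0), C = character(0))
    trip <- list(H = list(), C = list())
    blocks <- list(H = list(), C = list())
    for (g in c("H", "C")) {
      excl[[g]] <- take(pool, config$n_exclusive_per_group)
      pool <- setdiff(pool, excl[[g]])
      for (t in seq_len(config$n_planted_triplets_per_group)) {
        trip[[g]][[t]] <- take(pool, 3L)
        pool <- setdiff(pool, trip[[g]][[t]])
      }
    }
    bl <- config$copresence_blocks
    if (!is.null(bl) && nrow(bl)) {
      for (i in seq_len(nrow(bl))) {
        g <- bl$group[i]
        cand <- intersect(pool, annotation$gene_id[annotation$pathway_group == bl$pathway[i]])
        if (length(cand) < bl$size[i])
          stop(sprintf("not enough free genes in pathway group '%s' for a block of %d",
                       bl$pathway[i], bl$size[i]), call. = FALSE)
        b <- sort(sample(cand, bl$size[i]))
        blocks[[g]][[paste0(bl$pathway[i], "_", i)]] <- b
        pool <- setdiff(pool, b)
      }
    }

    ## per-gene presence probability by group
    p <- matrix(0, G, 2, dimnames = list(ids, c("H", "C")))
    p[core, ] <- 1
    base <- pool  # remaining ordinary non-core genes
    mu <- config$noncore_presence_baseline
    kap <- config$noncore_presence_conc
    p0 <- rbeta(length(base), mu * kap, (1 - mu) * kap)
    p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
    s <- sample(c(-1, 1), length(base), replace = TRUE)
    p[base, "H"] <- plogis(qlogis(p0) + s * config$group_effect / 2)
    p[base, "C"] <- plogis(qlogis(p0) - s * config$group_effect / 2)
    for (g in c("H", "C")) {
      other <- setdiff(c("H", "C"), g)
      p[excl[[g]], g] <- config$exclusive_presence
      p[excl[[g]], other] <- 0
      for (tg in trip[[g]]) {
        p[tg, g] <- config$triplet_presence_high
        p[tg, other] <- config$triplet_presence_low
      }
      marg <- config$block_latent_prob * config$block_on +
        (1 - config$block_latent_prob) * config$block_off
      for (bg in blocks[[g]]) {
        p[bg, g] <- marg
        p[bg, other] <- 0.5
      }
    }

    ## draw presence; block genes within their group are coupled by a
    ## per-sample latent state so their 0/1 profiles co-vary positively
    present <- matrix(runif(G * 2L * n) <
                        p[, rep(c(1L, 2L), each = n)], G, 2L * n,
                      dimnames = list(ids, samples))
    for (g in c("H", "C")) {
      gs <- samples[groups == g]
      for (bg in blocks[[g]]) {
        z <- runif(length(gs)) < config$block_latent_prob
        pb <- ifelse(z, config$block_on, config$block_off)
        present[bg, gs] <- matrix(runif(length(bg) * length(gs)), length(bg)) <
          matrix(pb, length(bg), length(gs), byrow = TRUE)
      }
    }

    ## intensities and SNR
    intensity <- matrix(0, G, 2L * n, dimnames = dimnames(present))
    snr <- intensity
    np <- sum(present)
    intensity[present] <- config$detection_intensity +
      rlnorm(np, config$intensity_log_mean, config$intensity_log_sd)
    snr[present] <- config$detection_snr +
      rlnorm(np, config$snr_log_mean, config$snr_log_sd)
    na <- sum(!present)
    intensity[!present] <- rlnorm(na,
      log(config$background_intensity_mean) - config$background_log_sd^2 / 2,
      config$background_log_sd)
    snr[!present] <- rlnorm(na, -config$background_snr_log_sd^2 / 2,
                            config$background_snr_log_sd)
    ## absent entries must fail at least one cutoff
    leak <- !present & intensity >= config$detection_intensity &
      snr >= config$detection_snr
    snr[leak] <- config$detection_snr * 0.9

    metadata <- data.frame(
      sample_id = samples, group = groups,
      dmft = ifelse(groups == "H", 0L, sample(6:10, 2L * n, replace = TRUE)),
      gender = sample(c("Male", "Female"), 2L * n, replace = TRUE),
      age = sample(18:23, 2L * n, replace = TRUE),
      stringsAsFactors = FALSE)
    metadata$dmft[groups == "H"] <- 0L

    truth <- list(core_gene_ids = core,
                  exclusive_gene_ids_by_group = excl,
                  planted_triplets_by_group = trip,
                  block_genes_by_group = blocks,
                  presence_prob = p)
    list(dataset = signal_dataset(intensity, snr, annotation, metadata),
         truth = truth)
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `intensity.tsv`, `snr.tsv`, `annotation.tsv`, `metadata.tsv` and,
#' when ground truth is supplied, `ground_truth.json` into `dir`. The TSV
#' matrices carry gene ids in the first column and sample ids as the header
#' row, and round-trip losslessly through [read_dataset()].
#'
#' @param dataset A [signal_dataset()].
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list from [simulate_dataset()].
#' @return Invisibly, the character vector of files written.
#' @export
write_dataset <- function(dataset, dir, truth = NULL) {
  stopifnot(inherits(dataset, "signal_dataset"))
  if (ncol(dataset$intensity) == 0L)
    stop("dataset has no samples", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    write_matrix_tsv(dataset$intensity, file.path(dir, "intensity.tsv")),
    write_matrix_tsv(dataset$snr, file.path(dir, "snr.tsv")),
    write_table_tsv(dataset$annotation, file.path(dir, "annotation.tsv")),
    write_table_tsv(dataset$metadata, file.path(dir, "metadata.tsv")))
  if (!is.null(truth)) {
    tr <- truth
    tr$presence_prob <- list(gene_id = rownames(truth$presence_prob),
                             H = unname(truth$presence_prob[, "H"]),
                             C = unname(truth$presence_prob[, "C"]))
    jf <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(tr, jf, auto_unbox = FALSE, digits = NA, pretty = TRUE)
    files <- c(files, jf)
  }
  invisible(files)
}
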