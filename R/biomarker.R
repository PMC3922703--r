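## Triplet-feature biomarker selection on binary non-core presence
## profiles: enumerate train/test groupings, score candidate gene triplets
## on training samples (majority-consensus patterns, Hamming
## nearest-consensus classification), validate on held-out samples, and
## detect exclusive-pattern genes.

#' Enumerate train/test groupings of a sample group
#'
#' All distinct ways of holding out `n_test` samples from the group, in
#' deterministic lexicographic order. Ten samples with three held out give
#' the 120 standard groupings.
#'
#' @param group_samples Character vector of the group's sample ids.
#' @param n_test Number of held-out (testing) samples.
#' @return List of splits, each a list with `train`, `test` and `index`.
#' @export
enumerate_groupings <- function(group_samples, n_test = 3) {
  n <- length(group_samples)
  if (n_test >= n) stop("'n_test' must be smaller than the group size", call. = FALSE)
  if (n_test < 1) stop("'n_test' must be at least 1", call. = FALSE)
  idx <- combn(n, n_test)
  lapply(seq_len(ncol(idx)), function(i) {
    test <- group_samples[idx[, i]]
    list(train = setdiff(group_samples, test), test = test, index = i)
  })
}

## Consensus presence pattern of genes over training samples: 1 when the
## majority of training samples carry the gene, 0 when the majority lack
## it, 0.5 for an exact tie (flagged ambiguous; it contributes half a
## mismatch to every Hamming distance, so tied samples count against the
## triplet).
consensus_pattern <- function(binary, samples) {
  rm <- rowMeans(binary[, samples, drop = FALSE])
  ifelse(rm > 0.5, 1, ifelse(rm < 0.5, 0, 0.5))
}

#' Evaluate a gene triplet on one pair of group splits
#'
#' The triplet's consensus pattern per group is the per-gene majority 0/1
#' over that group's training samples. The training discrimination score
#' is the fraction of training samples whose 3-bit profile is strictly
#' closer (Hamming distance) to their own group's consensus than to the
#' other group's. Each test sample is assigned to the group with the
#' nearer consensus (ties unclassified and counted incorrect); held-out
#' accuracy is the fraction of test samples assigned correctly.
#'
#' @param triplet Three distinct non-core gene ids.
#' @param noncore_binary Non-core gene x sample 0/1 matrix.
#' @param split_h,split_c Splits from [enumerate_groupings()] for the H
#'   and C groups.
#' @return List with `score`, `accuracy`, `consensus_h`, `consensus_c`,
#'   `ambiguous` (any tied consensus bit).
#' @export
evaluate_triplet <- function(triplet, noncore_binary, split_h, split_c) {
  triplet <- as.character(triplet)
  if (length(unique(triplet)) != 3L)
    stop("a triplet must consist of three distinct genes", call. = FALSE)
  bad <- setdiff(triplet, rownames(noncore_binary))
  if (length(bad))
    stop("not non-core genes (absent from the binary profile matrix): ",
         paste(bad, collapse = ", "), call. = FALSE)
  X <- noncore_binary[triplet, , drop = FALSE]
  ch <- consensus_pattern(X, split_h$train)
  cc <- consensus_pattern(X, split_c$train)
  dh <- colSums(abs(X - ch))
  dc <- colSums(abs(X - cc))
  train_ok <- sum(dh[split_h$train] < dc[split_h$train]) +
    sum(dc[split_c$train] < dh[split_c$train])
  test_ok <- sum(dh[split_h$test] < dc[split_h$test]) +
    sum(dc[split_c$test] < dh[split_c$test])
  list(score = train_ok / (length(split_h$train) + length(split_c$train)),
       accuracy = test_ok / (length(split_h$test) + length(split_c$test)),
       consensus_h = ch, consensus_c = cc,
       ambiguous = any(ch == 0.5) || any(cc == 0.5))
}

## Vectorized split evaluation used by select_triplets: `cand` is an
## m x 3 matrix of row indices into `binary`. Returns training scores and
## held-out accuracies for all m candidate triplets at once.
eval_candidates <- function(binary, cand, split_h, split_c) {
  ch <- consensus_pattern(binary, split_h$train)
  cc <- consensus_pattern(binary, split_c$train)
  CH <- abs(binary - ch)  # per-gene mismatch cost vs H consensus
  CC <- abs(binary - cc)
  DH <- CH[cand[, 1], , drop = FALSE] + CH[cand[, 2], , drop = FALSE] +
    CH[cand[, 3], , drop = FALSE]
  DC <- CC[cand[, 1], , drop = FALSE] + CC[cand[, 2], , drop = FALSE] +
    CC[cand[, 3], , drop = FALSE]
  closer_h <- DH < DC
  closer_c <- DC < DH
  n_train <- length(split_h$train) + length(split_c$train)
  n_test <- length(split_h$test) + length(split_c$test)
  score <- (rowSums(closer_h[, split_h$train, drop = FALSE]) +
              rowSums(closer_c[, split_c$train, drop = FALSE])) / n_train
  accuracy <- (rowSums(closer_h[, split_h$test, drop = FALSE]) +
                 rowSums(closer_c[, split_c$test, drop = FALSE])) / n_test
  list(score = score, accuracy = accuracy)
}

#' Select discriminative gene triplets by bootstrapped split evaluation
#'
#' For each bootstrap iteration a training/testing grouping is drawn
#' uniformly for each host group. Feature selection ranks non-core genes
#' by the absolute difference of their training presence frequencies
#' between groups and keeps the top `pool_size`; candidate triplets are
#' enumerated from the pool (sampled down to `n_candidates_per_split` when
#' the pool is large), scored on the training samples, and validated on
#' the held-out samples. A triplet is selected when its mean held-out
#' accuracy over all splits in which it was evaluated reaches
#' `accuracy_threshold`. Each selected triplet is attributed to the group
#' in whose full-sample consensus it is predominantly present. Ties in
#' mean accuracy are broken in favour of group-coherent triplets (all
#' three genes sharing the same group-specific consensus pattern), then
#' by the weakest gene's between-group presence difference, training
#' score, and number of evaluations.
#'
#' @param noncore_binary Non-core gene x sample 0/1 matrix (>= 3 genes).
#' @param groups Named vector mapping sample id to group ("H"/"C").
#' @param accuracy_threshold Minimum mean held-out accuracy in (0, 1];
#'   0 returns every evaluated triplet.
#' @param n_bootstrap Bootstrap iterations (split draws).
#' @param pool_size Genes kept by per-split feature selection.
#' @param n_candidates_per_split Maximum candidate triplets per split.
#' @param n_test Held-out samples per group in each split.
#' @param seed Seed controlling split draws and candidate sampling.
#' @return Object of class `"biomarker_report"`: `triplets` (data frame
#'   ranked by mean accuracy then training score), `selected` (the subset
#'   passing the threshold), `gene_frequencies`, `exclusive_genes` and
#'   `provenance`.
#' @export
select_triplets <- function(noncore_binary, groups, accuracy_threshold = 0.8,
                            n_bootstrap = 30, pool_size = 30,
                            n_candidates_per_split = 5000,
                            n_test = 3, seed = NULL) {
  if (accuracy_threshold < 0 || accuracy_threshold > 1)
    stop("'accuracy_threshold' must lie in [0, 1]", call. = FALSE)
  if (nrow(noncore_binary) < 3)
    stop("at least three non-core genes required", call. = FALSE)
  samples_h <- names(groups)[groups == "H"]
  samples_c <- names(groups)[groups == "C"]
  splits_h <- enumerate_groupings(samples_h, n_test)
  splits_c <- enumerate_groupings(samples_c, n_test)
  genes <- rownames(noncore_binary)
  pool_size <- min(pool_size, length(genes))

  store <- new.env(parent = emptyenv())
  record <- function(key, acc, sc) {
    cur <- get0(key, envir = store, inherits = FALSE,
                ifnotfound = c(n = 0, acc = 0, score = 0))
    store[[key]] <- c(n = cur[["n"]] + 1,
                      acc = cur[["acc"]] + unname(acc),
                      score = cur[["score"]] + unname(sc))
  }

  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      sh <- splits_h[[sample.int(length(splits_h), 1)]]
      sc_ <- splits_c[[sample.int(length(splits_c), 1)]]
      ## feature selection on training presence frequencies
      dif <- abs(rowMeans(noncore_binary[, sh$train, drop = FALSE]) -
                   rowMeans(noncore_binary[, sc_$train, drop = FALSE]))
      pool <- genes[order(-dif, genes)][seq_len(pool_size)]
      pool_idx <- match(pool, genes)
      n_all <- choose(pool_size, 3)
      if (n_all <= n_candidates_per_split) {
        cand_local <- t(combn(pool_size, 3))
      } else {
        pick <- matrix(0L, n_candidates_per_split, 3)
        for (i in seq_len(n_candidates_per_split))
          pick[i, ] <- sort(sample.int(pool_size, 3))
        cand_local <- unique(pick)
      }
      cand <- matrix(pool_idx[cand_local], ncol = 3)
      ev <- eval_candidates(noncore_binary, cand, sh, sc_)
      keymat <- matrix(genes[cand], ncol = 3)
      keymat <- t(apply(keymat, 1, sort))
      keys <- paste(keymat[, 1], keymat[, 2], keymat[, 3], sep = "|")
      for (i in seq_along(keys)) record(keys[i], ev$accuracy[i], ev$score[i])
    }
  })

  keys <- sort(ls(store))
  if (!length(keys)) {
    warning("no triplet was evaluated; empty report")
    trip <- data.frame(gene1 = character(0), gene2 = character(0),
                       gene3 = character(0), group = character(0),
                       coherence = numeric(0), specificity = numeric(0),
                       n_eval = integer(0),
                       mean_score = numeric(0), mean_accuracy = numeric(0))
  } else {
    agg <- t(vapply(keys, function(k) store[[k]],
                    c(n = 0, acc = 0, score = 0)))
    gs <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    ## group attribution: the group in whose full-sample consensus the
    ## triplet is predominantly present (majority of 1-bits)
    gene_diff <- abs(rowMeans(noncore_binary[, samples_h, drop = FALSE]) -
                       rowMeans(noncore_binary[, samples_c, drop = FALSE]))
    attrib <- vapply(seq_len(nrow(gs)), function(i) {
      tri <- gs[i, ]
      ch <- consensus_pattern(noncore_binary[tri, , drop = FALSE], samples_h)
      cc <- consensus_pattern(noncore_binary[tri, , drop = FALSE], samples_c)
      c(oh = sum(ch), oc = sum(cc), specificity = min(gene_diff[tri]))
    }, c(oh = 0, oc = 0, specificity = 0))
    grp <- ifelse(attrib["oh", ] > attrib["oc", ], "H",
                  ifelse(attrib["oc", ] > attrib["oh", ], "C", NA_character_))
    trip <- data.frame(gene1 = gs[, 1], gene2 = gs[, 2], gene3 = gs[, 3],
                       group = grp,
                       coherence = abs(attrib["oh", ] - attrib["oc", ]),
                       specificity = attrib["specificity", ],
                       n_eval = as.integer(agg[, "n"]),
                       mean_score = agg[, "score"] / agg[, "n"],
                       mean_accuracy = agg[, "acc"] / agg[, "n"],
                       stringsAsFactors = FALSE)
    trip <- trip[order(-trip$mean_accuracy, -trip$coherence,
                       -trip$specificity, -trip$mean_score,
                       -trip$n_eval, trip$gene1, trip$gene2, trip$gene3), ]
    rownames(trip) <- NULL
  }
  trip$rank <- seq_len(nrow(trip))
  selected <- trip[trip$mean_accuracy >= accuracy_threshold, , drop = FALSE]
  if (!nrow(selected) && nrow(trip))
    warning("no triplet reached the accuracy threshold; report is empty")
  report <- structure(list(
    triplets = trip, selected = selected,
    gene_frequencies = NULL, exclusive_genes = NULL,
    provenance = list(seed = seed, n_bootstrap = n_bootstrap,
                      pool_size = pool_size,
                      n_candidates_per_split = n_candidates_per_split,
                      n_test = n_test,
                      accuracy_threshold = accuracy_threshold)),
    class = "biomarker_report")
  report$gene_frequencies <- gene_frequencies(report)
  if (nrow(selected)) report$exclusive_genes <- detect_exclusive_genes(report)
  report
}

#' Per-gene frequency across selected triplets
#'
#' @param report A `"biomarker_report"`.
#' @return Data frame with `gene_id`, `group`, `n_triplets`.
#' @export
gene_frequencies <- function(report) {
  sel <- report$selected
  if (!nrow(sel))
    return(data.frame(gene_id = character(0), group = character(0),
                      n_triplets = integer(0)))
  long <- data.frame(
    gene_id = c(sel$gene1, sel$gene2, sel$gene3),
    group = rep(sel$group, 3), stringsAsFactors = FALSE)
  long <- long[!is.na(long$group), , drop = FALSE]
  agg <- stats::aggregate(list(n_triplets = rep(1L, nrow(long))),
                          by = long[c("gene_id", "group")], FUN = sum)
  agg[order(-agg$n_triplets, agg$gene_id), , drop = FALSE]
}

#' Detect exclusive-pattern genes
#'
#' Genes appearing in at least one selected triplet of exactly one group,
#' labeled H-exclusive or C-exclusive.
#'
#' @param report A `"biomarker_report"` with at least one selected
#'   triplet.
#' @return Data frame with `gene_id` and `group`.
#' @export
detect_exclusive_genes <- function(report) {
  sel <- report$selected
  if (!nrow(sel)) stop("report has no selected triplets", call. = FALSE)
  by_group <- function(g) unique(unlist(
    sel[!is.na(sel$group) & sel$group == g, c("gene1", "gene2", "gene3")]))
  h <- by_group("H"); c_ <- by_group("C")
  only_h <- setdiff(h, c_)
  only_c <- setdiff(c_, h)
  out <- rbind(
    data.frame(gene_id = only_h, group = rep("H", length(only_h)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = only_c, group = rep("C", length(only_c)),
               stringsAsFactors = FALSE))
  out[order(out$gene_id), , drop = FALSE]
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat(sprintf(paste0("biomarker_report: %d triplets evaluated, %d selected ",
                     "(mean held-out accuracy >= %.2f)\n"),
              nrow(x$triplets), nrow(x$selected),
              x$provenance$accuracy_threshold))
  if (!is.null(x$exclusive_genes) && nrow(x$exclusive_genes))
    cat(sprintf("  exclusive-pattern genes: %s\n",
                paste(sprintf("%s (%s)", x$exclusive_genes$gene_id,
                              x$exclusive_genes$group), collapse = ", ")))
  invisible(x)
}
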