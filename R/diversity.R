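## Per-sample diversity statistics and permutation t-tests comparing the
## healthy (H) and caries-active (C) host groups.

#' Per-sample diversity indices
#'
#' Computes, for each sample (column), the detected-gene richness, the
#' Shannon index in natural-log units, and the inverse Simpson index
#' (1 / sum p^2, the effective number of equally abundant genes).
#'
#' @param normalized Relative-abundance matrix whose columns sum to 1 over
#'   detected genes (see [normalize_abundance()]).
#' @return Data frame with columns `sample_id`, `richness`, `shannon`,
#'   `inverse_simpson`.
#' @export
diversity_indices <- function(normalized) {
  if (any(colSums(normalized) <= 0))
    stop("sample(s) with no abundance: ",
         paste(colnames(normalized)[colSums(normalized) <= 0], collapse = ", "),
         call. = FALSE)
  sh <- apply(normalized, 2, function(p) {
    p <- p[p > 0]; p <- p / sum(p); -sum(p * log(p))
  })
  inv <- apply(normalized, 2, function(p) {
    p <- p[p > 0]; p <- p / sum(p); 1 / sum(p^2)
  })
  data.frame(sample_id = colnames(normalized),
             richness = colSums(normalized > 0),
             shannon = sh, inverse_simpson = inv,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Welch (or pooled) t statistic; returns 0 for a fully degenerate
## comparison (zero spread, equal means) and +-Inf for zero spread with
## distinct means.
welch_t <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1); vy <- sum((y - my)^2) / (ny - 1)
  se2 <- if (var_equal) {
    sp <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    sp * (1 / nx + 1 / ny)
  } else vx / nx + vy / ny
  d <- mx - my
  if (se2 <= 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sqrt(se2)
}

#' Two-sided permutation t-test for a group comparison
#'
#' The observed statistic is a Welch t (pooled-variance t optionally).
#' The null distribution is formed by reassigning group labels: all
#' distinct label splits when their number is at most `exhaustive_limit`,
#' otherwise `n_perm` Monte-Carlo draws. The two-sided p-value is the
#' proportion of permuted |t| at least as large as the observed |t|
#' (with the add-one correction in the Monte-Carlo case).
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Group label per sample (exactly two levels, each with at
#'   least two samples).
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Seed for the Monte-Carlo draws.
#' @param exhaustive_limit Enumerate all splits when `choose(n, n1)` does
#'   not exceed this.
#' @param var_equal Use the pooled-variance t instead of Welch.
#' @return List with `statistic`, `p_value`, `tier`, `method`
#'   (`"exhaustive"` or `"monte-carlo"`) and `n_perm`.
#' @export
permutation_t_test <- function(values, labels, n_perm = 999, seed = NULL,
                               exhaustive_limit = 20000, var_equal = FALSE) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  i1 <- which(labels == lev[1])
  n <- length(values); n1 <- length(i1)
  if (n1 < 2L || n - n1 < 2L) stop("each group needs at least two samples", call. = FALSE)
  t_obs <- welch_t(values[i1], values[-i1], var_equal)
  tol <- 1e-12
  n_comb <- choose(n, n1)
  if (n_comb <= exhaustive_limit) {
    idx <- combn(n, n1)
    tp <- apply(idx, 2, function(i) welch_t(values[i], values[-i], var_equal))
    p <- mean(abs(tp) >= abs(t_obs) - tol)
    method <- "exhaustive"; used <- ncol(idx)
  } else {
    tp <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      i <- sample.int(n, n1)
      welch_t(values[i], values[-i], var_equal)
    }, numeric(1)))
    p <- (sum(abs(tp) >= abs(t_obs) - tol) + 1) / (n_perm + 1)
    method <- "monte-carlo"; used <- n_perm
  }
  list(statistic = t_obs, p_value = p, tier = significance_tier(p),
       method = method, n_perm = used)
}

#' Significance tier of a p-value
#'
#' Strict-inequality tiering: `***` for p < 0.01, `**` for p < 0.05,
#' `*` for p < 0.1, `NS` otherwise (so p = 0.05 is `*`, not `**`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "NS")))
}

#' Rank core genes by variability of normalized intensity
#'
#' Computes the sample standard deviation of each core gene's normalized
#' intensity across all samples and returns the genes sorted from most to
#' least varied.
#'
#' @param normalized Relative-abundance matrix.
#' @param core_genes Character vector of core gene ids.
#' @param annotation Optional annotation data frame (`gene_id`, `family`,
#'   `category`) merged into the output.
#' @return Data frame with `gene_id`, `sd`, `rank` (1 = most varied) and a
#'   `flag` column marking the most and least varied core genes.
#' @export
core_variability_ranking <- function(normalized, core_genes, annotation = NULL) {
  if (!length(core_genes)) stop("core gene set is empty", call. = FALSE)
  m <- normalized[core_genes, , drop = FALSE]
  sds <- apply(m, 1, sd)
  ord <- order(-sds, rownames(m))
  out <- data.frame(gene_id = rownames(m)[ord], sd = sds[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$flag <- ""
  out$flag[1] <- "most_varied"
  out$flag[nrow(out)] <- "least_varied"
  if (!is.null(annotation)) {
    out <- merge(out, annotation, by = "gene_id", sort = FALSE)
    out <- out[order(out$rank), ]
    rownames(out) <- NULL
  }
  out
}

#' Row-wise permutation t-tests between groups
#'
#' Applies [permutation_t_test()] to every row of a matrix (genes or gene
#' categories) and reports raw p-values, Benjamini-Hochberg adjusted
#' p-values, and significance tiers based on the raw p-values.
#'
#' @param mat Feature x sample numeric matrix.
#' @param labels Group label per column.
#' @param n_perm,seed,var_equal Passed to [permutation_t_test()].
#' @return Data frame with one row per feature.
#' @export
compare_groups <- function(mat, labels, n_perm = 999, seed = NULL,
                           var_equal = FALSE) {
  res <- lapply(seq_len(nrow(mat)), function(i)
    permutation_t_test(mat[i, ], labels, n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                       var_equal = var_equal))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  data.frame(feature = rownames(mat),
             statistic = vapply(res, `[[`, numeric(1), "statistic"),
             p_value = p,
             p_adjust_bh = stats::p.adjust(p, "BH"),
             tier = significance_tier(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
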