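## Gene sharing between and among microbiota: pairwise shared fractions,
## the within-group core fraction, and the shared-gene saturation curve.

#' Shared-gene percentage between two samples
#'
#' Percentage of genes detected in both samples, relative to the chosen
#' denominator: the union of the two detected sets (default), their mean
#' size, or the smaller set.
#'
#' @param detected Logical gene x sample detection matrix.
#' @param sample_a,sample_b Sample ids (column names).
#' @param denominator One of `"union"`, `"mean"`, `"min"`.
#' @return Percentage in \[0, 100\].
#' @export
pairwise_shared_fraction <- function(detected, sample_a, sample_b,
                                     denominator = c("union", "mean", "min")) {
  denominator <- match.arg(denominator)
  a <- detected[, sample_a]; b <- detected[, sample_b]
  inter <- sum(a & b)
  denom <- switch(denominator,
                  union = sum(a | b),
                  mean = (sum(a) + sum(b)) / 2,
                  min = min(sum(a), sum(b)))
  if (denom == 0) stop("both samples have empty detected sets", call. = FALSE)
  100 * inter / denom
}

#' All pairwise shared-gene percentages within a sample set
#'
#' @inheritParams pairwise_shared_fraction
#' @param samples Sample ids to compare (default: all columns).
#' @return Symmetric matrix of percentages (diagonal 100).
#' @export
pairwise_shared_matrix <- function(detected, samples = colnames(detected),
                                   denominator = c("union", "mean", "min")) {
  denominator <- match.arg(denominator)
  k <- length(samples)
  m <- matrix(100, k, k, dimnames = list(samples, samples))
  if (k > 1) for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <-
      pairwise_shared_fraction(detected, samples[i], samples[j], denominator)
  }
  m
}

#' Fraction of genes shared by every member of a sample subset
#'
#' The numerator counts genes detected in every subset sample; the
#' denominator counts genes detected in at least one subset sample (the
#' subset union). The percentage is rounded to one decimal.
#'
#' @param detected Logical gene x sample detection matrix.
#' @param samples Sample ids forming the subset.
#' @return List with `n_shared`, `n_total`, `percentage`.
#' @export
group_core_fraction <- function(detected, samples = colnames(detected)) {
  if (!length(samples)) stop("sample subset is empty", call. = FALSE)
  sub <- detected[, samples, drop = FALSE]
  k <- rowSums(sub)
  n_shared <- sum(k == length(samples))
  n_total <- sum(k >= 1L)
  list(n_shared = n_shared, n_total = n_total,
       percentage = round(100 * n_shared / n_total, 1))
}

#' Shared-gene saturation curve
#'
#' For each host count k from 1 to the pool size, draws `n_iter` random
#' k-subsets of the pool (without replacement within a subset) and counts
#' the genes detected in all k members; reports the mean and standard
#' deviation over iterations. At k equal to the pool size the value is the
#' exact group core and the standard deviation is 0.
#'
#' @param detected Logical gene x sample detection matrix.
#' @param samples Sample pool (default: all columns).
#' @param n_iter Iterations per k.
#' @param seed Seed for subset sampling.
#' @return Data frame with columns `k`, `mean_shared`, `sd_shared`,
#'   `n_iter`.
#' @export
saturation_curve <- function(detected, samples = colnames(detected),
                             n_iter = 100, seed = NULL) {
  n <- length(samples)
  if (n < 1) stop("sample pool is empty", call. = FALSE)
  sub <- detected[, samples, drop = FALSE]
  with_seed(seed, {
    out <- lapply(seq_len(n), function(k) {
      if (k == n) {
        shared <- sum(rowSums(sub) == n)
        c(mean = shared, sd = 0)
      } else {
        counts <- vapply(seq_len(n_iter), function(i) {
          pick <- sample.int(n, k)
          sum(rowSums(sub[, pick, drop = FALSE]) == k)
        }, numeric(1))
        c(mean = mean(counts), sd = sd(counts))
      }
    })
    data.frame(k = seq_len(n),
               mean_shared = vapply(out, `[[`, numeric(1), "mean"),
               sd_shared = vapply(out, `[[`, numeric(1), "sd"),
               n_iter = c(rep(n_iter, n - 1), 1L),
               row.names = NULL)
  })
}
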