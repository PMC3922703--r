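## Community-structure statistics: correspondence analysis with detrending
## by segments, and the multi-response permutation procedure (MRPP).

#' Correspondence analysis of a gene x sample abundance matrix
#'
#' Chi-square standardized residual decomposition by singular values:
#' with P the matrix scaled to sum 1 and r, c its row and column masses,
#' the SVD of (P - r c') / sqrt(r c') yields eigenvalues (squared singular
#' values) and row (gene) and column (sample) principal scores.
#'
#' @param x Non-negative gene x sample matrix with no all-zero row or
#'   column.
#' @param n_axes Number of axes to return (capped at the rank).
#' @return List of class `"ordination_result"` with `sample_scores`,
#'   `gene_scores` (matrices, axes in columns), `eigenvalues`, and
#'   `n_segments` (NA for plain CA).
#' @export
correspondence_analysis <- function(x, n_axes = 4) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundance matrix must be non-negative", call. = FALSE)
  zr <- rowSums(x) == 0; zc <- colSums(x) == 0
  if (any(zr) || any(zc))
    stop("all-zero rows/columns: ",
         paste(c(rownames(x)[zr], colnames(x)[zc]), collapse = ", "),
         call. = FALSE)
  P <- x / sum(x)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  dec <- svd(S)
  k <- min(n_axes, sum(dec$d > 1e-12))
  if (k < 1) stop("matrix has rank 0 after centering", call. = FALSE)
  ax <- seq_len(k)
  eig <- dec$d[ax]^2
  gene_scores <- sweep(dec$u[, ax, drop = FALSE] %*% diag(dec$d[ax], k), 1,
                       sqrt(r), "/")
  sample_scores <- sweep(dec$v[, ax, drop = FALSE] %*% diag(dec$d[ax], k), 1,
                         sqrt(cc), "/")
  dimnames(gene_scores) <- list(rownames(x), paste0("axis", ax))
  dimnames(sample_scores) <- list(colnames(x), paste0("axis", ax))
  structure(list(sample_scores = sample_scores, gene_scores = gene_scores,
                 eigenvalues = eig, n_segments = NA_integer_),
            class = "ordination_result")
}

#' Detrended correspondence analysis (detrending by segments)
#'
#' Runs [correspondence_analysis()], keeps axis 1 unchanged, and removes
#' the arch effect from axis 2 by splitting the axis-1 range of the sample
#' scores into `n_segments` equal bins and centering axis-2 scores within
#' each bin. No nonlinear rescaling is applied.
#'
#' @inheritParams correspondence_analysis
#' @param n_segments Number of detrending segments (>= 1; 1 reduces to
#'   global centering).
#' @return An `"ordination_result"`; `sample_scores[, "axis2"]` holds the
#'   detrended scores.
#' @export
detrended_ca <- function(x, n_segments = 26, n_axes = 4) {
  if (n_segments < 1) stop("'n_segments' must be >= 1", call. = FALSE)
  res <- correspondence_analysis(x, n_axes = n_axes)
  if (ncol(res$sample_scores) < 2)
    stop("fewer than 2 ordination axes available", call. = FALSE)
  a1 <- res$sample_scores[, 1]
  rng <- range(a1)
  if (diff(rng) <= 0) stop("degenerate axis-1 range", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_segments + 1)
  bin <- findInterval(a1, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  a2 <- res$sample_scores[, 2]
  res$sample_scores[, 2] <- a2 - stats::ave(a2, bin)
  res$n_segments <- as.integer(n_segments)
  res
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result: %d samples, %d axes; eigenvalues %s%s\n",
              nrow(x$sample_scores), ncol(x$sample_scores),
              paste(signif(x$eigenvalues, 3), collapse = ", "),
              if (!is.na(x$n_segments))
                sprintf(" (detrended, %d segments)", x$n_segments) else ""))
  invisible(x)
}

## Weighted mean within-group distance; D is a full symmetric matrix.
mrpp_delta <- function(D, labels) {
  N <- length(labels)
  delta <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    ni <- length(i)
    delta <- delta + (ni / N) * mean(D[i, i][upper.tri(matrix(0, ni, ni))])
  }
  delta
}

#' Multi-response permutation procedure (MRPP)
#'
#' Tests whether within-group sample distances are smaller than expected
#' under random group labeling. The observed delta is the group-size
#' weighted (n_i / N) mean of within-group pairwise distances; the null
#' distribution is built from `n_perm` random label permutations, and
#' p = (#\{delta_perm <= delta_obs\} + 1) / (n_perm + 1). The
#' chance-corrected within-group agreement is A = 1 - observed/expected.
#'
#' @param x Gene x sample abundance matrix (samples in columns) or a
#'   `dist` object over samples.
#' @param labels Group label per sample (>= 2 groups, each >= 2 samples).
#' @param metric Distance for matrix input: `"bray"` (Bray-Curtis, the
#'   default for normalized intensities) or `"euclidean"`.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutations.
#' @return List of class `"mrpp_result"`: `delta_observed`,
#'   `delta_expected`, `A`, `p_value`, `n_perm`, `metric`.
#' @export
mrpp_test <- function(x, labels, metric = c("bray", "euclidean"),
                      n_perm = 999, seed = NULL) {
  metric <- match.arg(metric)
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
    metric <- attr(x, "method") %||% metric
  } else {
    D <- as.matrix(vegan::vegdist(t(as.matrix(x)), method = metric))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(D))
    stop("one label per sample required", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("at least two groups with at least two samples each", call. = FALSE)
  delta_obs <- mrpp_delta(D, labels)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    mrpp_delta(D, sample(labels)), numeric(1)))
  p <- (sum(perm <= delta_obs + 1e-12) + 1) / (n_perm + 1)
  expected <- mean(perm)
  structure(list(delta_observed = delta_obs, delta_expected = expected,
                 A = 1 - delta_obs / expected, p_value = p,
                 n_perm = n_perm, metric = metric),
            class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat(sprintf("MRPP (%s): delta = %.4f (expected %.4f), A = %.4f, p = %.4g [%d permutations]\n",
              x$metric, x$delta_observed, x$delta_expected, x$A, x$p_value,
              x$n_perm))
  invisible(x)
}
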