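## Detection calling, per-sample normalization, the core/non-core gene
## partition and category-level aggregates.

#' Call positive (detected) genes from intensity and SNR
#'
#' A gene is called present in a sample when its signal intensity and its
#' signal-to-noise ratio both reach the cutoffs (defaults: intensity 1000,
#' SNR 2, the standard positive-calling rule for this chip family).
#'
#' @param dataset A [signal_dataset()], or an intensity matrix when `snr`
#'   is supplied separately.
#' @param min_intensity Minimum signal intensity.
#' @param min_snr Minimum signal-to-noise ratio.
#' @param snr Optional SNR matrix when `dataset` is a plain matrix.
#' @return Logical gene x sample matrix of detection calls.
#' @export
call_positives <- function(dataset, min_intensity = 1000, min_snr = 2, snr = NULL) {
  if (inherits(dataset, "signal_dataset")) {
    intensity <- dataset$intensity
    snr <- dataset$snr
  } else {
    intensity <- dataset
    if (is.null(snr)) stop("'snr' matrix required when 'dataset' is a matrix",
                           call. = FALSE)
  }
  check_aligned(intensity, snr)
  intensity >= min_intensity & snr >= min_snr
}

#' Normalize detected intensities to per-sample relative abundances
#'
#' Within each sample, detected-gene intensities are divided by the
#' sample's total detected intensity (total-sum scaling); undetected
#' entries are 0, so every column sums to 1 over detected genes.
#'
#' @param intensity Gene x sample intensity matrix, or a
#'   [signal_dataset()].
#' @param detected Logical detection matrix from [call_positives()].
#' @return Relative-abundance matrix of the same shape.
#' @export
normalize_abundance <- function(intensity, detected) {
  if (inherits(intensity, "signal_dataset")) intensity <- intensity$intensity
  check_aligned(intensity, detected, "intensity", "detected")
  masked <- intensity * detected
  tot <- colSums(masked)
  empty <- tot <= 0
  if (any(empty))
    stop("no detected genes in sample(s): ",
         paste(colnames(intensity)[empty], collapse = ", "), call. = FALSE)
  sweep(masked, 2, tot, "/")
}

#' Partition genes into core and non-core sets
#'
#' Core genes are detected in every sample; non-core genes are detected in
#' at least one but not all samples. Genes never detected belong to
#' neither set and are dropped from downstream analysis.
#'
#' @param detected Logical gene x sample detection matrix.
#' @return List with character vectors `core` and `noncore`.
#' @export
partition_core_noncore <- function(detected) {
  if (ncol(detected) < 1L) stop("at least one sample required", call. = FALSE)
  k <- rowSums(detected)
  list(core = rownames(detected)[k == ncol(detected)],
       noncore = rownames(detected)[k >= 1L & k < ncol(detected)])
}

#' Build a detection profile from a signal dataset
#'
#' Convenience constructor running [call_positives()],
#' [normalize_abundance()] and [partition_core_noncore()] and packaging the
#' results, including the binary presence matrix of non-core genes used by
#' the network and biomarker stages.
#'
#' @inheritParams call_positives
#' @return List of class `"detection_profile"` with elements `detected`,
#'   `normalized`, `core_genes`, `noncore_genes`, `noncore_binary` and the
#'   cutoffs used.
#' @export
detection_profile <- function(dataset, min_intensity = 1000, min_snr = 2) {
  stopifnot(inherits(dataset, "signal_dataset"))
  detected <- call_positives(dataset, min_intensity, min_snr)
  normalized <- normalize_abundance(dataset$intensity, detected)
  part <- partition_core_noncore(detected)
  nb <- detected[part$noncore, , drop = FALSE] * 1L
  structure(list(detected = detected, normalized = normalized,
                 core_genes = part$core, noncore_genes = part$noncore,
                 noncore_binary = nb,
                 min_intensity = min_intensity, min_snr = min_snr),
            class = "detection_profile")
}

#' @export
print.detection_profile <- function(x, ...) {
  cat(sprintf(paste0("detection_profile: %d genes detected in >=1 of %d samples\n",
                     "  core (all samples): %d; non-core: %d\n"),
              length(x$core_genes) + length(x$noncore_genes),
              ncol(x$detected), length(x$core_genes), length(x$noncore_genes)))
  invisible(x)
}

#' Aggregate abundance and richness by gene category
#'
#' Per sample, a category's relative abundance is the sum of normalized
#' intensities of its detected genes and its relative diversity is the
#' fraction of detected genes it contributes; both sum to 1 per sample.
#'
#' @param profile A [detection_profile()].
#' @param annotation Gene annotation data frame with `gene_id` and
#'   `category` columns covering every detected gene.
#' @return List with category x sample matrices `abundance` and
#'   `diversity`.
#' @export
aggregate_by_category <- function(profile, annotation) {
  stopifnot(inherits(profile, "detection_profile"))
  det_genes <- c(profile$core_genes, profile$noncore_genes)
  missing <- setdiff(det_genes, annotation$gene_id)
  if (length(missing))
    stop("detected genes without annotation: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10),
         call. = FALSE)
  cat_of <- setNames(annotation$category, annotation$gene_id)
  f <- factor(cat_of[rownames(profile$normalized)])
  abundance <- rowsum(profile$normalized, f)
  div_counts <- rowsum(profile$detected * 1L, f)
  diversity <- sweep(div_counts, 2, colSums(div_counts), "/")
  list(abundance = as.matrix(abundance), diversity = as.matrix(diversity))
}
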