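## Readers and writers for the package's plain-text artifacts. All tables
## are UTF-8, tab-separated, with a header row; matrices carry gene ids in
## the first column and sample ids as the remaining column names.

#' Write a numeric matrix as TSV
#'
#' @param mat Matrix with row and column names.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path Input file.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table written by [write_table_tsv()]
#'
#' @param path Input file.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Read a signal dataset from a directory
#'
#' Expects the file layout produced by [write_dataset()]: `intensity.tsv`,
#' `snr.tsv`, `annotation.tsv` and `metadata.tsv`.
#'
#' @param dir Directory containing the files.
#' @return A [signal_dataset()].
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("intensity.tsv", "snr.tsv", "annotation.tsv", "metadata.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stop("missing dataset files: ", paste(basename(miss), collapse = ", "),
         call. = FALSE)
  signal_dataset(read_matrix_tsv(need[1]), read_matrix_tsv(need[2]),
                 read_table_tsv(need[3]), read_table_tsv(need[4]))
}
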