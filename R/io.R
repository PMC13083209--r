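#' Read / write ASV count tables
#'
#' TSV layout: samples in rows, ASVs in columns, first column `sample`
#' holding sample ids, header row of ASV ids. Round-trips preserve integer
#' storage and ordering.
#'
#' @param path File path.
#' @return `read_counts()`: an integer matrix with sample rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (all(m == round(m))) storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Samples x ASVs matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write sample metadata tables (TSV)
#' @param path File path.
#' @return `read_metadata()`: a tibble.
#' @export
read_metadata <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_metadata
#' @param metadata A data frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a square distance matrix as TSV with an id header
#' @param d Square matrix or `dist`.
#' @param path File path.
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
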