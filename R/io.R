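#' Write a CpG-by-sample matrix as CSV
#'
#' First column holds the CpG ids (`cpg_id`), the header row the sample ids.
#'
#' @param mat matrix with rownames (CpG ids) and colnames (sample ids).
#' @param path output file path.
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.frame(cpg_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a CpG-by-sample matrix from CSV
#'
#' @param path CSV written by [write_matrix_csv()] (first column CpG ids,
#'   header sample ids).
#' @return numeric matrix with CpG rownames and sample colnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
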