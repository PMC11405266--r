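#' Read and write protein matrices as delimited tables
#'
#' The on-disk schema is a CSV with a `sample_id` first column and one
#' column per protein; empty cells are missing values.
#'
#' @param matrix samples-by-proteins numeric matrix.
#' @param path file path.
#' @export
write_protein_matrix <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_protein_matrix
#' @export
read_protein_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  check_protein_matrix(m)
  m
}

#' Write a data.frame as CSV with a fixed column order
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize normalization parameters
#' @param params `normalization_params` data.frame (protein, min, max, median).
#' @param path file path.
#' @export
write_normalization_params <- function(params, path) {
  write_table_csv(params, path)
}

#' @rdname write_normalization_params
#' @export
read_normalization_params <- function(path) {
  out <- read_table_csv(path)
  structure(out, class = c("normalization_params", "data.frame"))
}

#' Read a reference edge list (protein_a, protein_b, score)
#'
#' Accepts any 3+ column delimited table whose first three columns are the
#' two proteins and the confidence score.
#'
#' @param path file path (CSV or TSV, inferred from the extension).
#' @export
read_edge_list <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("a", "b", "score")
  df
}
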