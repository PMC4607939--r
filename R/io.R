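#' Read and write classic tab-delimited OTU tables
#'
#' The classic format has a header line starting with `#OTU ID`, one column
#' per sample, and optionally a terminal `taxonomy` column holding
#' semicolon-separated lineages. `write_otu_table()` / `read_otu_table()`
#' round-trip a [community_table()] bit-identically for integer counts.
#'
#' @param table a `community_table`.
#' @param path file path.
#' @return `read_otu_table()` returns a `community_table`;
#'   `write_otu_table()` returns `path` invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  df <- as.data.frame(table$counts, check.names = FALSE)
  df <- cbind(`#OTU ID` = table$otu_ids, df)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  assert_that(names(df)[1] == "#OTU ID",
              "not a classic OTU table (first column must be '#OTU ID')")
  otus <- as.character(df[[1]])
  tax <- NULL
  has_tax <- tolower(names(df)[ncol(df)]) == "taxonomy"
  if (has_tax) {
    tax <- stats::setNames(as.character(df[[ncol(df)]]), otus)
    df <- df[, -ncol(df), drop = FALSE]
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- if (all(m == round(m))) "integer" else "double"
  rownames(m) <- otus
  community_table(m, taxonomy = tax)
}

#' Write/read a square distance matrix as TSV
#'
#' Serializes a symmetric distance matrix with a header row and a leading
#' ID column, the layout common ecology tools exchange.
#'
#' @param D symmetric numeric matrix with matching row/col names.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  D <- validate_distance_matrix(D)
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_distance_matrix(m)
}

#' Validate a distance matrix
#'
#' Checks squareness, symmetry (to 1e-12 relative), zero diagonal and
#' nonnegativity, and returns the matrix with symmetrized rounding noise
#' removed.
#'
#' @param D numeric matrix.
#' @return the validated matrix.
#' @export
validate_distance_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  assert_that(is.matrix(D) && nrow(D) == ncol(D), "distance matrix not square")
  assert_that(!is.null(rownames(D)), "distance matrix needs sample IDs")
  assert_that(identical(rownames(D), colnames(D)),
              "row/column sample IDs disagree")
  assert_that(max(abs(D - t(D))) <= 1e-12 * max(1, max(abs(D))),
              "distance matrix not symmetric")
  assert_that(all(abs(diag(D)) <= 1e-12), "distance matrix diagonal not zero")
  assert_that(all(D >= -1e-12), "negative distances")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}
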