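# Labelled delimited-matrix I/O. Dialect: comma-separated, '.' decimal,
# header row and first column carry the species identifiers; scientific
# notation accepted.

#' Write a labelled numeric matrix as CSV
#'
#' @param M numeric matrix.
#' @param path output file.
#' @param labels row/column identifiers; defaults to the matrix dimnames.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(M, path, labels = NULL) {
  M <- as.matrix(M)
  if (is.null(labels)) labels <- rownames(M)
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(M)))
  df <- data.frame(id = labels, M, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", if (ncol(M) == length(labels) &&
                              (is.null(colnames(M)) || all(colnames(M) == labels)))
    labels else colnames(M))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled numeric matrix from CSV
#'
#' Expects the dialect written by [write_matrix()]: a header row of labels and
#' a first column of labels. When `labels` is supplied, the matrix is
#' reordered to that label order (a note is emitted if reordering was needed)
#' and any mismatch in the label sets is an error listing the symmetric
#' difference.
#'
#' @param path input file.
#' @param labels optional canonical label order to enforce.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, labels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2] + 1L, path))
  }
  rownames(M) <- ids
  if (!is.null(labels)) {
    missing_ids <- setdiff(labels, ids)
    extra_ids <- setdiff(ids, labels)
    if (length(missing_ids) > 0 || length(extra_ids) > 0) {
      stop(sprintf("label mismatch in %s: missing {%s}, unexpected {%s}",
                   path, paste(missing_ids, collapse = ", "),
                   paste(extra_ids, collapse = ", ")))
    }
    if (!identical(ids, as.character(labels))) {
      message("reordering matrix rows/columns to canonical species order")
      M <- M[labels, , drop = FALSE]
      if (ncol(M) == length(labels) && all(colnames(M) %in% labels)) {
        M <- M[, labels, drop = FALSE]
      }
    }
  }
  M
}
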