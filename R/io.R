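#' Read and write the pipeline's plain-text tables
#'
#' Counts travel as TSV with miRNA rows and sample columns, an empty cell
#' meaning missing (absent from the sequencing output, distinct from an
#' observed zero); sample sheets, well tables and cohort tables are plain
#' TSV/CSV with a header row.
#'
#' @param counts miRNA x sample matrix (`NA` = missing).
#' @param path file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(mirna_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = "", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname pipeline_io
#' @param table a data frame (sample sheet, wells, cohort, report table).
#' @param sep field separator (`"\t"` for .tsv, `","` for .csv).
#' @export
write_table <- function(table, path, sep = "\t") {
  utils::write.table(table, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_table <- function(path, sep = "\t") {
  utils::read.delim(path, sep = sep, check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
}
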