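# Tabular readers/writers. All tables are TSV with a single header line so
# every output round-trips through its own reader.

#' Write / read an expression matrix TSV (genes as rows, sample-id header)
#'
#' @param mat Matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a plain data.frame TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Read an hourly-temperature or daily-min/max CSV
#'
#' Accepts `timestamp,temp_c` (hourly) or `date,tmin,tmax` (daily) columns.
#'
#' @param path CSV path.
#' @return data.frame in the same shape as the file.
#' @export
read_temperatures_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("timestamp", "temp_c") %in% names(df))) {
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  } else if (all(c("date", "tmin", "tmax") %in% names(df))) {
    df$date <- as.Date(df$date)
  } else {
    stop("temperature CSV needs timestamp/temp_c or date/tmin/tmax columns")
  }
  df
}
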