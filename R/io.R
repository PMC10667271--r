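# File contracts: feature x sample matrices as TSV (header = sample IDs,
# first column = feature ID, "." decimal, UTF-8); sample sheet and long
# tables as CSV.

#' Write / read a feature x sample matrix as TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output TSV path.
#' @param id_col Name of the feature-ID column header.
#' @return `write_matrix_tsv`: the path, invisibly. `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read the sample sheet
#' @param samples Sample sheet data frame.
#' @param path CSV path.
#' @export
write_sample_sheet <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue", "state", "replicate")
  if (!all(req %in% names(s)))
    stop("sample sheet needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  s
}
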