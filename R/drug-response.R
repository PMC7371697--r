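#' Construct a drug-response matrix
#'
#' Drugs x cell lines sensitivity values with a declared orientation. Panels
#' mix two conventions: GI50-like (growth-inhibitory concentration; lower =
#' more sensitive) and sAUC-like (1 - standardized area under the
#' dose-response curve; higher = more sensitive). On construction the values
#' are brought to a single canonical form in which HIGHER always means MORE
#' sensitive (GI50-like inputs are negated), so every downstream direction
#' label (sensitivity vs resistance marker) has one meaning.
#'
#' @param values numeric matrix, drugs x cell lines, NA for unmeasured pairs.
#' @param higher_is_sensitive TRUE for sAUC-like input, FALSE for GI50-like.
#' @return a `drug_response_matrix` (classed matrix, canonical orientation).
#' @export
drug_response_matrix <- function(values, higher_is_sensitive = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("drug_response_matrix: drug and cell line ids are required")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) stop("drug_response_matrix: duplicate drug ids: ",
                        paste(dup, collapse = ", "))
  if (!higher_is_sensitive) values <- -values
  structure(values, input_orientation = if (higher_is_sensitive)
    "higher_is_sensitive" else "lower_is_sensitive",
    class = c("drug_response_matrix", class(values)))
}

#' @export
print.drug_response_matrix <- function(x, ...) {
  cat(sprintf("<drug_response_matrix> %d drugs x %d cell lines (canonical: higher = sensitive; input %s)\n",
              nrow(x), ncol(x), attr(x, "input_orientation")))
  invisible(x)
}

#' Read / write drug-response TSV
#'
#' First column the drug id; remaining columns cell lines; "NA" for missing.
#'
#' @param path file path.
#' @param higher_is_sensitive orientation of the values ON DISK.
#' @return a `drug_response_matrix` (reader) / `path` invisibly (writer).
#' @export
read_drug_tsv <- function(path, higher_is_sensitive = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  drug_response_matrix(m, higher_is_sensitive = higher_is_sensitive)
}

#' @rdname read_drug_tsv
#' @param x a `drug_response_matrix` (written in canonical orientation).
#' @export
write_drug_tsv <- function(x, path) {
  df <- data.frame(drug = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
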