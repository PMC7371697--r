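#' Construct an intensity matrix
#'
#' Features x cell lines matrix of log10-scale intensities (arbitrary units)
#' with explicit missing values. Internal storage is always log10; conversion
#' to the linear scale happens only at operation boundaries (summation,
#' fold-changes). A kind tag distinguishes protein, p-site and aggregated
#' phosphoprotein matrices and is fixed after construction.
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (cell line ids); NA marks a missing (undetected) entry.
#' @param kind one of "protein", "psite", "phosphoprotein".
#' @return an `intensity_matrix` (a classed numeric matrix).
#' @export
intensity_matrix <- function(values, kind = c("protein", "psite", "phosphoprotein")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("intensity_matrix: feature and cell line ids are required")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f)) stop("intensity_matrix: duplicate feature ids: ",
                          paste(dup_f, collapse = ", "))
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c)) stop("intensity_matrix: duplicate cell line ids: ",
                          paste(dup_c, collapse = ", "))
  if (any(is.infinite(values))) stop("intensity_matrix: values must be finite or NA")
  structure(values, kind = kind, class = c("intensity_matrix", class(values)))
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix[%s]> %d features x %d cell lines, %.1f%% missing\n",
              attr(x, "kind"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Matrix kind accessor
#' @param x an `intensity_matrix`.
#' @return "protein", "psite" or "phosphoprotein".
#' @export
matrix_kind <- function(x) attr(x, "kind")

#' Read / write intensity matrices as TSV
#'
#' UTF-8 tab-separated, first column the feature id, "NA" for missing.
#' Duplicate feature or cell line ids are rejected with the offenders listed.
#'
#' @param path file path.
#' @param kind matrix kind tag, see [intensity_matrix()].
#' @return an `intensity_matrix` (reader) / `path` invisibly (writer).
#' @export
read_intensity_tsv <- function(path, kind = "protein") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("read_intensity_tsv: duplicate feature ids: ",
                        paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  intensity_matrix(m, kind = kind)
}

#' @rdname read_intensity_tsv
#' @param x an `intensity_matrix`.
#' @param id_col name of the feature-id column in the output.
#' @export
write_intensity_tsv <- function(x, path, id_col = "feature") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write GMT set collections
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' The returned collection is a named list of character member vectors with a
#' `description` attribute.
#'
#' @param path file path.
#' @return named list of member vectors (reader) / `path` invisibly (writer).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) stop("read_gmt: duplicate set names: ", paste(dup, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of member vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description") %||%
      rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' P-site annotation table
#'
#' One row per p-site: id (grammar `GENE_p<RES><POS>`, e.g. MAPK1_pY187),
#' protein group, phosphorylated residue (S/T/Y), 1-based position and a
#' regulatory class (activating / inhibitory / unknown) used by the kinase
#' activity channels and the regulatory-site drug screen.
#'
#' @param psite,protein,residue,position,reg_class parallel vectors.
#' @return validated data.frame.
#' @export
psite_annotation <- function(psite, protein, residue, position,
                             reg_class = "unknown") {
  df <- data.frame(psite = as.character(psite), protein = as.character(protein),
                   residue = as.character(residue),
                   position = as.integer(position),
                   reg_class = rep_len(as.character(reg_class), length(psite)),
                   stringsAsFactors = FALSE)
  if (!all(df$residue %in% c("S", "T", "Y")))
    stop("psite_annotation: residue must be one of S, T, Y")
  if (any(df$position < 1L)) stop("psite_annotation: position must be >= 1")
  if (!all(df$reg_class %in% c("activating", "inhibitory", "unknown")))
    stop("psite_annotation: reg_class must be activating/inhibitory/unknown")
  dup <- unique(df$psite[duplicated(df$psite)])
  if (length(dup)) stop("psite_annotation: duplicate p-site ids: ",
                        paste(dup, collapse = ", "))
  df
}

#' Parse the protein group out of p-site ids
#'
#' Convenience for the id grammar `GENE_p<RES><POS>`; everything before the
#' final `_p<RES><POS>` suffix is the protein group.
#'
#' @param ids character vector of p-site ids.
#' @return character vector of protein group ids.
#' @export
psite_protein <- function(ids) {
  sub("_p[STY][0-9]+$", "", ids)
}

#' Aggregate p-sites to phosphoprotein intensities
#'
#' Per protein group and cell line, the phosphoprotein intensity is the log10
#' of the sum of linear-scale intensities of the observed member sites;
#' missing if and only if all member sites are missing in that cell line.
#' Missing members are skipped (never treated as zero-on-log-scale).
#'
#' @param psites an `intensity_matrix` of kind "psite".
#' @param annotation data.frame from [psite_annotation()] mapping every p-site
#'   to exactly one protein group. Sites present in the matrix but not in the
#'   annotation are an error listing the offenders.
#' @return an `intensity_matrix` of kind "phosphoprotein".
#' @export
aggregate_phosphoprotein <- function(psites, annotation) {
  stopifnot(inherits(psites, "intensity_matrix"))
  map <- stats::setNames(annotation$protein, annotation$psite)
  missing_ids <- setdiff(rownames(psites), names(map))
  if (length(missing_ids))
    stop("aggregate_phosphoprotein: unmapped p-sites: ",
         paste(missing_ids, collapse = ", "))
  grp <- map[rownames(psites)]
  lin <- 10^unclass(psites)
  lin[is.na(lin)] <- 0
  summed <- rowsum(lin, group = grp)
  n_obs <- rowsum((!is.na(unclass(psites))) * 1, group = grp)
  out <- log10(summed)
  out[n_obs == 0] <- NA_real_
  intensity_matrix(out, kind = "phosphoprotein")
}

#' Fold-change between intensity extremes
#'
#' `mode = "fold"` takes two log10 intensities and returns 10^(high - low),
#' the convention used when quoting a marker's dynamic range across a panel
#' ("fold-change of 151 from the lowest"). `mode = "ratio"` divides two
#' linear-scale inputs (e.g. ED50 concentrations). Optional rounding is
#' half-away-from-zero to the nearest integer.
#'
#' @param low,high scalars; log10 intensities for "fold", linear values for
#'   "ratio" (then `low` is the denominator).
#' @param mode "fold" or "ratio".
#' @param round_to_int report the nearest integer?
#' @return positive real (or integer-valued when rounded).
#' @export
fold_change <- function(low, high, mode = c("fold", "ratio"),
                        round_to_int = FALSE) {
  mode <- match.arg(mode)
  if (!is.finite(low) || !is.finite(high)) stop("fold_change: non-finite input")
  if (mode == "fold") {
    if (high < low) stop("fold_change: high must be >= low for mode = 'fold'")
    fc <- 10^(high - low)
  } else {
    if (low == 0) stop("fold_change: zero denominator")
    fc <- high / low
  }
  if (round_to_int) round_half_away(fc) else fc
}

#' Median-center cell line columns
#'
#' Subtracts the per-cell-line median over observed entries so every column
#' has median 0; the missingness pattern is unchanged. This is the package's
#' documented normalization stand-in.
#'
#' @param x an `intensity_matrix`.
#' @return an `intensity_matrix` of the same kind.
#' @export
median_center <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  meds <- apply(x, 2L, stats::median, na.rm = TRUE)
  empty <- !is.finite(meds)
  if (any(empty)) stop("median_center: no observed values in column(s): ",
                       paste(colnames(x)[empty], collapse = ", "))
  intensity_matrix(sweep(unclass(x), 2L, meds, "-"), kind = matrix_kind(x))
}

#' Pairwise-complete filter
#'
#' Indices observed in both of two equal-length series, or a rejection when
#' fewer than `min_n` (default 7, the panel-wide association screen rule)
#' complete pairs remain.
#'
#' @param x,y numeric vectors over the same cell lines.
#' @param min_n minimum number of complete pairs.
#' @return list with `indices` (integer vector), `n`, and `rejected` flag;
#'   `indices` is empty when rejected.
#' @export
pairwise_complete_filter <- function(x, y, min_n = 7L) {
  if (length(x) != length(y)) stop("pairwise_complete_filter: length mismatch")
  idx <- which(!is.na(x) & !is.na(y))
  if (length(idx) < min_n) {
    list(indices = integer(0), n = length(idx), rejected = TRUE)
  } else {
    list(indices = idx, n = length(idx), rejected = FALSE)
  }
}

#' Read / write p-site annotation TSV
#' @param path file path.
#' @return data.frame (reader) / `path` invisibly (writer).
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  psite_annotation(df$psite, df$protein, df$residue, df$position, df$reg_class)
}

#' @rdname read_annotation_tsv
#' @param annotation data.frame from [psite_annotation()].
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
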