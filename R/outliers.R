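#' Call single-cell-line outlier features
#'
#' Detects proteins/p-sites with substantially higher abundance in one cell
#' line than in all others. For a feature observed in at least `min_observed`
#' cell lines, cell line s is called when
#' x_fs - median(x_f over the other observed lines) >= log10(threshold_fold);
#' the leave-one-out median is robust to the outlier itself. Features
#' observed in exactly one cell line are additionally called
#' `detection_only` when the single value exceeds the matrix's 25th intensity
#' percentile (to avoid calling noise-level single detections).
#'
#' @param mat an [intensity_matrix()] (log10 scale).
#' @param threshold_fold linear fold-change threshold (> 1; default 5, below
#'   the 7-10-fold regime of typical strong cases so those are always
#'   called).
#' @param min_observed minimum observed cell lines for threshold calls
#'   (default 10).
#' @return data.frame with columns feature, cell_line, excess (log10 units
#'   above the leave-one-out median; NA for detection-only calls),
#'   detection_only, n_observed.
#' @export
call_outliers <- function(mat, threshold_fold = 5, min_observed = 10L) {
  if (threshold_fold <= 1) stop("call_outliers: threshold_fold must be > 1")
  x <- unclass(mat)
  log_thr <- log10(threshold_fold)
  floor_q <- stats::quantile(x, 0.25, na.rm = TRUE)
  calls <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    obs <- which(!is.na(v))
    if (length(obs) == 1L) {
      if (v[obs] > floor_q) {
        calls[[i]] <- data.frame(feature = rownames(x)[i],
                                 cell_line = colnames(x)[obs],
                                 excess = NA_real_, detection_only = TRUE,
                                 n_observed = 1L, stringsAsFactors = FALSE)
      }
      next
    }
    if (length(obs) < min_observed) next
    vo <- v[obs]
    # leave-one-out medians for all observed lines at once
    med_all <- stats::median(vo)
    excess <- vapply(seq_along(obs), function(j)
      vo[j] - stats::median(vo[-j]), 0)
    hit <- which(excess >= log_thr)
    if (length(hit)) {
      calls[[i]] <- data.frame(feature = rownames(x)[i],
                               cell_line = colnames(x)[obs[hit]],
                               excess = unname(excess[hit]),
                               detection_only = FALSE,
                               n_observed = length(obs),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(feature = character(0), cell_line = character(0),
                      excess = numeric(0), detection_only = logical(0),
                      n_observed = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster the outlier incidence matrix
#'
#' Builds the binary feature x cell-line incidence matrix of outlier calls
#' and clusters both axes by average linkage on Jaccard distance. Features
#' falling in the same cluster (cut at Jaccard distance `group_cut`) and
#' sharing at least one outlier cell line are reported as candidate
#' co-regulated sets — strong phosphorylation events from the same pathway
#' context in the same cell line.
#'
#' @param calls data.frame from [call_outliers()].
#' @param group_cut Jaccard-distance cut defining co-outlier groups
#'   (default 0.5).
#' @return list with `incidence`, `feature_order`, `cell_line_order`,
#'   `feature_hclust`, `cell_line_hclust`, `co_outlier_groups` (list of
#'   feature vectors).
#' @export
cluster_outlier_matrix <- function(calls, group_cut = 0.5) {
  feats <- unique(calls$feature)
  if (length(feats) < 2L) stop("cluster_outlier_matrix: need >= 2 called features")
  lines <- unique(calls$cell_line)
  inc <- matrix(0L, length(feats), length(lines),
                dimnames = list(feats, lines))
  inc[cbind(match(calls$feature, feats), match(calls$cell_line, lines))] <- 1L
  jacc_dist <- function(m) {
    inter <- tcrossprod(m)
    sz <- rowSums(m)
    uni <- outer(sz, sz, "+") - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 1
    stats::as.dist(d)
  }
  hf <- stats::hclust(jacc_dist(inc), method = "average")
  hc <- if (length(lines) >= 2L) stats::hclust(jacc_dist(t(inc)), method = "average")
        else NULL
  cl <- stats::cutree(hf, h = group_cut)
  groups <- split(feats, cl)
  groups <- Filter(function(g) {
    if (length(g) < 2L) return(FALSE)
    shared <- colSums(inc[g, , drop = FALSE]) == length(g)
    any(shared)
  }, groups)
  list(incidence = inc,
       feature_order = feats[hf$order],
       cell_line_order = if (is.null(hc)) lines else lines[hc$order],
       feature_hclust = hf, cell_line_hclust = hc,
       co_outlier_groups = unname(groups))
}
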