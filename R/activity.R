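#' @title Pathway and kinase activity landscapes
#' @description Relative-activity scoring of pathways and kinases across a
#'   cell line panel, per-cell-line waterfalls, and smoothed 2D activity
#'   landscapes. Raw activity is a mean member z-score (a KSEA-style
#'   statistic) behind a substitution-friendly interface; relative activity is
#'   the per-entity min-max rescaling to [0, 1] across cell lines ("minimal
#'   and maximal relative activity").
#' @name phosmarker-activity
NULL

activity_matrix <- function(raw, provenance, flat) {
  rel <- raw
  for (i in seq_len(nrow(raw))) {
    v <- raw[i, ]
    if (flat[i]) { rel[i, ] <- NA_real_; next }
    rng <- range(v, na.rm = TRUE)
    rel[i, ] <- (v - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(raw = raw, relative = rel, provenance = provenance,
                 flat = flat), class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d entities x %d cell lines (%d flat)\n",
              nrow(x$raw), ncol(x$raw), sum(x$flat)))
  invisible(x)
}

# mean of member z-score rows, NA-aware; returns NULL if no members resolve
member_mean_z <- function(z, members) {
  members <- intersect(members, rownames(z))
  if (!length(members)) return(NULL)
  colMeans(z[members, , drop = FALSE], na.rm = TRUE)
}

#' Pathway relative activity
#'
#' Per feature, z-scores across cell lines (observed entries only); the raw
#' pathway score of a cell line is the mean z over member proteins and over
#' p-sites located on member proteins; relative activity is the min-max
#' rescaling per pathway. Pathways with fewer than `min_members` resolvable
#' members are dropped with a warning; pathways whose members are constant
#' across the panel are flagged FLAT and carry no relative scores.
#'
#' @param protein an [intensity_matrix()] of protein abundances.
#' @param psite optional [intensity_matrix()] of p-site abundances; sites are
#'   assigned to proteins via `annotation` or, if NULL, the
#'   `GENE_p<RES><POS>` id grammar.
#' @param pathways named list of member (protein id) vectors.
#' @param annotation optional [psite_annotation()].
#' @param min_members minimum resolvable members (default 3).
#' @return an `activity_matrix` with elements `raw`, `relative`,
#'   `provenance`, `flat`.
#' @export
pathway_activity <- function(protein, psite = NULL, pathways,
                             annotation = NULL, min_members = 3L) {
  if (!length(pathways)) stop("pathway_activity: empty pathway collection")
  if (ncol(protein) < 2L) stop("pathway_activity: need >= 2 cell lines")
  zp <- row_zscore(unclass(protein))
  zs <- NULL
  site_host <- NULL
  if (!is.null(psite)) {
    zs <- row_zscore(unclass(psite))
    site_host <- if (!is.null(annotation))
      stats::setNames(annotation$protein, annotation$psite)[rownames(psite)]
    else psite_protein(rownames(psite))
  }
  raw <- matrix(NA_real_, length(pathways), ncol(protein),
                dimnames = list(names(pathways), colnames(protein)))
  prov <- character(length(pathways))
  keep <- logical(length(pathways))
  for (i in seq_along(pathways)) {
    members <- pathways[[i]]
    rows <- zp[intersect(members, rownames(zp)), , drop = FALSE]
    chan <- if (nrow(rows)) "protein" else character(0)
    if (!is.null(zs)) {
      site_rows <- zs[which(site_host %in% members), , drop = FALSE]
      if (nrow(site_rows)) {
        rows <- rbind(rows, site_rows)
        chan <- c(chan, "psite")
      }
    }
    n_resolved <- length(intersect(members, rownames(zp))) +
      if (is.null(zs)) 0L else length(unique(site_host[site_host %in% members]))
    if (n_resolved < min_members) next
    keep[i] <- TRUE
    raw[i, ] <- colMeans(rows, na.rm = TRUE)
    prov[i] <- paste(chan, collapse = "+")
  }
  if (!all(keep))
    warning("pathway_activity: dropped pathways with < ", min_members,
            " resolvable members: ",
            paste(names(pathways)[!keep], collapse = ", "))
  if (!any(keep)) stop("pathway_activity: no pathway has enough members")
  raw <- raw[keep, , drop = FALSE]
  flat <- apply(raw, 1L, is_flat_profile)
  activity_matrix(raw, stats::setNames(prov[keep], rownames(raw)), flat)
}

is_flat_profile <- function(v) {
  v <- v[is.finite(v)]
  length(v) == 0L || diff(range(v)) == 0
}

#' Kinase relative activity
#'
#' Integrates three evidence channels per kinase and cell line: (1) z-score
#' of the kinase's protein abundance, (2) mean z of p-sites on the kinase
#' itself, (3) mean z of its substrate p-sites, with substrate sites
#' annotated as inhibitory entering with negated z. Channels are combined as
#' the unweighted mean of those available; kinases with no channel are
#' dropped with a warning.
#'
#' @param protein,psite [intensity_matrix()]s.
#' @param kinase_substrates named list kinase -> substrate p-site ids.
#' @param annotation [psite_annotation()]; used to locate sites on the kinase
#'   and to flag inhibitory substrate sites.
#' @return an `activity_matrix`; `provenance` records the channels used.
#' @export
kinase_activity <- function(protein, psite, kinase_substrates, annotation) {
  if (!length(kinase_substrates)) stop("kinase_activity: empty kinase map")
  zp <- row_zscore(unclass(protein))
  zs <- row_zscore(unclass(psite))
  site_host <- stats::setNames(annotation$protein, annotation$psite)
  site_class <- stats::setNames(annotation$reg_class, annotation$psite)
  # inhibitory sites argue for LOW activity of their kinase when high
  zs_signed <- zs
  inh <- rownames(zs)[site_class[rownames(zs)] %in% "inhibitory"]
  zs_signed[inh, ] <- -zs_signed[inh, , drop = FALSE]

  kinases <- names(kinase_substrates)
  raw <- matrix(NA_real_, length(kinases), ncol(protein),
                dimnames = list(kinases, colnames(protein)))
  prov <- character(length(kinases))
  keep <- logical(length(kinases))
  for (i in seq_along(kinases)) {
    k <- kinases[i]
    channels <- list()
    if (k %in% rownames(zp)) channels$abundance <- zp[k, ]
    own <- names(site_host)[site_host == k]
    own_z <- member_mean_z(zs, own)
    if (!is.null(own_z)) channels$own_sites <- own_z
    sub_z <- member_mean_z(zs_signed, kinase_substrates[[k]])
    if (!is.null(sub_z)) channels$substrates <- sub_z
    if (!length(channels)) next
    keep[i] <- TRUE
    raw[i, ] <- colMeans(do.call(rbind, channels), na.rm = TRUE)
    prov[i] <- paste(names(channels), collapse = "+")
  }
  if (!all(keep))
    warning("kinase_activity: dropped kinases with no evidence channel: ",
            paste(kinases[!keep], collapse = ", "))
  if (!any(keep)) stop("kinase_activity: no kinase has an evidence channel")
  raw <- raw[keep, , drop = FALSE]
  flat <- apply(raw, 1L, is_flat_profile)
  activity_matrix(raw, stats::setNames(prov[keep], rownames(raw)), flat)
}

#' Waterfall of relative activities in one cell line
#'
#' Entities sorted by descending relative activity, ties broken
#' lexicographically by entity id. Flat entities are omitted.
#'
#' @param activity an `activity_matrix`.
#' @param cell_line a cell line id present in the matrix.
#' @return data.frame with columns entity, relative.
#' @export
waterfall <- function(activity, cell_line) {
  if (!cell_line %in% colnames(activity$relative))
    stop("waterfall: unknown cell line: ", cell_line)
  v <- activity$relative[!activity$flat, cell_line]
  o <- order(-v, names(v))
  data.frame(entity = names(v)[o], relative = unname(v[o]),
             stringsAsFactors = FALSE)
}

#' Build a smoothed activity landscape
#'
#' Cell lines are embedded in 2D by the first two principal components of the
#' entity x cell-line relative-activity matrix (deterministic sign
#' convention: the largest-magnitude loading of each component is made
#' positive). Each entity's height field is the Nadaraya-Watson
#' Gaussian-kernel smoothing of its relative scores over a regular grid,
#' clipped to [0, 1]; mountains mark groups of cell lines with high relative
#' activity of that entity.
#'
#' @param activity an `activity_matrix`.
#' @param grid points per axis (default 25).
#' @param bandwidth Gaussian kernel bandwidth in embedding units; default
#'   half the median inter-cell-line distance.
#' @param seed kept for interface stability; the construction is
#'   deterministic.
#' @return list with `coordinates` (cell lines x 2), `grid_x`, `grid_y`,
#'   `heights` (named list of grid matrices), `bandwidth`.
#' @export
build_landscape <- function(activity, grid = 25L, bandwidth = NULL, seed = 1L) {
  rel <- activity$relative[!activity$flat, , drop = FALSE]
  if (ncol(rel) < 3L) stop("build_landscape: need >= 3 cell lines")
  rel0 <- rel
  rel0[is.na(rel0)] <- 0.5
  pc <- stats::prcomp(t(rel0), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) coords <- cbind(coords, 0)
  for (j in 1:2) {
    if (max(abs(coords[, j])) == 0) next
    load <- pc$rotation[, min(j, ncol(pc$rotation))]
    if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- c("dim1", "dim2")
  if (is.null(bandwidth)) {
    d <- stats::dist(coords)
    bandwidth <- max(stats::median(d) / 2, 1e-8)
  }
  pad <- function(r) r + c(-1, 1) * max(0.05 * diff(r), 1e-8)
  gx <- seq(pad(range(coords[, 1]))[1], pad(range(coords[, 1]))[2], length.out = grid)
  gy <- seq(pad(range(coords[, 2]))[1], pad(range(coords[, 2]))[2], length.out = grid)
  gp <- as.matrix(expand.grid(gx, gy))
  d2 <- outer(rowSums(gp^2), rowSums(coords^2), "+") - 2 * gp %*% t(coords)
  w <- exp(-pmax(d2, 0) / (2 * bandwidth^2))
  heights <- lapply(rownames(rel), function(e) {
    v <- rel[e, ]
    ok <- !is.na(v)
    h <- (w[, ok, drop = FALSE] %*% v[ok]) / rowSums(w[, ok, drop = FALSE])
    matrix(pmin(pmax(h, 0), 1), grid, grid)
  })
  names(heights) <- rownames(rel)
  list(coordinates = coords, grid_x = gx, grid_y = gy, heights = heights,
       bandwidth = bandwidth)
}
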