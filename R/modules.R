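#' @title Correlation-network modules and guilt-by-association
#' @description Weighted correlation-network analysis of the concatenated
#'   protein + p-site matrix: soft-power adjacency, topological overlap,
#'   average-linkage clustering with a fixed-height cut, module eigenfeatures,
#'   three-axis (functional set / module / phenotype) association, and
#'   guilt-by-association annotation transfer.
#' @name phosmarker-modules
NULL

#' Topological overlap matrix
#'
#' Unsigned soft-power adjacency a_ij = |cor(x_i, x_j)|^beta over
#' pairwise-complete entries, and
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' TOM_ii = 1.
#'
#' @param mat features x cell lines matrix.
#' @param beta soft power (>= 1).
#' @return list with `adjacency` and `tom` (both features x features).
#' @export
tom_matrix <- function(mat, beta = 6) {
  if (beta < 1) stop("tom_matrix: beta must be >= 1")
  a <- abs(stats::cor(t(mat), use = "pairwise.complete.obs"))^beta
  a[is.na(a)] <- 0
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  list(adjacency = a, tom = tom)
}

#' Detect correlation-network modules
#'
#' Clusters features (proteins and p-sites concatenated by the caller) by the
#' similarity of their abundance profiles: average-linkage clustering of
#' 1 - TOM with a fixed-height cut; clusters below `min_size` are left
#' unassigned (label 0). The eigenfeature of a module is the first principal
#' component of the standardized member profiles, sign-oriented to correlate
#' positively with the module's mean profile and scaled to unit norm.
#'
#' @param mat features x cell lines matrix (an [intensity_matrix()] or plain
#'   matrix); features observed in fewer than half the cell lines are dropped
#'   with a warning, all-missing features are an error.
#' @param beta soft power of the unsigned adjacency (default 6, the
#'   conventional unsigned choice).
#' @param min_size minimum module size (default 10).
#' @param cut_height fixed dissimilarity cut on the 1 - TOM dendrogram
#'   (default 0.9). If `NULL`, the `cut_quantile` of the off-diagonal
#'   dissimilarities is used instead.
#' @param cut_quantile quantile used when `cut_height = NULL`.
#' @return list with `labels` (named integer; 0 = unassigned), `eigenfeatures`
#'   (cell lines x modules), `tom`, `merge_height`, `beta`, `min_size`.
#' @export
detect_modules <- function(mat, beta = 6, min_size = 10L, cut_height = 0.9,
                           cut_quantile = 0.25) {
  mat <- unclass(mat)
  if (ncol(mat) < 8L) stop("detect_modules: need >= 8 cell lines")
  all_na <- rowSums(!is.na(mat)) == 0L
  if (any(all_na)) stop("detect_modules: all-missing feature(s): ",
                        paste(rownames(mat)[all_na], collapse = ", "))
  frac_obs <- rowMeans(!is.na(mat))
  if (any(frac_obs < 0.5)) {
    warning("detect_modules: dropping ", sum(frac_obs < 0.5),
            " feature(s) observed in < 50% of cell lines")
    mat <- mat[frac_obs >= 0.5, , drop = FALSE]
  }
  tm <- tom_matrix(mat, beta = beta)
  diss <- 1 - tm$tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (is.null(cut_height))
    cut_height <- stats::quantile(diss[upper.tri(diss)], cut_quantile)
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep_cl <- as.integer(names(sizes)[sizes >= min_size])
  labels <- integer(nrow(mat))
  names(labels) <- rownames(mat)
  for (i in seq_along(keep_cl)) labels[cl == keep_cl[i]] <- i
  eig <- NULL
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods)) {
    eig <- sapply(mods, function(mid) {
      sub <- mat[labels == mid, , drop = FALSE]
      subz <- row_zscore(sub)
      subz[is.na(subz)] <- 0
      sv <- svd(subz, nu = 0L, nv = 1L)
      e <- sv$v[, 1L]
      mean_prof <- colMeans(subz)
      if (stats::cor(e, mean_prof) < 0) e <- -e
      e / sqrt(sum(e^2))
    })
    colnames(eig) <- paste0("M", mods)
    rownames(eig) <- colnames(mat)
  }
  list(labels = labels, eigenfeatures = eig, tom = tm$tom,
       cut_height = unname(cut_height), beta = beta, min_size = min_size)
}

# feature-level moderated t + BH over the analyzed universe, then enrichment
# of direction-consistent significant features within a group of features
group_phenotype_edge <- function(group_features, sig_up, sig_down, universe_n) {
  res <- list()
  for (dir in c("up_in_positive", "up_in_negative")) {
    sig <- if (dir == "up_in_positive") sig_up else sig_down
    ov <- length(intersect(group_features, sig))
    if (!length(sig) || !length(group_features)) next
    ht <- hypergeom_enrich(ov, length(sig), length(group_features), universe_n)
    res[[dir]] <- ht$p
  }
  res
}

#' Associate functional sets, modules and a binary phenotype
#'
#' Builds the three-axis association structure behind a hive plot:
#' set<->module edges by hypergeometric enrichment over the analyzed feature
#' universe; module<->phenotype and set<->phenotype edges from feature-level
#' moderated t-tests (BH q < `q_threshold` over the universe) whose
#' direction-consistent significant features are enriched in the module/set
#' (BH over all such tests). Edge direction is up-in-positive /
#' up-in-negative by the sign of the mean difference.
#'
#' @param partition result of [detect_modules()].
#' @param sets named list of feature sets (resolved against the analyzed
#'   universe).
#' @param phenotype named logical over cell lines (TRUE = positive class;
#'   both classes need >= 3 cell lines).
#' @param mat the features x cell lines matrix the partition was built from.
#' @param q_threshold BH q cutoff for edges (default 0.05).
#' @param level "member" (default) tests member features; "eigenfeature"
#'   tests module eigenfeatures directly with an ordinary t-test.
#' @return list with `edges` (data.frame: axis_a, node_a, axis_b, node_b, q,
#'   direction), `feature_tests` (the moderated-t table), `universe`.
#' @export
associate_axes <- function(partition, sets, phenotype, mat,
                           q_threshold = 0.05,
                           level = c("member", "eigenfeature")) {
  level <- match.arg(level)
  mat <- unclass(mat)
  phenotype <- phenotype[colnames(mat)]
  if (any(is.na(phenotype))) stop("associate_axes: phenotype missing for some cell lines")
  if (sum(phenotype) < 3L || sum(!phenotype) < 3L)
    stop("associate_axes: both phenotype classes need >= 3 cell lines")
  universe <- names(partition$labels)
  nU <- length(universe)
  sets <- lapply(sets, intersect, y = universe)
  mods <- sort(unique(partition$labels[partition$labels > 0]))
  edges <- data.frame(axis_a = character(0), node_a = character(0),
                      axis_b = character(0), node_b = character(0),
                      q = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  add_edges <- function(df, ps) {
    if (!nrow(ps)) return(df)
    ps$q <- bh_adjust(ps$p)
    rbind(df, ps[ps$q < q_threshold, setdiff(names(ps), "p")])
  }

  # axis 1 <-> axis 2: set enrichment in modules
  sm <- do.call(rbind, lapply(names(sets), function(sn) {
    do.call(rbind, lapply(mods, function(mid) {
      members <- universe[partition$labels == mid]
      ov <- length(intersect(sets[[sn]], members))
      ht <- hypergeom_enrich(ov, length(sets[[sn]]), length(members), nU)
      data.frame(axis_a = "set", node_a = sn, axis_b = "module",
                 node_b = paste0("M", mid), p = ht$p, direction = "none",
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(sm)) edges <- add_edges(edges, sm)

  # feature-level differential abundance (positive vs negative class)
  ft <- moderated_t_matrix(mat[universe, , drop = FALSE], phenotype)
  sig_up <- ft$feature[!is.na(ft$q) & ft$q < q_threshold & ft$effect > 0]
  sig_down <- ft$feature[!is.na(ft$q) & ft$q < q_threshold & ft$effect < 0]

  pheno_rows <- function(axis, node, features) {
    if (level == "eigenfeature" && axis == "module") {
      e <- partition$eigenfeatures[, node]
      tt <- moderated_t(e[phenotype], e[!phenotype])
      return(data.frame(axis_a = axis, node_a = node, axis_b = "phenotype",
                        node_b = "positive", p = tt$p,
                        direction = if (tt$effect > 0) "up_in_positive" else
                          "up_in_negative", stringsAsFactors = FALSE))
    }
    ps <- group_phenotype_edge(features, sig_up, sig_down, nU)
    if (!length(ps)) return(NULL)
    do.call(rbind, lapply(names(ps), function(dir) {
      data.frame(axis_a = axis, node_a = node, axis_b = "phenotype",
                 node_b = "positive", p = ps[[dir]], direction = dir,
                 stringsAsFactors = FALSE)
    }))
  }
  mp <- do.call(rbind, lapply(mods, function(mid)
    pheno_rows("module", paste0("M", mid), universe[partition$labels == mid])))
  sp <- do.call(rbind, lapply(names(sets), function(sn)
    pheno_rows("set", sn, sets[[sn]])))
  if (!is.null(mp)) edges <- add_edges(edges, mp)
  if (!is.null(sp)) edges <- add_edges(edges, sp)
  rownames(edges) <- NULL
  list(edges = edges, feature_tests = ft, universe = universe,
       sets = sets, labels = partition$labels, q_threshold = q_threshold)
}

#' Guilt-by-association annotation candidates
#'
#' For every significant (set, module) edge, emits module members that are
#' significant for the phenotype in the same direction as the module's
#' phenotype edge and are NOT already members of the set ("in databases-"):
#' candidate new functional annotations.
#'
#' @param assoc result of [associate_axes()].
#' @param sets the same set collection.
#' @return data.frame with columns feature, set, module, direction, q
#'   (feature-level q); zero rows when there is nothing to transfer.
#' @export
guilt_by_association <- function(assoc, sets) {
  ed <- assoc$edges
  sm <- ed[ed$axis_a == "set" & ed$axis_b == "module", , drop = FALSE]
  mp <- ed[ed$axis_a == "module" & ed$axis_b == "phenotype", , drop = FALSE]
  out <- data.frame(feature = character(0), set = character(0),
                    module = character(0), direction = character(0),
                    q = numeric(0), stringsAsFactors = FALSE)
  ft <- assoc$feature_tests
  for (i in seq_len(nrow(sm))) {
    mod <- sm$node_b[i]
    dirs <- mp$direction[mp$node_a == mod]
    if (!length(dirs)) next
    mid <- as.integer(sub("^M", "", mod))
    members <- assoc$universe[assoc$labels == mid]
    for (dir in dirs) {
      sig <- ft$feature[!is.na(ft$q) & ft$q < assoc$q_threshold &
                          (if (dir == "up_in_positive") ft$effect > 0 else ft$effect < 0)]
      cand <- setdiff(intersect(members, sig), sets[[sm$node_a[i]]])
      if (length(cand))
        out <- rbind(out, data.frame(
          feature = cand, set = sm$node_a[i], module = mod, direction = dir,
          q = ft$q[match(cand, ft$feature)], stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Functional-association recapitulation at two quantitative levels
#'
#' A database-annotated protein pair is "recapitulated" at a level (protein
#' or phosphoprotein) if the Pearson correlation of the two profiles over
#' pairwise-complete entries (>= `min_n`) is positive with BH q < `q_threshold`
#' within that level. Returns both recapitulated pair sets, the fraction of
#' phosphoprotein-recapitulated pairs that are also protein-recapitulated,
#' and per-pathway enrichment among recapitulated pairs.
#'
#' @param protein,phosphoprotein [intensity_matrix()]s sharing cell lines.
#' @param pairs data.frame with columns a, b (protein ids) and optionally
#'   pathway.
#' @param min_n pairwise-complete minimum (default 7).
#' @param q_threshold BH q cutoff (default 0.05).
#' @return list with `protein_pairs`, `phospho_pairs` (character pair keys),
#'   `overlap_fraction`, `tests` (per level data.frames), and
#'   `pathway_enrichment`.
#' @export
recapitulation_overlap <- function(protein, phosphoprotein, pairs,
                                   min_n = 7L, q_threshold = 0.05) {
  level_test <- function(mat) {
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs$a[i]; b <- pairs$b[i]
      if (!(a %in% rownames(mat)) || !(b %in% rownames(mat))) return(NULL)
      flt <- pairwise_complete_filter(mat[a, ], mat[b, ], min_n = min_n)
      if (flt$rejected) return(NULL)
      pt <- pearson_test(mat[a, flt$indices], mat[b, flt$indices])
      if (pt$undefined) return(NULL)
      data.frame(pair = paste(a, b, sep = "|"), i = i, r = pt$statistic,
                 p = pt$p, n = pt$n, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (!is.null(res) && nrow(res)) res$q <- bh_adjust(res$p)
    res
  }
  tp <- level_test(unclass(protein))
  tf <- level_test(unclass(phosphoprotein))
  if (is.null(tp) && is.null(tf))
    stop("recapitulation_overlap: no testable pairs at either level")
  recap <- function(tt) if (is.null(tt)) character(0) else
    tt$pair[tt$r > 0 & tt$q < q_threshold]
  rp <- recap(tp); rf <- recap(tf)
  overlap <- if (length(rf)) length(intersect(rf, rp)) / length(rf) else NA_real_
  enrich <- NULL
  if (!is.null(pairs$pathway) && !is.null(tf) && nrow(tf)) {
    tested <- tf$pair
    enrich <- do.call(rbind, lapply(unique(pairs$pathway), function(pw) {
      pw_pairs <- paste(pairs$a, pairs$b, sep = "|")[pairs$pathway == pw]
      pw_tested <- intersect(pw_pairs, tested)
      if (!length(pw_tested)) return(NULL)
      ht <- hypergeom_enrich(length(intersect(pw_tested, rf)),
                             length(pw_tested), length(rf), length(tested))
      data.frame(pathway = pw, overlap = ht$statistic, p = ht$p,
                 effect = ht$effect, stringsAsFactors = FALSE)
    }))
    if (!is.null(enrich) && nrow(enrich)) enrich$q <- bh_adjust(enrich$p)
  }
  list(protein_pairs = rp, phospho_pairs = rf, overlap_fraction = overlap,
       tests = list(protein = tp, phosphoprotein = tf),
       pathway_enrichment = enrich)
}
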