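#' @title Protein / p-site drug-association models
#' @description Correlation screening with the pairwise-complete rule,
#'   elastic-net marker frequency ranking, metabolic random-forest subset
#'   models, and the regulatory-p-site screen. All direction labels derive
#'   from the canonical drug-response orientation (higher = more sensitive).
#' @name phosmarker-drugmodels
NULL

#' Correlation screen of feature-drug associations
#'
#' Pearson test for every feature-drug pair with at least `min_n`
#' pairwise-complete observations over the shared cell lines; BH adjustment
#' within each drug; direction "sensitivity" when r > 0 under the canonical
#' orientation, "resistance" otherwise. Pairs failing the pairwise-complete
#' rule are absent from the output entirely.
#'
#' @param features an [intensity_matrix()].
#' @param drugs a [drug_response_matrix()].
#' @param min_n pairwise-complete minimum (default 7).
#' @return a MarkerTable data.frame: feature, drug, r, p, q, n, direction,
#'   method = "correlation".
#' @export
correlation_screen <- function(features, drugs, min_n = 7L) {
  shared <- intersect(colnames(features), colnames(drugs))
  if (!length(shared)) stop("correlation_screen: no shared cell lines")
  X <- unclass(features)[, shared, drop = FALSE]
  Y <- unclass(drugs)[, shared, drop = FALSE]
  res <- vector("list", nrow(Y))
  for (d in seq_len(nrow(Y))) {
    y <- Y[d, ]
    obs_y <- !is.na(y)
    n <- rowSums(!is.na(X[, obs_y, drop = FALSE]))
    ok <- which(n >= min_n)
    if (!length(ok)) next
    rows <- lapply(ok, function(f) {
      pt <- pearson_test(X[f, ], y)
      if (pt$undefined) return(NULL)
      data.frame(feature = rownames(X)[f], drug = rownames(Y)[d],
                 r = pt$statistic, p = pt$p, n = pt$n,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab) || !nrow(tab)) next
    tab$q <- bh_adjust(tab$p)
    res[[d]] <- tab
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("correlation_screen: no testable feature-drug pair")
  out$direction <- ifelse(out$r > 0, "sensitivity", "resistance")
  out$method <- "correlation"
  rownames(out) <- NULL
  out[, c("feature", "drug", "r", "p", "q", "n", "direction", "method")]
}

#' Elastic-net drug markers and frequency ranking
#'
#' Per drug, fits an elastic net (glmnet; penalty
#' lambda (alpha L1 + (1-alpha)/2 L2)) of the canonical sensitivity on the
#' feature matrix, with lambda chosen by cross-validation under the 1-SE
#' rule. No imputation: only cell lines with an observed response and only
#' features observed in all of those cell lines enter a drug's model. The
#' frequency of a feature is the number of drugs in which its coefficient is
#' nonzero with a given sign; the ranking is by descending frequency.
#'
#' @param features an [intensity_matrix()].
#' @param drugs a [drug_response_matrix()].
#' @param alpha elastic-net mixing (default 0.5).
#' @param cv_folds cross-validation folds (default 5).
#' @param seed RNG seed controlling fold assignment.
#' @param min_lines minimum usable cell lines per drug (default 20).
#' @return list with `coefficients` (per-drug named list of nonzero
#'   coefficients), `frequency` (data.frame: feature, sensitivity_count,
#'   resistance_count, total ranked descending), `skipped` drugs.
#' @export
enet_markers <- function(features, drugs, alpha = 0.5, cv_folds = 5L,
                         seed = 1L, min_lines = 20L) {
  shared <- intersect(colnames(features), colnames(drugs))
  X_all <- t(unclass(features)[, shared, drop = FALSE])
  Y <- unclass(drugs)[, shared, drop = FALSE]
  coefs <- list()
  skipped <- character(0)
  for (d in rownames(Y)) {
    y <- Y[d, ]
    rows <- which(!is.na(y))
    if (length(rows) < min_lines) { skipped <- c(skipped, d); next }
    Xd <- X_all[rows, , drop = FALSE]
    complete <- colSums(is.na(Xd)) == 0L
    Xd <- Xd[, complete, drop = FALSE]
    if (ncol(Xd) < 2L || stats::sd(y[rows]) == 0) { skipped <- c(skipped, d); next }
    set.seed(derive_seed(seed, match(d, rownames(Y))))
    foldid <- sample(rep_len(seq_len(cv_folds), length(rows)))
    cv <- glmnet::cv.glmnet(Xd, y[rows], alpha = alpha, foldid = foldid,
                            standardize = TRUE)
    cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1L, 1L]
    nz <- cf[cf != 0]
    coefs[[d]] <- nz
  }
  if (!length(coefs)) stop("enet_markers: no drug could be modeled")
  all_feats <- unique(unlist(lapply(coefs, names)))
  sens <- vapply(all_feats, function(f)
    sum(vapply(coefs, function(cf) isTRUE(cf[f] > 0), TRUE)), 0L)
  resi <- vapply(all_feats, function(f)
    sum(vapply(coefs, function(cf) isTRUE(cf[f] < 0), TRUE)), 0L)
  freq <- data.frame(feature = all_feats, sensitivity_count = sens,
                     resistance_count = resi, total = sens + resi,
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$total, -freq$sensitivity_count, freq$feature), ]
  rownames(freq) <- NULL
  list(coefficients = coefs, frequency = freq, skipped = skipped,
       alpha = alpha, cv_folds = cv_folds, seed = seed)
}

#' Enumerate feature subsets for the subset-model screen
#' @param panel character vector of panel feature ids.
#' @param sizes subset sizes (default 3:7).
#' @return list of character vectors, all subsets of the given sizes.
#' @export
enumerate_subsets <- function(panel, sizes = 3:7) {
  if (max(sizes) > length(panel))
    stop("enumerate_subsets: sizes exceed panel size")
  unlist(lapply(sizes, function(k)
    utils::combn(panel, k, simplify = FALSE)), recursive = FALSE)
}

#' Random-forest subset models of a metabolic panel
#'
#' Enumerates all subsets of `sizes` features from a small panel (e.g. the
#' 14 enzymes of a drug's metabolic pathway), fits a bagged regression
#' forest per subset, ranks subsets by the cross-validated Pearson r between
#' predicted and observed sensitivity, and reports the top `top_k` models per
#' size. Optionally evaluates those top models on a held-out cell-line set.
#'
#' @param features an [intensity_matrix()] restricted to the panel features.
#' @param drug_response named numeric vector of canonical sensitivities over
#'   cell lines (one drug).
#' @param sizes subset sizes (default 3:7).
#' @param cv_folds cross-validation folds (default 5).
#' @param n_trees trees per forest (default 500; reduce for screening).
#' @param top_k models reported per size (default 5).
#' @param holdout optional named numeric vector of sensitivities for
#'   held-out cell lines present in `features`.
#' @param seed RNG seed; the ranking is reproducible given the seed.
#' @return list with `models` (data.frame: subset, size, cv_r) ranked within
#'   size, `top` (top_k per size), and `holdout_r` for the top models when a
#'   holdout is supplied.
#' @export
rf_subset_models <- function(features, drug_response, sizes = 3:7,
                             cv_folds = 5L, n_trees = 500L, top_k = 5L,
                             holdout = NULL, seed = 1L) {
  panel <- rownames(features)
  if (max(sizes) > length(panel)) stop("rf_subset_models: sizes exceed panel")
  lines <- intersect(colnames(features), names(drug_response))
  lines <- lines[!is.na(drug_response[lines])]
  X <- t(unclass(features)[, lines, drop = FALSE])
  keep <- rowSums(is.na(X)) == 0L
  X <- X[keep, , drop = FALSE]
  y <- drug_response[rownames(X)]
  if (length(y) < 15L) stop("rf_subset_models: response available for < 15 usable cell lines")
  subsets <- enumerate_subsets(panel, sizes)
  set.seed(derive_seed(seed, 0L))
  foldid <- sample(rep_len(seq_len(cv_folds), length(y)))
  cv_r <- vapply(seq_along(subsets), function(si) {
    cols <- subsets[[si]]
    pred <- rep(NA_real_, length(y))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      fit <- bag_forest(X[tr, cols, drop = FALSE], y[tr], n_trees = n_trees,
                        seed = derive_seed(seed, si * 13L + f))
      pred[!tr] <- predict(fit, X[!tr, cols, drop = FALSE])
    }
    suppressWarnings(stats::cor(pred, y))
  }, 0)
  models <- data.frame(subset = vapply(subsets, paste, "", collapse = "+"),
                       size = vapply(subsets, length, 0L), cv_r = cv_r,
                       stringsAsFactors = FALSE)
  models <- models[order(models$size, -models$cv_r), ]
  rownames(models) <- NULL
  top <- do.call(rbind, lapply(split(models, models$size), utils::head, top_k))
  rownames(top) <- NULL
  holdout_r <- NULL
  if (!is.null(holdout)) {
    ho_lines <- intersect(colnames(features), names(holdout))
    ho_lines <- ho_lines[!is.na(holdout[ho_lines])]
    Xh <- t(unclass(features)[, ho_lines, drop = FALSE])
    ok <- rowSums(is.na(Xh)) == 0L
    Xh <- Xh[ok, , drop = FALSE]
    holdout_r <- vapply(seq_len(nrow(top)), function(i) {
      cols <- strsplit(top$subset[i], "+", fixed = TRUE)[[1L]]
      fit <- bag_forest(X[, cols, drop = FALSE], y, n_trees = n_trees,
                        seed = derive_seed(seed, 7919L + i))
      suppressWarnings(stats::cor(predict(fit, Xh[, cols, drop = FALSE]),
                                  holdout[rownames(Xh)]))
    }, 0)
    top$holdout_r <- holdout_r
  }
  list(models = models, top = top, n_trees = n_trees, cv_folds = cv_folds,
       seed = seed)
}

#' Regulatory-p-site drug screen
#'
#' [correlation_screen()] restricted to p-sites whose regulatory class is
#' annotated (activating or inhibitory): sites reporting on kinase activity.
#' The output carries the class so that e.g. a positive correlation of an
#' inhibitory site with a drug's sensitivity can seed co-treatment
#' hypotheses.
#'
#' @param psites an [intensity_matrix()] of p-sites.
#' @param drugs a [drug_response_matrix()].
#' @param annotation [psite_annotation()] providing `reg_class`.
#' @param min_n pairwise-complete minimum (default 7).
#' @return MarkerTable data.frame with an extra `reg_class` column.
#' @export
regulatory_site_screen <- function(psites, drugs, annotation, min_n = 7L) {
  cls <- stats::setNames(annotation$reg_class, annotation$psite)
  keep <- rownames(psites)[cls[rownames(psites)] %in% c("activating", "inhibitory")]
  if (!length(keep)) stop("regulatory_site_screen: no regulatory-annotated sites")
  sub <- intensity_matrix(unclass(psites)[keep, , drop = FALSE], "psite")
  out <- correlation_screen(sub, drugs, min_n = min_n)
  out$reg_class <- unname(cls[out$feature])
  out
}
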