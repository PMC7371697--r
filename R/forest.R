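#' @title Bagged regression-tree forest
#' @description A compact random-forest regressor (bootstrap-aggregated CART
#'   trees with per-split feature subsampling), used by the metabolic
#'   subset-model screen. Written in-package because no random-forest
#'   implementation is part of the supported dependency set; adequate for the
#'   small panels (<= 14 features, tens of cell lines) it is applied to.
#' @name phosmarker-forest
NULL

# Grow one regression tree by exhaustive variance-reduction split search on a
# random feature subset at each node. Returns a flat list of nodes.
grow_tree <- function(x, y, mtry, min_node = 3L, max_depth = 12L) {
  nodes <- list()
  new_node <- function(idx, depth) {
    node <- list(pred = mean(y[idx]), split_var = NA_integer_,
                 split_val = NA_real_, left = NA_integer_, right = NA_integer_)
    if (length(idx) < 2L * min_node || depth >= max_depth ||
        stats::var(y[idx]) == 0) {
      nodes[[length(nodes) + 1L]] <<- node
      return(length(nodes))
    }
    vars <- sample.int(ncol(x), min(mtry, ncol(x)))
    best <- list(score = Inf)
    for (v in vars) {
      xv <- x[idx, v]
      ord <- order(xv)
      xs <- xv[ord]; ys <- y[idx][ord]
      n <- length(ys)
      csum <- cumsum(ys); tot <- csum[n]
      csq <- cumsum(ys^2); totsq <- csq[n]
      nl <- seq_len(n - 1L)
      valid <- xs[nl] != xs[nl + 1L] & nl >= min_node & (n - nl) >= min_node
      if (!any(valid)) next
      sseL <- csq[nl] - csum[nl]^2 / nl
      sseR <- (totsq - csq[nl]) - (tot - csum[nl])^2 / (n - nl)
      score <- sseL + sseR
      score[!valid] <- Inf
      j <- which.min(score)
      if (score[j] < best$score)
        best <- list(score = score[j], var = v,
                     val = (xs[j] + xs[j + 1L]) / 2)
    }
    if (!is.finite(best$score)) {
      nodes[[length(nodes) + 1L]] <<- node
      return(length(nodes))
    }
    go_left <- x[idx, best$var] <= best$val
    node$split_var <- best$var
    node$split_val <- best$val
    nodes[[length(nodes) + 1L]] <<- node
    me <- length(nodes)
    nodes[[me]]$left <<- new_node(idx[go_left], depth + 1L)
    nodes[[me]]$right <<- new_node(idx[!go_left], depth + 1L)
    me
  }
  root <- new_node(seq_along(y), 0L)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, x) {
  apply(x, 1L, function(row) {
    i <- tree$root
    repeat {
      nd <- tree$nodes[[i]]
      if (is.na(nd$split_var)) return(nd$pred)
      i <- if (row[nd$split_var] <= nd$split_val) nd$left else nd$right
    }
  })
}

#' Fit a bagged regression forest
#'
#' @param x numeric matrix, samples x features (no NAs).
#' @param y numeric response.
#' @param n_trees number of bootstrap trees (default 500).
#' @param mtry features tried per split (default: all features, the
#'   usual regression-forest choice; bagging provides the randomness).
#' @param min_node minimum samples per leaf-side of a split (default 3;
#'   small because the screen targets panels of tens of cell lines).
#' @param seed RNG seed; fits are reproducible given the seed.
#' @return a `bag_forest` model object.
#' @export
bag_forest <- function(x, y, n_trees = 500L, mtry = NULL, min_node = 3L,
                       seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), !anyNA(x), !anyNA(y))
  if (is.null(mtry)) mtry <- ncol(x)
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(i) {
    idx <- sample.int(nrow(x), replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], y[idx], mtry = mtry, min_node = min_node)
  })
  structure(list(trees = trees, mtry = mtry, n_trees = n_trees,
                 features = colnames(x)), class = "bag_forest")
}

#' @rdname bag_forest
#' @param object a `bag_forest`.
#' @param newdata samples x features matrix with the training columns.
#' @param ... unused.
#' @export
predict.bag_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) newdata <- newdata[, object$features, drop = FALSE]
  preds <- vapply(object$trees, predict_tree, numeric(nrow(newdata)),
                  x = newdata)
  if (nrow(newdata) == 1L) mean(preds) else rowMeans(preds)
}
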