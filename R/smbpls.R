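#' @title Sparse multiblock partial least squares regression
#' @description Links multiple omics blocks (cell lines x features) to a drug
#'   response matrix through latent components with sparse feature weights
#'   per block, nonnegative block combination weights, and sparse drug
#'   weights, so that each component reads as "a cluster of drugs (nonzero q)
#'   explained by a sparse set of markers (nonzero w)". The update rules are
#'   NIPALS iterations with soft-thresholding after a dense warm start;
#'   sparsity parameters are expressed on the correlation scale (a minimum
#'   |Pearson r| with the latent score; 0 disables sparsity, and one block
#'   with lambda = 0 reduces exactly to PLS-SVD of X'Y).
#' @name phosmarker-smbpls
NULL

# Soft-threshold a cross-covariance vector on the correlation scale, then
# normalize. `v` is X'u for column-standardized X and centered u, so
# v / ((n-1) sd(u)) is the vector of Pearson correlations with u; lambda is
# therefore an interpretable "minimum |correlation|" sparsity level,
# independent of n, block size and extreme-value statistics. Returns NULL
# when everything is zeroed (over-sparsified).
sparse_unit <- function(v, lambda, scale) {
  if (all(v == 0) || scale == 0) return(NULL)
  w <- soft_threshold(v / scale, lambda)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) return(NULL)
  w / nrm
}

standardize_block <- function(x) {
  x <- as.matrix(unclass(x))
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2L, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  n_missing <- sum(is.na(xs))
  xs[is.na(xs)] <- 0  # mean-imputation equivalent after standardization
  attr(xs, "n_imputed") <- n_missing
  xs
}

#' Fit a sparse multiblock PLS model
#'
#' Per component: initialize u as the first left singular vector of Y; then
#' iterate w_b = S(X_b' u, lambda_b), normalized; t_b = X_b w_b;
#' a_b proportional to max(cov(t_b, u), 0)^2, summing to 1 (squared
#' covariances, so an uninformative block is suppressed rather than merely
#' down-weighted); t = sum a_b t_b; q = S(Y' t, lambda_y), normalized;
#' u = Y q; until the super score t moves by less than `tol`. Each component
#' first converges the dense (lambda = 0) iteration, then switches the
#' sparsity on (graduated sparsity), so thresholding prunes a converged
#' covariance direction rather than the raw initialization. Soft-threshold
#' levels are applied on the correlation scale: lambda_b = 0.4 zeroes
#' features whose |Pearson r| with the drug score u is below 0.4. X_b and Y
#' are then deflated on t and the next component is extracted. Missing
#' entries are zero-filled after column standardization (mean-imputation
#' equivalent) with a logged count. The sign indeterminacy is resolved by
#' forcing the largest-magnitude entry of each q positive.
#'
#' @param blocks named list of cell lines x features matrices (or
#'   [intensity_matrix()]s transposed by the caller — rows must be cell
#'   lines). All blocks must share rownames with `Y`.
#' @param Y a [drug_response_matrix()] (drugs x cell lines; transposed and
#'   standardized internally) or a cell lines x drugs matrix.
#' @param n_components number of components.
#' @param lambda_block per-block sparsity levels in [0, 1), on the
#'   correlation scale (recycled across blocks).
#' @param lambda_y drug-weight sparsity level in [0, 1), correlation scale.
#' @param on_oversparse "error" aborts with the offending block named when a
#'   weight vector is entirely zeroed; "truncate" stops extracting further
#'   components with a warning (useful when mining an unknown number of drug
#'   clusters).
#' @param tol convergence tolerance on the super score (default 1e-8).
#' @param max_iter maximum NIPALS iterations per component (default 500).
#' @param seed kept for interface stability; the fit is deterministic.
#' @return an `smbpls_model`: per-component lists `w` (block weights), `t_b`
#'   (block scores), `a` (block combination weights), `t` (super scores), `q`
#'   (drug weights), `u` (drug scores), plus `deflation_norms`, `iterations`,
#'   `lambda_block`, `lambda_y`, `n_imputed`.
#' @export
fit_smbpls <- function(blocks, Y, n_components = 2L, lambda_block = 0.4,
                       lambda_y = 0.3, tol = 1e-8, max_iter = 500L,
                       on_oversparse = c("error", "truncate"), seed = 1L) {
  on_oversparse <- match.arg(on_oversparse)
  if (inherits(Y, "drug_response_matrix")) Y <- t(unclass(Y))
  Y <- as.matrix(Y)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  Xb <- lapply(blocks, function(b) {
    b <- as.matrix(unclass(b))
    b[rownames(Y), , drop = FALSE]
  })
  lambda_block <- rep_len(lambda_block, length(Xb))
  if (any(lambda_block < 0 | lambda_block >= 1) || lambda_y < 0 || lambda_y >= 1)
    stop("fit_smbpls: sparsity fractions must be in [0, 1)")
  Xb <- lapply(Xb, standardize_block)
  n_imputed <- sum(vapply(Xb, function(x) attr(x, "n_imputed"), 0))
  if (n_imputed > 0)
    message("fit_smbpls: zero-filled ", n_imputed,
            " missing entries after standardization")
  Ys <- standardize_block(Y)
  n_imputed_y <- attr(Ys, "n_imputed")

  comps <- list()
  deflation_norms <- matrix(NA_real_, n_components, length(Xb) + 1L,
                            dimnames = list(NULL, c(names(Xb), "Y")))
  for (comp in seq_len(n_components)) {
    # one NIPALS run from a given drug-score initialization; returns NULL
    # when a weight vector is entirely zeroed (over-sparsified)
    extract_component <- function(u_init) {
      u <- u_init
      t_old <- rep(0, nrow(Ys))
      iter <- 0L
      # dense warm start: converge the lambda = 0 (plain multiblock PLS)
      # iteration first, then switch the sparsity on, so thresholding prunes
      # a converged covariance direction instead of the raw initialization
      warm <- TRUE
      repeat {
        iter <- iter + 1L
        lam_b <- if (warm) rep(0, length(Xb)) else lambda_block
        lam_y <- if (warm) 0 else lambda_y
        w <- vector("list", length(Xb))
        tb <- matrix(0, nrow(Ys), length(Xb))
        su <- stats::sd(u)
        for (b in seq_along(Xb)) {
          wb <- sparse_unit(crossprod(Xb[[b]], u)[, 1L], lam_b[b],
                            (nrow(Ys) - 1) * su)
          if (is.null(wb)) return(structure(list(), block = names(Xb)[b]))
          w[[b]] <- wb
          tb[, b] <- Xb[[b]] %*% wb
        }
        a <- vapply(seq_along(Xb), function(b)
          max(stats::cov(tb[, b], u), 0), 0)^2
        if (sum(a) == 0) a <- rep(1, length(Xb))
        a <- a / sum(a)
        tt <- as.numeric(tb %*% a)
        tn <- sqrt(sum(tt^2))
        if (tn == 0) return(structure(list(), block = names(Xb)[1L]))
        tt <- tt / tn
        q <- sparse_unit(crossprod(Ys, tt)[, 1L], lam_y,
                         (nrow(Ys) - 1) * stats::sd(tt))
        if (is.null(q)) return(structure(list(), block = "Y"))
        u <- as.numeric(Ys %*% q)
        delta <- sqrt(sum((tt - t_old)^2))
        t_old <- tt
        if (delta < tol) {
          if (warm) { warm <- FALSE; t_old <- rep(0, nrow(Ys)) } else break
        }
        if (iter >= max_iter) {
          warning("fit_smbpls: component ", comp,
                  " did not converge (last delta ",
                  format(delta, digits = 3), ")")
          break
        }
      }
      list(w = w, tb = tb, a = a, t = tt, q = q, u = u, iterations = iter,
           objective = abs(sum(tt * u)))
    }

    # multi-start: leading singular vectors of the residual Y plus the
    # best-aligned single drug profiles; near-degenerate cluster strengths
    # rotate the singular vectors into mixtures, and a pure component always
    # has higher covariance with its drug score than a mixture, so the run
    # with the largest objective is kept
    sv <- svd(Ys, nu = min(3L, ncol(Ys), nrow(Ys)), nv = 0L)
    col_norms <- sqrt(colSums(Ys^2))
    top_drugs <- order(col_norms, decreasing = TRUE)[seq_len(min(2L, ncol(Ys)))]
    inits <- c(lapply(seq_len(ncol(sv$u)), function(j) sv$u[, j]),
               lapply(top_drugs, function(d) Ys[, d]))
    runs <- lapply(inits, extract_component)
    ok <- which(vapply(runs, function(r) length(r) > 0L, TRUE))
    if (!length(ok)) {
      if (on_oversparse == "truncate") {
        warning("fit_smbpls: stopped after ", comp - 1L,
                " component(s); residual structure over-sparsified")
        break
      }
      stop("fit_smbpls: component ", comp, " over-sparsified in block '",
           attr(runs[[1L]], "block"), "' (lambda too large)")
    }
    best <- runs[[ok[which.max(vapply(runs[ok], `[[`, 0, "objective"))]]]
    w <- best$w; tb <- best$tb; a <- best$a; tt <- best$t; q <- best$q
    u <- best$u; iter <- best$iterations
    # resolve sign: largest-magnitude drug weight positive
    if (q[which.max(abs(q))] < 0) {
      q <- -q; u <- -u; tt <- -tt
      w <- lapply(w, function(x) -x)
      tb <- -tb
    }
    names(q) <- colnames(Ys)
    for (b in seq_along(w)) names(w[[b]]) <- colnames(Xb[[b]])
    comps[[comp]] <- list(w = stats::setNames(w, names(Xb)),
                          t_b = tb, a = stats::setNames(a, names(Xb)),
                          t = tt, q = q, u = u, iterations = iter)
    # deflate blocks and Y on the super score
    for (b in seq_along(Xb)) {
      p <- crossprod(Xb[[b]], tt)[, 1L] / sum(tt^2)
      Xb[[b]] <- Xb[[b]] - tcrossprod(tt, p)
      deflation_norms[comp, b] <- sqrt(sum(Xb[[b]]^2))
    }
    c_y <- crossprod(Ys, tt)[, 1L] / sum(tt^2)
    Ys <- Ys - tcrossprod(tt, c_y)
    deflation_norms[comp, ncol(deflation_norms)] <- sqrt(sum(Ys^2))
  }
  structure(list(components = comps, deflation_norms = deflation_norms,
                 lambda_block = lambda_block, lambda_y = lambda_y,
                 n_components = n_components, block_names = names(blocks),
                 n_imputed = n_imputed + n_imputed_y,
                 cell_lines = rownames(Y)),
            class = "smbpls_model")
}

#' @export
print.smbpls_model <- function(x, ...) {
  cat(sprintf("<smbpls_model> %d components, blocks: %s\n", x$n_components,
              paste(x$block_names, collapse = ", ")))
  for (i in seq_along(x$components)) {
    cc <- x$components[[i]]
    cat(sprintf("  comp %d: %d drugs, %s markers, %d iter\n", i,
                sum(cc$q != 0),
                paste(vapply(cc$w, function(w) sum(w != 0), 0L), collapse = "+"),
                cc$iterations))
  }
  invisible(x)
}

#' Report drug clusters and their markers
#'
#' Per component: the drug cluster (drugs with |q| >= `min_abs_q`), drug
#' effect sizes (|q|), the marker list with direction (sensitivity when
#' sign(w) * sign(q-consensus) > 0 under the canonical orientation), and
#' drug-drug edges as the pairwise Pearson r of the observed sensitivity
#' columns (pairwise-complete, >= `min_n`).
#'
#' @param model an `smbpls_model`.
#' @param Y the [drug_response_matrix()] used for the fit (for edges).
#' @param min_abs_q cluster membership floor as a fraction of the
#'   component's largest |q| (default 0.25): drugs with tiny but nonzero
#'   weights are not reported as cluster members.
#' @param min_n pairwise-complete minimum for edges (default 7).
#' @return list of per-component reports: `drugs` (data.frame drug, q),
#'   `markers` (data.frame feature, block, weight, direction), `edges`
#'   (data.frame drug_a, drug_b, r, n).
#' @export
report_clusters <- function(model, Y, min_abs_q = 0.25, min_n = 7L) {
  if (inherits(Y, "drug_response_matrix")) Ym <- t(unclass(Y)) else Ym <- as.matrix(Y)
  reports <- list()
  for (i in seq_along(model$components)) {
    cc <- model$components[[i]]
    sel <- which(cc$q != 0 & abs(cc$q) >= min_abs_q * max(abs(cc$q)))
    if (!length(sel)) { warning("report_clusters: component ", i, " empty; skipped"); next }
    drugs <- data.frame(drug = names(cc$q)[sel], q = unname(cc$q[sel]),
                        effect_size = abs(unname(cc$q[sel])),
                        stringsAsFactors = FALSE)
    # consensus drug sign: sign of the dominant q entry (positive by the
    # model's sign convention)
    qs <- sign(cc$q[which.max(abs(cc$q))])
    markers <- do.call(rbind, lapply(names(cc$w), function(b) {
      w <- cc$w[[b]]
      nz <- which(w != 0)
      if (!length(nz)) return(NULL)
      data.frame(feature = names(w)[nz], block = b, weight = unname(w[nz]),
                 direction = ifelse(sign(w[nz]) * qs > 0, "sensitivity",
                                    "resistance"),
                 stringsAsFactors = FALSE)
    }))
    edges <- NULL
    if (nrow(drugs) >= 2L) {
      cmb <- utils::combn(drugs$drug, 2L)
      edges <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
        ya <- Ym[, cmb[1L, j]]; yb <- Ym[, cmb[2L, j]]
        flt <- pairwise_complete_filter(ya, yb, min_n = min_n)
        if (flt$rejected) return(NULL)
        pt <- pearson_test(ya[flt$indices], yb[flt$indices])
        data.frame(drug_a = cmb[1L, j], drug_b = cmb[2L, j],
                   r = pt$statistic, n = pt$n, stringsAsFactors = FALSE)
      }))
    }
    reports[[length(reports) + 1L]] <-
      list(component = i, drugs = drugs, markers = markers, edges = edges)
  }
  reports
}

#' Cross-validated sparsity selection
#'
#' Evaluates a grid of (lambda_block, lambda_y) pairs by `cv_folds`-fold
#' cross-validated Y-reconstruction error and returns the sparsest grid
#' point within one standard error of the minimum.
#'
#' @param blocks,Y as in [fit_smbpls()].
#' @param grid data.frame with columns lambda_block, lambda_y (duplicates
#'   are ignored).
#' @param n_components components used during evaluation (default 2).
#' @param cv_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `lambda_block`, `lambda_y`, `cv` (per-grid-point errors).
#' @export
select_sparsity <- function(blocks, Y, grid, n_components = 2L, cv_folds = 5L,
                            seed = 1L) {
  if (!nrow(grid)) stop("select_sparsity: empty grid")
  grid <- unique(grid[, c("lambda_block", "lambda_y")])
  if (inherits(Y, "drug_response_matrix")) Ym <- t(unclass(Y)) else Ym <- as.matrix(Y)
  blocks <- lapply(blocks, function(b) as.matrix(unclass(b))[rownames(Ym), , drop = FALSE])
  n <- nrow(Ym)
  set.seed(derive_seed(seed, 0L))
  foldid <- sample(rep_len(seq_len(cv_folds), n))
  errs <- matrix(NA_real_, nrow(grid), cv_folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      fit <- tryCatch(
        fit_smbpls(lapply(blocks, function(b) b[tr, , drop = FALSE]),
                   Ym[tr, , drop = FALSE], n_components = n_components,
                   lambda_block = grid$lambda_block[g],
                   lambda_y = grid$lambda_y[g]),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict_smbpls(fit, lapply(blocks, function(b) b[!tr, , drop = FALSE]),
                             train_blocks = lapply(blocks, function(b) b[tr, , drop = FALSE]),
                             train_Y = Ym[tr, , drop = FALSE])
      obs <- scale(Ym[!tr, , drop = FALSE],
                   center = colMeans(Ym[tr, , drop = FALSE], na.rm = TRUE),
                   scale = apply(Ym[tr, , drop = FALSE], 2L, stats::sd, na.rm = TRUE))
      ok <- !is.na(obs)
      errs[g, f] <- mean((pred[ok] - obs[ok])^2)
    }
  }
  mean_err <- rowMeans(errs, na.rm = TRUE)
  if (all(is.na(mean_err))) stop("select_sparsity: all grid points over-sparsified")
  se <- apply(errs, 1L, function(e) stats::sd(e, na.rm = TRUE) / sqrt(sum(!is.na(e))))
  best <- which.min(mean_err)
  cutoff <- mean_err[best] + ifelse(is.na(se[best]), 0, se[best])
  ok <- which(!is.na(mean_err) & mean_err <= cutoff)
  sparsity <- grid$lambda_block + grid$lambda_y
  pick <- ok[order(-sparsity[ok], mean_err[ok])][1L]
  list(lambda_block = grid$lambda_block[pick], lambda_y = grid$lambda_y[pick],
       cv = data.frame(grid, mean_error = mean_err, se = se))
}

# project new cell lines through a fitted model and rebuild standardized-Y
# predictions component by component
predict_smbpls <- function(model, new_blocks, train_blocks, train_Y) {
  tr_std <- lapply(train_blocks, function(b) {
    mu <- colMeans(b, na.rm = TRUE)
    sd <- apply(b, 2L, stats::sd, na.rm = TRUE)
    sd[!is.finite(sd) | sd == 0] <- 1
    list(mu = mu, sd = sd)
  })
  Xn <- lapply(seq_along(new_blocks), function(b) {
    x <- sweep(sweep(as.matrix(new_blocks[[b]]), 2L, tr_std[[b]]$mu, "-"),
               2L, tr_std[[b]]$sd, "/")
    x[is.na(x)] <- 0
    x
  })
  Xt <- lapply(seq_along(train_blocks), function(b) {
    x <- sweep(sweep(as.matrix(train_blocks[[b]]), 2L, tr_std[[b]]$mu, "-"),
               2L, tr_std[[b]]$sd, "/")
    x[is.na(x)] <- 0
    x
  })
  mu_y <- colMeans(train_Y, na.rm = TRUE)
  sd_y <- apply(train_Y, 2L, stats::sd, na.rm = TRUE)
  sd_y[!is.finite(sd_y) | sd_y == 0] <- 1
  Yt <- sweep(sweep(train_Y, 2L, mu_y, "-"), 2L, sd_y, "/")
  Yt[is.na(Yt)] <- 0
  pred <- matrix(0, nrow(Xn[[1L]]), ncol(train_Y))
  for (cc in model$components) {
    tb_new <- do.call(cbind, lapply(seq_along(Xn), function(b) Xn[[b]] %*% cc$w[[b]]))
    tb_tr <- do.call(cbind, lapply(seq_along(Xt), function(b) Xt[[b]] %*% cc$w[[b]]))
    t_new <- as.numeric(tb_new %*% cc$a)
    t_tr <- as.numeric(tb_tr %*% cc$a)
    c_y <- crossprod(Yt, t_tr)[, 1L] / sum(t_tr^2)
    pred <- pred + tcrossprod(t_new, c_y)
    for (b in seq_along(Xt)) {
      p <- crossprod(Xt[[b]], t_tr)[, 1L] / sum(t_tr^2)
      Xt[[b]] <- Xt[[b]] - tcrossprod(t_tr, p)
      Xn[[b]] <- Xn[[b]] - tcrossprod(t_new, p)
    }
    Yt <- Yt - tcrossprod(t_tr, c_y)
  }
  pred
}
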