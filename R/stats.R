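#' @title Shared statistical kernel
#' @description Pearson tests, empirical-Bayes moderated t, hypergeometric
#'   enrichment, Benjamini-Hochberg adjustment and the RV matrix correlation.
#'   These primitives are reused by every downstream analysis stage.
#' @name phosmarker-stats
NULL

test_result <- function(statistic, p, effect = NA_real_, n = NA_integer_,
                        q = NA_real_, undefined = FALSE) {
  list(statistic = statistic, p = p, q = q, effect = effect, n = n,
       undefined = undefined)
}

#' Pearson correlation test
#'
#' Two-sided test of zero correlation via the t transform with n - 2 degrees
#' of freedom. Pairs with a missing value in either series are dropped first.
#' A constant series yields an UNDEFINED result (flagged, not an error), since
#' flat features are routine in filtered intensity matrices.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `statistic` (r), `p`, `effect` (= r), `n`, `undefined`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_result(NA_real_, NA_real_, n = n, undefined = TRUE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  test_result(r, p, effect = r, n = n)
}

#' Moderated two-sample t-test
#'
#' Empirical-Bayes moderated t: the pooled sample variance s^2 (d = nA+nB-2
#' df) is shrunk toward a prior `prior_var` (s0^2) carrying `prior_df` (d0)
#' degrees of freedom, s_post^2 = (d0 s0^2 + d s^2) / (d0 + d), and the
#' statistic (meanA - meanB) / (s_post sqrt(1/nA + 1/nB)) is referred to a t
#' distribution with d0 + d df. `prior_df = 0` recovers the classical pooled
#' t; `prior_df = Inf` fixes the variance at `prior_var`.
#'
#' @param a,b numeric vectors (>= 2 observed values each).
#' @param prior_df prior degrees of freedom d0 (>= 0, may be `Inf`).
#' @param prior_var prior variance s0^2 (ignored when `prior_df = 0`).
#' @return list with `statistic`, `p`, `effect` (meanA - meanB, a log10
#'   fold-change on log10 inputs), `n`.
#' @seealso [moderated_t_matrix()] which estimates the prior from a feature
#'   matrix by moment matching.
#' @export
moderated_t <- function(a, b, prior_df = 0, prior_var = NA_real_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("moderated_t: each group needs >= 2 observed values")
  d <- na + nb - 2
  s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / d
  if (is.infinite(prior_df)) {
    s2_post <- prior_var
    df_total <- Inf
  } else if (prior_df == 0) {
    s2_post <- s2
    df_total <- d
  } else {
    s2_post <- (prior_df * prior_var + d * s2) / (prior_df + d)
    df_total <- prior_df + d
  }
  eff <- mean(a) - mean(b)
  tt <- eff / sqrt(s2_post * (1 / na + 1 / nb))
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tt)) else
    2 * stats::pt(-abs(tt), df = df_total)
  test_result(tt, p, effect = eff, n = na + nb)
}

#' Estimate the variance prior by moment matching
#'
#' Closed-form moment matching of the scaled-F model for observed sample
#' variances on the log scale: with s^2 ~ s0^2 F(d, d0),
#' Var(log s^2) = trigamma(d/2) + trigamma(d0/2), so d0 follows from a
#' trigamma inversion and s0^2 from the mean of log s^2. This is a
#' deterministic stand-in for a full empirical-Bayes ML fit.
#'
#' @param s2 vector of sample variances (one per feature).
#' @param df residual degrees of freedom of each s2 (scalar).
#' @return list with `prior_df` (d0, possibly `Inf`) and `prior_var` (s0^2).
#' @export
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) stop("fit_variance_prior: need >= 2 positive variances")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
  }
  list(prior_df = d0, prior_var = s0)
}

# Invert the trigamma function by Newton iteration.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated t-test across a feature matrix
#'
#' Runs [moderated_t()] on every row of a features x samples matrix for a
#' binary grouping, with (d0, s0^2) estimated once from the distribution of
#' residual variances via [fit_variance_prior()], and BH-adjusted q-values.
#'
#' @param mat numeric matrix, features x samples.
#' @param groups logical or two-level vector over columns; `TRUE` (or the
#'   first level) is "group A". Effects are meanA - meanB.
#' @return data.frame with feature, statistic, effect, n, p, q.
#' @export
moderated_t_matrix <- function(mat, groups) {
  if (is.logical(groups)) {
    ga <- groups
  } else {
    lev <- unique(groups)
    if (length(lev) != 2L) stop("moderated_t_matrix: groups must be binary")
    ga <- groups == lev[1L]
  }
  stopifnot(length(ga) == ncol(mat))
  a <- mat[, ga, drop = FALSE]
  b <- mat[, !ga, drop = FALSE]
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  usable <- na >= 2 & nb >= 2
  va <- apply(a, 1L, stats::var, na.rm = TRUE)
  vb <- apply(b, 1L, stats::var, na.rm = TRUE)
  d <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / d
  # prior fitted on the modal df so moment matching sees a homogeneous sample
  df_mode <- as.numeric(names(which.max(table(d[usable]))))
  prior <- fit_variance_prior(s2[usable & d == df_mode & s2 > 0], df_mode)
  eff <- rowMeans(a, na.rm = TRUE) - rowMeans(b, na.rm = TRUE)
  if (is.infinite(prior$prior_df)) {
    s2_post <- rep(prior$prior_var, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (prior$prior_df * prior$prior_var + d * s2) / (prior$prior_df + d)
    df_total <- prior$prior_df + d
  }
  tt <- eff / sqrt(s2_post * (1 / na + 1 / nb))
  p <- ifelse(is.infinite(df_total), 2 * stats::pnorm(-abs(tt)),
              2 * stats::pt(-abs(tt), df = df_total))
  p[!usable] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  data.frame(feature = rownames(mat) %||% seq_len(nrow(mat)),
             statistic = tt, effect = eff, n = na + nb, p = p, q = q,
             prior_df = prior$prior_df, prior_var = prior$prior_var,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided hypergeometric enrichment test
#'
#' P(X >= overlap) for X ~ Hypergeometric(universe, set_size, group_size);
#' identical to the one-sided Fisher exact test on the 2x2 enrichment table.
#'
#' @param overlap observed overlap count.
#' @param set_size size of the annotated set.
#' @param group_size size of the selected group.
#' @param universe size of the analyzed universe.
#' @return list with `statistic` (= overlap), `p`, `effect`
#'   (fold-enrichment over expectation), `n` (= universe).
#' @export
hypergeom_enrich <- function(overlap, set_size, group_size, universe) {
  if (any(c(overlap, set_size, group_size, universe) < 0) ||
      overlap > min(set_size, group_size) ||
      set_size > universe || group_size > universe) {
    stop("hypergeom_enrich: inconsistent counts")
  }
  p <- stats::phyper(overlap - 1, set_size, universe - set_size, group_size,
                     lower.tail = FALSE)
  expected <- set_size * group_size / universe
  eff <- if (expected > 0) overlap / expected else NA_real_
  test_result(overlap, p, effect = eff, n = universe)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_i = min over {j : p_j >= p_i} of p_j * m / rank_j,
#' capped at 1. Order-preserving in the input ranks.
#'
#' @param p vector of p-values in [0, 1] (no NAs).
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("bh_adjust: p-values must be in [0,1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
}

#' RV coefficient between two matrices
#'
#' Matrix-level analogue of the Pearson correlation between two blocks sharing
#' rows (cell lines): RV = tr(XX'YY') / sqrt(tr((XX')^2) tr((YY')^2)).
#' Columns are mean-centered internally. A zero (constant) matrix yields NA
#' with a warning rather than an error.
#'
#' @param x,y numeric matrices with the same number of rows.
#' @return scalar in [0, 1], or NA if either configuration is zero.
#' @export
rv_coefficient <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  y <- scale(as.matrix(y), center = TRUE, scale = FALSE)
  sx <- tcrossprod(x)
  sy <- tcrossprod(y)
  den <- sqrt(sum(sx * sx) * sum(sy * sy))
  if (den == 0) {
    warning("rv_coefficient: zero configuration; RV undefined")
    return(NA_real_)
  }
  sum(sx * sy) / den
}

#' Serialize test results to a TSV-ready data.frame
#'
#' @param results named list of results from the `*_test`/`*_enrich` functions.
#' @return data.frame with columns id, statistic, effect, n, p, q.
#' @export
test_results_table <- function(results) {
  do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(id = id, statistic = r$statistic, effect = r$effect,
               n = r$n, p = r$p, q = r$q, stringsAsFactors = FALSE)
  }))
}
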