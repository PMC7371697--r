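#' Soft-thresholding operator
#'
#' The L1 proximal operator `S(x, lambda) = sign(x) * max(|x| - lambda, 0)`,
#' used by the sparse multiblock PLS updates.
#'
#' @param x numeric vector.
#' @param lambda non-negative threshold.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' soft_threshold(c(0.5, -0.1), 0.2)  # 0.3, 0
soft_threshold <- function(x, lambda) {
  stopifnot(is.numeric(x), is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  sign(x) * pmax(abs(x) - lambda, 0)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted correlation modules against a detected
#' partition. Labels may be any atomic vectors; NA labels are dropped pairwise.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) return(NA_real_)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Round half away from zero
#'
#' Rounding convention for reported integer fold-changes (151, 12, 17x, ...):
#' ties go away from zero rather than to even as in base [round()].
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Jaccard index of two sets
#' @param a,b vectors treated as sets.
#' @return scalar in [0, 1]; 1 for identical non-empty sets.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

# Derive a child RNG seed from a master seed and a stream index, kept within
# 32-bit integer range. Each generator output block draws from its own stream
# so adding outputs never perturbs existing ones.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + 97 * stream) %% .Machine$integer.max)
}

# Column z-scores over observed entries; columns = cell lines handled by caller.
# Operates on rows of a features x cell-lines matrix.
row_zscore <- function(mat) {
  mu <- rowMeans(mat, na.rm = TRUE)
  sd <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- NA_real_
  (mat - mu) / sd
}

`%||%` <- function(x, y) if (is.null(x)) y else x
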