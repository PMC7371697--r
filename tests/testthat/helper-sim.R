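# Shared fixtures, all built in code at test time.

# A reduced panel that keeps every planted structure but runs fast.
small_config <- function(seed = 1L, ...) {
  args <- list(n_cell_lines = 40L, n_proteins = 120L, n_psites = 140L,
               n_tissue_groups = 4L, n_pathways = 4L, pathway_size = 8L,
               n_kinases = 3L, substrates_per_kinase = 6L, n_outliers = 5L,
               n_drugs = 12L, n_drug_clusters = 2L,
               n_differential_features = 12L, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# intensity matrix from a plain matrix with auto ids
im <- function(values, kind = "protein", features = NULL, lines = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- features %||% sprintf("F%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- lines %||% sprintf("c%02d", seq_len(ncol(values)))
  intensity_matrix(values, kind)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# planted correlation-block world used by the module tests: `blocks` blocks
# of `block_size` features at within-block correlation ~r, plus noise
planted_blocks <- function(n_lines = 60L, blocks = 2L, block_size = 15L,
                           n_noise = 80L, r = 0.9, seed = 1L) {
  set.seed(seed)
  lambda <- sqrt(r / (1 - r))  # loading for unit noise
  rows <- list()
  labels <- integer(0)
  for (b in seq_len(blocks)) {
    f <- rnorm(n_lines)
    x <- matrix(rnorm(block_size * n_lines), block_size, n_lines) +
      lambda * rep(f, each = block_size)
    rows[[b]] <- x
    labels <- c(labels, rep(b, block_size))
  }
  rows[[blocks + 1L]] <- matrix(rnorm(n_noise * n_lines), n_noise, n_lines)
  labels <- c(labels, rep(0L, n_noise))
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("F%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("c%02d", seq_len(n_lines))
  names(labels) <- rownames(m)
  list(mat = m, labels = labels)
}

best_cluster_jaccard <- function(reports, truth_labels) {
  ks <- sort(unique(truth_labels[truth_labels > 0]))
  vapply(ks, function(k) {
    truth_drugs <- names(truth_labels)[truth_labels == k]
    if (!length(reports)) return(0)
    max(0, vapply(reports, function(r)
      jaccard_index(r$drugs$drug, truth_drugs), 0))
  }, 0)
}
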