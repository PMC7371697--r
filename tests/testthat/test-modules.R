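test_that("topological overlap matches its definition on small cases", {
  # two identical features: adjacency 1, TOM 1 at beta = 1
  m <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  tm <- tom_matrix(m, beta = 1)
  expect_equal(tm$adjacency["a", "b"], 1)
  expect_equal(tm$tom["a", "b"], 1)
  # random 4-feature instance vs the brute-force double sum
  set.seed(12)
  x <- matrix(rnorm(4 * 12), 4, 12, dimnames = list(letters[1:4], NULL))
  tm <- tom_matrix(x, beta = 6)
  a <- tm$adjacency
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    num <- sum(vapply(1:4, function(u) a[i, u] * a[u, j], 0)) + a[i, j]
    den <- min(sum(a[i, ]), sum(a[j, ])) + 1 - a[i, j]
    expect_equal(tm$tom[i, j], num / den, tolerance = 1e-12)
  }
  expect_true(all(tm$tom >= 0 & tm$tom <= 1))
  expect_equal(tm$tom, t(tm$tom))
  expect_equal(unname(diag(tm$tom)), rep(1, 4))
  expect_error(tom_matrix(x, beta = 0.5), "beta")
})

test_that("planted correlation blocks are detected and noise left unassigned", {
  pb <- planted_blocks(n_lines = 60, blocks = 2, block_size = 15,
                       n_noise = 80, r = 0.9, seed = 3)
  part <- detect_modules(pb$mat, min_size = 10)
  found <- sort(unique(part$labels[part$labels > 0]))
  expect_identical(length(found), 2L)
  expect_true(all(part$labels[pb$labels == 0] == 0))
  expect_equal(adjusted_rand_index(part$labels[pb$labels > 0],
                                   pb$labels[pb$labels > 0]), 1)
  # eigenfeatures track the module mean profiles
  for (mid in found) {
    memb <- names(part$labels)[part$labels == mid]
    zprof <- colMeans(t(scale(t(pb$mat[memb, ]))))
    expect_gte(stats::cor(part$eigenfeatures[, paste0("M", mid)], zprof), 0.9)
  }
})

test_that("module recovery is stable across seeds (ARI >= 0.9)", {
  aris <- vapply(1:10, function(s) {
    pb <- planted_blocks(n_lines = 60, blocks = 3, block_size = 12,
                         n_noise = 60, r = 0.9, seed = s)
    part <- detect_modules(pb$mat, min_size = 8)
    keep <- pb$labels > 0
    adjusted_rand_index(part$labels[keep], pb$labels[keep])
  }, 0)
  expect_gte(min(aris), 0.9)
})

test_that("detect_modules validates its inputs", {
  m <- matrix(rnorm(40), 5, 8, dimnames = list(letters[1:5], NULL))
  m[1, ] <- NA
  expect_error(detect_modules(m), "all-missing feature.*a")
  m2 <- matrix(rnorm(100), 10, 10, dimnames = list(letters[1:10], NULL))
  m2[1, 1:6] <- NA
  expect_warning(detect_modules(m2, min_size = 2), "50%")
  expect_error(detect_modules(m2[, 1:7]), ">= 8 cell lines")
})

test_that("the planted differential module closes the three-axis circuit", {
  sim <- simulate_dataset(sim_config(seed = 1))
  comb <- rbind(unclass(median_center(sim$protein)),
                unclass(median_center(sim$psite)))
  comb <- comb[rowSums(!is.na(comb)) > 0, ]
  part <- suppressWarnings(detect_modules(comb))
  assoc <- associate_axes(part, sim$pathways, sim$phenotype, comb)
  ed <- assoc$edges
  # locate the module enriched for the differential-annotation set PW2
  sm <- ed[ed$axis_a == "set" & ed$node_a == "PW2" & ed$axis_b == "module", ]
  expect_gte(nrow(sm), 1L)
  mod <- sm$node_b[1]
  expect_true(any(ed$axis_a == "module" & ed$node_a == mod &
                    ed$axis_b == "phenotype" &
                    ed$direction == "up_in_positive"))
  expect_true(any(ed$axis_a == "set" & ed$node_a == "PW2" &
                    ed$axis_b == "phenotype" &
                    ed$direction == "up_in_positive"))

  # guilt-by-association: unannotated module members surface as candidates,
  # features already in the set never do
  cand <- guilt_by_association(assoc, sim$pathways)
  unannotated <- setdiff(sim$truth$differential_features$feature,
                         sim$pathways$PW2)
  expect_true(all(unannotated %in% cand$feature))
  expect_false(any(cand$feature %in% sim$pathways$PW2))
})

test_that("associate_axes handles degenerate inputs", {
  pb <- planted_blocks(n_lines = 20, blocks = 1, block_size = 12,
                       n_noise = 30, seed = 5)
  part <- detect_modules(pb$mat, min_size = 8)
  pheno <- stats::setNames(rep(c(TRUE, FALSE), each = 10), colnames(pb$mat))
  # empty set collection: no set axis edges
  assoc <- associate_axes(part, list(), pheno, pb$mat)
  expect_false(any(assoc$edges$axis_a == "set"))
  expect_error(associate_axes(part, list(), stats::setNames(rep(TRUE, 20),
               colnames(pb$mat)), pb$mat), "both phenotype classes")
  # no significant edges on pure noise -> empty GBA output
  cand <- guilt_by_association(assoc, list())
  expect_identical(nrow(cand), 0L)
})

test_that("permuted phenotypes produce edges at no more than the FDR level", {
  sim <- simulate_dataset(small_config(seed = 4))
  comb <- rbind(unclass(median_center(sim$protein)),
                unclass(median_center(sim$psite)))
  comb <- comb[rowSums(!is.na(comb)) > 0, ]
  part <- suppressWarnings(detect_modules(comb, min_size = 8))
  n_mods <- length(unique(part$labels[part$labels > 0]))
  n_tests_per_perm <- (length(sim$pathways) + n_mods) * 2
  set.seed(99)
  pheno <- sim$phenotype
  n_pheno_edges <- vapply(1:20, function(i) {
    perm <- stats::setNames(sample(pheno), names(pheno))
    assoc <- associate_axes(part, sim$pathways, perm, comb)
    sum(assoc$edges$axis_b == "phenotype")
  }, 0)
  expect_lte(mean(n_pheno_edges) / n_tests_per_perm, 0.05)
})

test_that("recapitulation overlap behaves at its extremes and mid-point", {
  set.seed(17)
  n <- 30
  mk <- function(mat) im(mat, kind = "protein")
  # identical matrices recapitulate identically -> overlap 1
  base <- matrix(rnorm(20 * n, 7, 1), 20, n,
                 dimnames = list(sprintf("G%02d", 1:20), sprintf("c%02d", 1:n)))
  f <- rnorm(n)
  base[1:10, ] <- base[1:10, ] + 2 * rep(f, each = 10)  # correlated pairs
  pairs <- data.frame(a = sprintf("G%02d", 1:5), b = sprintf("G%02d", 6:10),
                      pathway = "P1")
  res <- recapitulation_overlap(mk(base), mk(base), pairs)
  expect_equal(res$overlap_fraction, 1)
  # disjoint planted correlations -> overlap 0
  other <- matrix(rnorm(20 * n, 7, 1), 20, n, dimnames = dimnames(base))
  res0 <- recapitulation_overlap(mk(other), mk(base), pairs)
  expect_equal(res0$overlap_fraction, 0)
  expect_error(recapitulation_overlap(mk(base[11:20, ]), mk(base[11:20, ]),
                                      pairs),
               "no testable pairs")
})

test_that("half-shared planted correlations give overlap near one half", {
  overlaps <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 30
    ids <- sprintf("G%02d", 1:40)
    mk_level <- function(correlated_pairs) {
      m <- matrix(rnorm(40 * n, 7, 1), 40, n,
                  dimnames = list(ids, sprintf("c%02d", 1:n)))
      for (i in correlated_pairs) {
        f <- rnorm(n)
        m[2 * i - 1, ] <- m[2 * i - 1, ] + 2 * f
        m[2 * i, ] <- m[2 * i, ] + 2 * f
      }
      im(m)
    }
    phospho <- mk_level(1:20)          # all 20 pairs correlated
    protein <- mk_level(1:10)          # half of them also at protein level
    pairs <- data.frame(a = ids[seq(1, 39, 2)], b = ids[seq(2, 40, 2)])
    recapitulation_overlap(protein, phospho, pairs)$overlap_fraction
  }, 0)
  expect_equal(mean(overlaps), 0.5, tolerance = 0.1)
})
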