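test_that("soft_threshold implements the L1 proximal operator", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.1, 0.2), 0)
  expect_equal(soft_threshold(c(-1, 0, 2), 0.5), c(-0.5, 0, 1.5))
})

test_that("one dense block reduces exactly to PLS-SVD of X'Y", {
  set.seed(42)
  X <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("c%02d", 1:10), sprintf("f%d", 1:8)))
  Y <- matrix(rnorm(50), 10, 5,
              dimnames = list(rownames(X), sprintf("d%d", 1:5)))
  fit <- fit_smbpls(list(b = X), Y, n_components = 1,
                    lambda_block = 0, lambda_y = 0, tol = 1e-12)
  sv <- svd(crossprod(scale(X), scale(Y)))
  w <- fit$components[[1]]$w$b
  q <- fit$components[[1]]$q
  expect_lt(max(abs(abs(w) - abs(sv$u[, 1]))), 1e-6)
  expect_lt(max(abs(abs(q) - abs(sv$v[, 1]))), 1e-6)
})

test_that("super scores are orthogonal and Y-variance explained decreases", {
  set.seed(43)
  X <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(sprintf("c%02d", 1:30), sprintf("f%d", 1:20)))
  Y <- X[, 1:6] %*% matrix(rnorm(24), 6, 4) + matrix(rnorm(120, sd = 0.5), 30, 4)
  dimnames(Y) <- list(rownames(X), sprintf("d%d", 1:4))
  fit <- fit_smbpls(list(b = X), Y, n_components = 3,
                    lambda_block = 0, lambda_y = 0, tol = 1e-10)
  tmat <- sapply(fit$components, `[[`, "t")
  gram <- crossprod(tmat)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  norm0 <- sqrt(sum(scale(Y)^2, na.rm = TRUE))
  ynorms <- c(norm0, fit$deflation_norms[, "Y"])
  explained <- -diff(ynorms^2)
  expect_true(all(diff(explained) <= 1e-8))
  # sign convention: the dominant drug weight is positive; fits reproduce
  for (cc in fit$components) expect_gt(cc$q[which.max(abs(cc$q))], 0)
  fit2 <- fit_smbpls(list(b = X), Y, n_components = 3,
                     lambda_block = 0, lambda_y = 0, tol = 1e-10)
  expect_identical(fit$components, fit2$components)
})

test_that("over-sparsification errors name the offender or truncates on request", {
  set.seed(44)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("c%02d", 1:20), sprintf("f%d", 1:10)))
  Y <- matrix(rnorm(60), 20, 3,
              dimnames = list(rownames(X), sprintf("d%d", 1:3)))
  expect_error(fit_smbpls(list(noise = X), Y, n_components = 1,
                          lambda_block = 0.99, lambda_y = 0),
               "over-sparsified in block 'noise'")
  expect_warning(
    fit <- fit_smbpls(list(noise = X), Y, n_components = 2,
                      lambda_block = 0.99, lambda_y = 0,
                      on_oversparse = "truncate"),
    "over-sparsified")
  expect_identical(length(fit$components), 0L)
  expect_error(fit_smbpls(list(b = X), Y, lambda_y = 1.2), "\\[0, 1\\)")
})

test_that("planted drug clusters with disjoint marker blocks are recovered", {
  # 12 drugs in 2 pure clusters: cluster 1 driven by protein markers,
  # cluster 2 by p-site markers
  jac <- sapply(1:3, function(s) {
    sim <- simulate_dataset(sim_config(n_drugs = 12L, seed = s))
    fit <- suppressWarnings(suppressMessages(
      fit_smbpls(list(protein = t(unclass(sim$protein)),
                      psite = t(unclass(sim$psite))),
                 sim$drugs_sauc, n_components = 3,
                 on_oversparse = "truncate")))
    reports <- suppressWarnings(report_clusters(fit, sim$drugs_sauc))
    best_cluster_jaccard(reports, sim$truth$drug_cluster_labels)
  })
  expect_gte(mean(jac), 0.8)
  expect_gte(sum(apply(jac, 2, min) >= 0.8), 2L)  # both clusters in >= 2/3 seeds
})

test_that("marker directions and drug-drug edges are reported per component", {
  sim <- simulate_dataset(small_config(seed = 1))
  fit <- suppressWarnings(suppressMessages(
    fit_smbpls(list(protein = t(unclass(sim$protein)),
                    psite = t(unclass(sim$psite))),
               sim$drugs_sauc, n_components = 2, on_oversparse = "truncate")))
  reports <- suppressWarnings(report_clusters(fit, sim$drugs_sauc))
  cl <- sim$truth$drug_cluster_labels
  for (r in reports) {
    k <- which.max(vapply(1:2, function(k)
      jaccard_index(r$drugs$drug, names(cl)[cl == k]), 0))
    planted <- sim$truth$cluster_marker_sets[[k]]
    found <- r$markers$feature[r$markers$feature %in% planted]
    # planted markers present and labeled sensitivity (all planted signs +)
    expect_gte(length(found), 2L)
    expect_true(all(r$markers$direction[r$markers$feature %in% planted] ==
                      "sensitivity"))
    expect_true(all(r$edges$r >= -1 & r$edges$r <= 1))
  }
  # two drugs with identical sensitivity profiles get edge weight 1
  lines <- sprintf("c%02d", 1:12)
  X <- matrix(rnorm(240), 12, 20,
              dimnames = list(lines, sprintf("f%d", 1:20)))
  y <- X[, 1] + rnorm(12, sd = 0.1)
  Y <- cbind(d1 = y, d2 = y, d3 = X[, 2])
  rownames(Y) <- lines
  fit2 <- fit_smbpls(list(b = X), Y, n_components = 1,
                     lambda_block = 0.3, lambda_y = 0.3)
  rep2 <- report_clusters(fit2, Y)
  edge <- rep2[[1]]$edges
  pair <- edge[edge$drug_a == "d1" & edge$drug_b == "d2", ]
  expect_equal(pair$r, 1, tolerance = 1e-12)
})

test_that("sparsity selection prefers nonzero penalties on sparse truth", {
  # grid of one point behaves as the identity
  set.seed(45)
  X <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("c%02d", 1:20), sprintf("f%d", 1:12)))
  Y <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(rownames(X), sprintf("d%d", 1:3)))
  g0 <- select_sparsity(list(b = X), Y,
                        data.frame(lambda_block = 0, lambda_y = 0),
                        n_components = 1, cv_folds = 3)
  expect_identical(c(g0$lambda_block, g0$lambda_y), c(0, 0))
  # duplicated grid points do not change the choice
  grid <- data.frame(lambda_block = c(0, 0.3, 0.3), lambda_y = c(0, 0.2, 0.2))
  g1 <- select_sparsity(list(b = X), Y, grid, n_components = 1, cv_folds = 3,
                        seed = 5)
  g2 <- select_sparsity(list(b = X), Y, unique(grid), n_components = 1,
                        cv_folds = 3, seed = 5)
  expect_identical(g1[c("lambda_block", "lambda_y")],
                   g2[c("lambda_block", "lambda_y")])
  # with sparse planted structure, penalties beat the dense fit in CV error
  wins <- vapply(1:10, function(s) {
    set.seed(500 + s)
    n <- 30
    Xs <- matrix(rnorm(n * 40), n, 40,
                 dimnames = list(sprintf("c%02d", 1:n), sprintf("f%d", 1:40)))
    f <- rowMeans(Xs[, 1:3])
    Ys <- sapply(1:4, function(d) f + rnorm(n, sd = 0.6))
    dimnames(Ys) <- list(rownames(Xs), sprintf("d%d", 1:4))
    sel <- select_sparsity(list(b = Xs), Ys,
                           data.frame(lambda_block = c(0, 0.3),
                                      lambda_y = c(0, 0.2)),
                           n_components = 1, cv_folds = 4, seed = s)
    err <- sel$cv$mean_error
    err[2] < err[1]
  }, TRUE)
  expect_gt(mean(wins), 0.5)
  expect_error(select_sparsity(list(b = X), Y,
                               data.frame(lambda_block = numeric(0),
                                          lambda_y = numeric(0))),
               "empty grid")
})
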