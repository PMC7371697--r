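test_that("correlation screen applies the pairwise-complete rule exactly", {
  lines <- sprintf("c%02d", 1:10)
  X <- matrix(rnorm(20, 7), 2, 10, dimnames = list(c("F6", "F7"), lines))
  X["F6", 7:10] <- NA            # 6 complete pairs with the drug
  X["F7", 8:10] <- NA            # 7 complete pairs
  Y <- matrix(rnorm(10), 1, 10, dimnames = list("D1", lines))
  out <- correlation_screen(im(X), drug_response_matrix(Y), min_n = 7)
  expect_false("F6" %in% out$feature)
  expect_true("F7" %in% out$feature)
  expect_identical(out$n[out$feature == "F7"], 7L)
})

test_that("directions follow the canonical sensitivity orientation", {
  lines <- sprintf("c%02d", 1:12)
  y <- rnorm(12)
  X <- matrix(c(y, -y), 2, 12, byrow = TRUE,
              dimnames = list(c("POS", "NEG"), lines))
  sauc <- drug_response_matrix(matrix(y, 1, 12, dimnames = list("D", lines)),
                               higher_is_sensitive = TRUE)
  out <- correlation_screen(im(X), sauc)
  expect_equal(out$r[out$feature == "POS"], 1, tolerance = 1e-12)
  expect_identical(out$direction[out$feature == "POS"], "sensitivity")
  expect_identical(out$direction[out$feature == "NEG"], "resistance")
  # the same biology encoded GI50-style gives identical output
  gi50 <- drug_response_matrix(matrix(-y, 1, 12, dimnames = list("D", lines)),
                               higher_is_sensitive = FALSE)
  out2 <- correlation_screen(im(X), gi50)
  expect_equal(out$r, out2$r, tolerance = 1e-12)
  expect_identical(out$direction, out2$direction)
})

test_that("planted negative markers screen as resistance markers", {
  sim <- simulate_dataset(sim_config(seed = 1))
  out <- correlation_screen(sim$protein, sim$drugs_sauc)
  neg <- do.call(rbind, lapply(names(sim$truth$marker_map), function(d) {
    mk <- sim$truth$marker_map[[d]]
    mk <- mk[mk$sign < 0, , drop = FALSE]
    if (nrow(mk)) data.frame(drug = d, feature = mk$feature)
  }))
  hits <- merge(neg, out, by = c("drug", "feature"))
  expect_gte(nrow(hits), nrow(neg) * 0.9)
  expect_true(all(hits$direction == "resistance"))
  expect_true(all(hits$q[hits$r < -0.5] < 0.05))
})

test_that("elastic-net marker frequencies surface the common marker first", {
  firsts <- vapply(1:3, function(s) {
    sim <- simulate_dataset(sim_config(seed = s))
    em <- suppressWarnings(enet_markers(sim$protein, sim$drugs_sauc, seed = s))
    fr <- em$frequency[order(-em$frequency$sensitivity_count,
                             em$frequency$feature), ]
    fr$feature[1] == sim$truth$common_marker
  }, TRUE)
  expect_gte(sum(firsts), 2L)
  # degenerate constant responses are skipped with the drug named
  lines <- sprintf("c%02d", 1:30)
  X <- matrix(rnorm(600, 7), 20, 30,
              dimnames = list(sprintf("F%02d", 1:20), lines))
  Y <- matrix(1, 1, 30, dimnames = list("FLAT", lines))
  expect_error(suppressWarnings(
    enet_markers(im(X), drug_response_matrix(Y), min_lines = 20)),
    "no drug")
})

test_that("the penalty-free limit reproduces least squares and the orthonormal
           design soft-thresholds", {
  set.seed(3)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4)
  beta <- c(1.5, -2, 0.5, 0)
  y <- X %*% beta + rnorm(n, sd = 0.01)
  g0 <- glmnet::glmnet(X, y, alpha = 0.5, lambda = 0, standardize = FALSE,
                       intercept = TRUE, thresh = 1e-12)
  ols <- stats::lm(y ~ X)
  expect_equal(as.numeric(stats::coef(g0))[-1], unname(stats::coef(ols))[-1],
               tolerance = 1e-4)
  # orthonormal columns (X'X/n = I), alpha = 1: soft-thresholded OLS
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)
  yq <- Q %*% c(2, -1, 0.5)
  lam <- 0.8
  g1 <- glmnet::glmnet(Q, yq, alpha = 1, lambda = lam, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-12)
  expect_equal(as.numeric(stats::coef(g1))[-1],
               unname(soft_threshold(as.numeric(crossprod(Q, yq) / n), lam)),
               tolerance = 1e-6)
  # coefficients vanish as the penalty grows
  path <- glmnet::glmnet(X, y, alpha = 0.5, standardize = FALSE)
  expect_true(all(abs(path$beta[, 1]) <= 1e-12))
})

test_that("subset enumeration counts match the combinatorics", {
  panel14 <- sprintf("P%02d", 1:14)
  expect_equal(length(enumerate_subsets(panel14, 3:7)),
               sum(choose(14, 3:7)))  # 9802
  expect_identical(length(enumerate_subsets(sprintf("P%d", 1:3), 3)), 1L)
  expect_error(enumerate_subsets(sprintf("P%d", 1:3), 3:4), "exceed")
})

test_that("random-forest subset models find near-deterministic predictors", {
  set.seed(40)
  lines <- sprintf("c%02d", 1:48)
  X <- matrix(rnorm(240, 7, 1), 5, 48,
              dimnames = list(sprintf("P%d", 1:5), lines))
  y <- stats::setNames(as.numeric(X["P2", ]), lines)  # response = one feature
  res <- rf_subset_models(im(X), y, sizes = 3, cv_folds = 5, n_trees = 80,
                          seed = 2)
  with_p2 <- grepl("P2", res$models$subset)
  expect_gte(min(res$models$cv_r[with_p2]), 0.95)
  expect_equal(nrow(res$models), choose(5, 3))
  # reproducible given the seed
  res2 <- rf_subset_models(im(X), y, sizes = 3, cv_folds = 5, n_trees = 80,
                           seed = 2)
  expect_identical(res$models, res2$models)
  # holdout evaluation runs on unseen cell lines
  ho <- stats::setNames(rnorm(5, mean(y), stats::sd(y)), lines[1:5])
  res3 <- rf_subset_models(im(X[, 6:48]), y[6:48], sizes = 3, cv_folds = 3,
                           n_trees = 50, holdout = ho, seed = 1)
  expect_true("holdout_r" %in% names(res3$top))
  expect_error(rf_subset_models(im(X), y, sizes = 3:7), "exceed")
})

test_that("the regulatory-site screen is the restriction of the full screen", {
  sim <- simulate_dataset(small_config(seed = 6))
  ann <- sim$annotation
  out <- regulatory_site_screen(sim$psite, sim$drugs_sauc, ann)
  expect_true(all(out$reg_class %in% c("activating", "inhibitory")))
  keep <- ann$psite[ann$reg_class != "unknown"]
  sub <- intensity_matrix(unclass(sim$psite)[intersect(rownames(sim$psite), keep), ],
                          "psite")
  full <- correlation_screen(sub, sim$drugs_sauc)
  expect_equal(out[names(full)], full, tolerance = 1e-12)
  ann0 <- ann; ann0$reg_class <- "unknown"
  expect_error(regulatory_site_screen(sim$psite, sim$drugs_sauc, ann0),
               "no regulatory")
})
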