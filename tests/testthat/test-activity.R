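test_that("single-member pathways min-max rescale the feature itself", {
  m <- im(matrix(c(6.0, 6.5, 7.0, 5, 5, 5), 2, 3, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("c1", "c2", "c3"))))
  act <- pathway_activity(m, NULL, list(P = "A"), min_members = 1)
  expect_equal(unname(act$relative["P", ]), c(0, 0.5, 1))
  flat <- pathway_activity(m, NULL, list(P = "B"), min_members = 1)
  expect_true(flat$flat[["P"]])
  expect_true(all(is.na(flat$relative["P", ])))
})

test_that("relative activity spans [0,1] and is invariant to per-feature affine maps", {
  sim <- simulate_dataset(small_config(seed = 2))
  act <- suppressWarnings(pathway_activity(sim$protein, sim$psite,
                                           sim$pathways, sim$annotation))
  rng <- t(apply(act$relative[!act$flat, , drop = FALSE], 1, range))
  expect_equal(unname(rng[, 1]), rep(0, nrow(rng)))
  expect_equal(unname(rng[, 2]), rep(1, nrow(rng)))
  # z-scoring makes activity invariant to positive per-feature affine maps
  a <- runif(nrow(sim$protein), 0.5, 2)
  b <- rnorm(nrow(sim$protein))
  scaled <- intensity_matrix(unclass(sim$protein) * a + b, "protein")
  act2 <- suppressWarnings(pathway_activity(scaled, sim$psite,
                                            sim$pathways, sim$annotation))
  expect_equal(act2$relative, act$relative, tolerance = 1e-9)
})

test_that("the planted active pathway peaks in its tissue group", {
  sim <- simulate_dataset(sim_config(seed = 1))
  act <- suppressWarnings(pathway_activity(median_center(sim$protein),
                                           median_center(sim$psite),
                                           sim$pathways, sim$annotation))
  rel <- act$relative["PW1", ]
  top <- names(sort(rel, decreasing = TRUE))[seq_along(sim$truth$pathway_active$cell_lines)]
  expect_setequal(top, sim$truth$pathway_active$cell_lines)
})

test_that("pathways with too few members are dropped with a warning", {
  m <- im(matrix(rnorm(20, 7), 4, 5))
  expect_warning(
    act <- pathway_activity(m, NULL, list(big = rownames(m), tiny = "F01")),
    "tiny")
  expect_identical(rownames(act$relative), "big")
  expect_error(pathway_activity(m, NULL, list()), "empty")
})

test_that("kinase activity combines available channels and respects classes", {
  lines <- sprintf("c%02d", 1:10)
  prot <- im(matrix(rnorm(10, 7), 1, 10, dimnames = list("OTHER", lines)))
  psite <- im(matrix(rnorm(30, 7), 3, 10,
                     dimnames = list(c("S1_pS10", "S2_pS20", "S3_pS30"), lines)),
              kind = "psite")
  ann <- psite_annotation(rownames(psite), c("S1", "S2", "S3"),
                          rep("S", 3), c(10, 20, 30))
  # only the substrate channel exists -> combined equals substrate mean z
  act <- kinase_activity(prot, psite, list(KINX = rownames(psite)), ann)
  expect_identical(unname(act$provenance["KINX"]), "substrates")
  z <- t(scale(t(unclass(psite))))
  expect_equal(unname(act$raw["KINX", ]), unname(colMeans(z)), tolerance = 1e-9)
  # an inhibitory substrate enters with negated z
  ann2 <- ann; ann2$reg_class <- c("unknown", "unknown", "inhibitory")
  act2 <- kinase_activity(prot, psite, list(KINX = rownames(psite)), ann2)
  z2 <- z; z2[3, ] <- -z2[3, ]
  expect_equal(unname(act2$raw["KINX", ]), unname(colMeans(z2)), tolerance = 1e-9)
  # flat channels are flagged; kinases with no channel are dropped
  flatp <- im(matrix(7, 2, 10, dimnames = list(c("K_pS1", "K_pS2"), lines)),
              kind = "psite")
  annf <- psite_annotation(rownames(flatp), c("K", "K"), c("S", "S"), 1:2)
  actf <- kinase_activity(prot, flatp, list(K = character(0)), annf)
  expect_true(actf$flat[["K"]])
  expect_warning(
    kinase_activity(prot, psite, list(KINX = rownames(psite), GHOST = "nope_pS1"), ann),
    "GHOST")
})

test_that("planted active kinases reach relative 1 and lead their waterfall", {
  sim <- simulate_dataset(sim_config(seed = 3))
  act <- kinase_activity(median_center(sim$protein), median_center(sim$psite),
                         sim$kinase_substrates, sim$annotation)
  for (k in names(sim$truth$active_kinase_lines)) {
    cl <- sim$truth$active_kinase_lines[[k]]
    expect_equal(act$relative[k, cl], 1)
    wf <- waterfall(act, cl)
    expect_lte(match(k, wf$entity), 3L)
  }
})

test_that("waterfall sorts by relative score with lexicographic ties", {
  rel <- matrix(c(0.2, 0.9, 0.9, 0.1), 4, 1,
                dimnames = list(c("Z", "B", "A", "C"), "c1"))
  am <- structure(list(raw = rel, relative = rel,
                       flat = stats::setNames(rep(FALSE, 4), rownames(rel))),
                  class = "activity_matrix")
  wf <- waterfall(am, "c1")
  expect_identical(wf$entity, c("A", "B", "Z", "C"))
  expect_error(waterfall(am, "nope"), "unknown cell line")
})

test_that("landscapes place maxima at high-activity cell lines", {
  lines <- sprintf("c%02d", 1:6)
  rel <- matrix(0, 2, 6, dimnames = list(c("e1", "e2"), lines))
  rel["e1", "c01"] <- 1
  rel["e2", ] <- 0.5
  raw <- rel
  am <- structure(list(raw = raw, relative = rel,
                       flat = c(e1 = FALSE, e2 = FALSE)),
                  class = "activity_matrix")
  ls <- build_landscape(am, grid = 15, bandwidth = 10)
  # with a huge bandwidth the e1 surface peaks nearest c01's position
  h <- ls$heights$e1
  peak <- which(h == max(h), arr.ind = TRUE)[1, ]
  gx <- ls$grid_x[peak[1]]; gy <- ls$grid_y[peak[2]]
  d_all <- sqrt((ls$coordinates[, 1] - gx)^2 + (ls$coordinates[, 2] - gy)^2)
  expect_identical(names(which.min(d_all)), "c01")
  expect_true(all(abs(ls$heights$e2 - 0.5) < 1e-9))
  expect_true(all(unlist(ls$heights) >= 0 & unlist(ls$heights) <= 1))
  # deterministic given the inputs
  ls2 <- build_landscape(am, grid = 15, bandwidth = 10)
  expect_identical(ls$coordinates, ls2$coordinates)
  expect_identical(ls$heights, ls2$heights)
  expect_error(build_landscape(am2 <- structure(list(
    raw = raw[, 1:2], relative = rel[, 1:2], flat = c(e1 = FALSE, e2 = FALSE)),
    class = "activity_matrix"), grid = 5), ">= 3")
})

test_that("complementary activity groups form two separated maxima regions", {
  lines <- sprintf("c%02d", 1:12)
  set.seed(6)
  rel <- rbind(e1 = c(rep(0.95, 6), rep(0.05, 6)) + runif(12, 0, 0.05),
               e2 = c(rep(0.05, 6), rep(0.95, 6)) + runif(12, 0, 0.05))
  colnames(rel) <- lines
  am <- structure(list(raw = rel, relative = rel,
                       flat = c(e1 = FALSE, e2 = FALSE)),
                  class = "activity_matrix")
  ls <- build_landscape(am, grid = 21)
  peak_of <- function(e) {
    h <- ls$heights[[e]]
    p <- which(h == max(h), arr.ind = TRUE)[1, ]
    c(ls$grid_x[p[1]], ls$grid_y[p[2]])
  }
  p1 <- peak_of("e1"); p2 <- peak_of("e2")
  nearest <- function(p) names(which.min(
    sqrt((ls$coordinates[, 1] - p[1])^2 + (ls$coordinates[, 2] - p[2])^2)))
  expect_true(nearest(p1) %in% lines[1:6])
  expect_true(nearest(p2) %in% lines[7:12])
})
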