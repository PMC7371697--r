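#' Simulation configuration
#'
#' Parameters of the synthetic NCI60/CRC65-like panel generator. All
#' intensities are simulated directly on the log10 scale (arbitrary units);
#' the linear-scale value of an entry x is 10^x. Defaults describe a
#' desk-scale panel of 60 cell lines in 6 tissue groups with planted
#' correlation modules, a planted active pathway and active kinases, planted
#' single-cell-line outliers, planted linear drug markers, two planted drug
#' clusters sharing marker sets, and an MSI-like binary phenotype with a
#' differential module.
#'
#' @param n_cell_lines,n_proteins,n_psites panel dimensions.
#' @param n_tissue_groups number of tissue-of-origin groups (cell lines are
#'   split as evenly as possible).
#' @param tissue_shift_sd sd (log10 units) of per-feature tissue-group shifts.
#' @param noise_sd sd (log10 units) of per-entry measurement noise.
#' @param baseline_mean,baseline_sd feature baseline abundance distribution
#'   (log10 units).
#' @param missing_midpoint,missing_steepness logistic MNAR parameters: the
#'   probability that an entry with true log10 intensity x is missing is
#'   plogis(missing_steepness * (missing_midpoint - x)). A midpoint of -Inf
#'   disables missingness.
#' @param n_pathways,pathway_size pathway collection shape; pathway 1 is the
#'   planted active pathway (members shifted by `activity_shift` in tissue
#'   group 1), pathway 2 annotates the differential module.
#' @param n_kinases,substrates_per_kinase kinase-substrate map shape; every
#'   kinase is planted active in one distinct cell line (its protein, its own
#'   p-sites and its substrate sites are shifted by `activity_shift` there).
#' @param activity_shift log10 shift of planted pathway/kinase activity.
#' @param n_outliers,outlier_shift count and log10 excess of planted
#'   single-cell-line outlier p-sites.
#' @param n_drugs,n_planted_markers_per_drug,marker_effect drug panel shape;
#'   sensitivity = marker_effect * mean(signed marker z-scores) + noise.
#' @param n_drug_clusters planted drug clusters (6 drugs each, sharing one
#'   marker set); remaining drugs share one common sensitivity marker plus
#'   private markers.
#' @param phenotype_fraction fraction of cell lines positive for the binary
#'   (MSI-like) phenotype.
#' @param n_differential_features,differential_shift size and log10 shift of
#'   the planted phenotype-differential module.
#' @param seed master seed; each output block draws from its own derived RNG
#'   stream so adding outputs never perturbs existing ones.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cell_lines = 60L, n_proteins = 300L, n_psites = 400L,
                       n_tissue_groups = 6L, tissue_shift_sd = 0.1,
                       noise_sd = 0.12, baseline_mean = 7.0, baseline_sd = 0.8,
                       missing_midpoint = 5.5, missing_steepness = 4.0,
                       n_pathways = 8L, pathway_size = 15L, n_kinases = 6L,
                       substrates_per_kinase = 10L, activity_shift = 1.0,
                       n_outliers = 10L, outlier_shift = 1.0, n_drugs = 24L,
                       n_planted_markers_per_drug = 3L, marker_effect = 1.0,
                       n_drug_clusters = 2L, phenotype_fraction = 0.25,
                       n_differential_features = 20L, differential_shift = 0.5,
                       seed = 1L) {
  cfg <- list(n_cell_lines = as.integer(n_cell_lines),
              n_proteins = as.integer(n_proteins),
              n_psites = as.integer(n_psites),
              n_tissue_groups = as.integer(n_tissue_groups),
              tissue_shift_sd = tissue_shift_sd, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              missing_midpoint = missing_midpoint,
              missing_steepness = missing_steepness,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_kinases = as.integer(n_kinases),
              substrates_per_kinase = as.integer(substrates_per_kinase),
              activity_shift = activity_shift,
              n_outliers = as.integer(n_outliers),
              outlier_shift = outlier_shift, n_drugs = as.integer(n_drugs),
              n_planted_markers_per_drug = as.integer(n_planted_markers_per_drug),
              marker_effect = marker_effect,
              n_drug_clusters = as.integer(n_drug_clusters),
              phenotype_fraction = phenotype_fraction,
              n_differential_features = as.integer(n_differential_features),
              differential_shift = differential_shift, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

sim_fail <- function(field, why) {
  stop(sprintf("sim_config: invalid '%s' (%s)", field, why), call. = FALSE)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_cell_lines", "n_proteins", "n_psites", "n_tissue_groups",
              "n_pathways", "pathway_size", "n_kinases",
              "substrates_per_kinase", "n_drugs", "n_planted_markers_per_drug")
  for (f in counts) if (cfg[[f]] < 1L) sim_fail(f, "count must be >= 1")
  for (f in c("n_outliers", "n_drug_clusters", "n_differential_features"))
    if (cfg[[f]] < 0L) sim_fail(f, "count must be >= 0")
  if (cfg$phenotype_fraction <= 0 || cfg$phenotype_fraction >= 1)
    sim_fail("phenotype_fraction", "fraction must be in (0,1)")
  if (cfg$pathway_size > cfg$n_proteins)
    sim_fail("pathway_size", "exceeds n_proteins")
  if (cfg$substrates_per_kinase > cfg$n_psites)
    sim_fail("substrates_per_kinase", "exceeds n_psites")
  if (cfg$n_kinases > cfg$n_cell_lines)
    sim_fail("n_kinases", "more kinases than cell lines to plant them in")
  if (cfg$n_tissue_groups > cfg$n_cell_lines)
    sim_fail("n_tissue_groups", "exceeds n_cell_lines")
  if (cfg$n_drug_clusters > 2L)
    sim_fail("n_drug_clusters", "at most 2 planted drug clusters are supported")
  alloc <- tryCatch(sim_allocation(cfg), error = function(e) stop(e))
  invisible(cfg)
}

# Fixed internal design constants of the stated synthetic world (documented
# in the methods vignette): planted correlation blocks and drug-response
# noise are not config dials.
SIM_BLOCK_SIZE <- 20L      # features per planted correlation module
SIM_BLOCK_LOADING <- 0.15  # log10 loading of the module latent factor
SIM_BLOCK_NOISE <- 0.05    # residual noise sd of module member features
SIM_DRUG_NOISE <- 0.5      # sd of drug-sensitivity noise (z units)
SIM_DRUG_MISSING <- 0.1    # MCAR fraction of unmeasured drug/line pairs
SIM_CLUSTER_SIZE <- 6L     # drugs per planted cluster (capped by n_drugs)
SIM_PLANT_BASELINE <- 7.5  # baseline mean of planted-role features
SIM_PLANT_BASELINE_SD <- 0.3

# Deterministic partition of feature indices into planted roles.
sim_allocation <- function(cfg) {
  cluster_size <- max(2L, min(SIM_CLUSTER_SIZE,
                              cfg$n_drugs %/% max(1L, cfg$n_drug_clusters)))
  n_cluster_drugs <- cfg$n_drug_clusters * cluster_size
  if (n_cluster_drugs > cfg$n_drugs)
    sim_fail("n_drug_clusters", "clusters need more drugs than n_drugs")
  n_generic <- cfg$n_drugs - n_cluster_drugs
  m <- cfg$n_planted_markers_per_drug
  n_prot_markers <- (if (n_generic > 0L) 1L + n_generic * (m - 1L) else 0L) +
    (if (cfg$n_drug_clusters >= 1L) m else 0L)
  take <- function(n, from) if (n == 0L) integer(0) else seq.int(from, length.out = n)
  p <- list()
  at <- 1L
  p$block_a <- take(min(SIM_BLOCK_SIZE, cfg$n_proteins %/% 4L), at); at <- at + length(p$block_a)
  p$diff <- take(cfg$n_differential_features, at); at <- at + length(p$diff)
  p$pathway1 <- take(cfg$pathway_size, at); at <- at + length(p$pathway1)
  p$kinase_prot <- take(cfg$n_kinases, at); at <- at + length(p$kinase_prot)
  p$prot_markers <- take(n_prot_markers, at); at <- at + length(p$prot_markers)
  if (at - 1L > cfg$n_proteins)
    sim_fail("n_proteins", sprintf("too small for planted structure (needs >= %d)", at - 1L))
  p$prot_background <- seq.int(at, cfg$n_proteins)

  s <- list()
  at <- 1L
  s$block_b <- take(min(SIM_BLOCK_SIZE, cfg$n_psites %/% 4L), at); at <- at + length(s$block_b)
  s$kinase_sites <- take(2L * cfg$n_kinases, at); at <- at + length(s$kinase_sites)
  s$substrates <- take(cfg$n_kinases * cfg$substrates_per_kinase, at)
  at <- at + length(s$substrates)
  n_psite_markers <- if (cfg$n_drug_clusters >= 2L) m else 0L
  s$psite_markers <- take(n_psite_markers, at); at <- at + length(s$psite_markers)
  s$outlier_carriers <- take(cfg$n_outliers, at); at <- at + length(s$outlier_carriers)
  if (at - 1L > cfg$n_psites)
    sim_fail("n_psites", sprintf("too small for planted structure (needs >= %d)", at - 1L))
  s$psite_background <- seq.int(at, cfg$n_psites)
  list(protein = p, psite = s, cluster_size = cluster_size,
       n_generic = n_generic)
}

rtruncnorm2 <- function(n) {
  stats::qnorm(stats::runif(n, stats::pnorm(-2), stats::pnorm(2)))
}

#' Generate a synthetic panel dataset
#'
#' Produces every input of the analysis pipeline together with a ground-truth
#' record of all planted structure. Matrices are on the log10 scale with
#' intensity-dependent (logistic MNAR) missingness; planted shifts are applied
#' before missingness (high values are preferentially observed), while
#' single-cell-line outliers are injected afterwards at
#' `median(observed others) + outlier_shift` so the planted excess is exact in
#' the emitted matrix.
#'
#' @param config a [sim_config()].
#' @return list with elements `protein`, `psite` ([intensity_matrix()]s),
#'   `pathways`, `kinase_substrates` (GMT-style lists), `annotation`
#'   ([psite_annotation()]), `drugs_sauc`, `drugs_gi50`
#'   ([drug_response_matrix()]s in both orientations), `phenotype` (named
#'   logical), `truth` (ground-truth list) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  al <- sim_allocation(cfg)
  nC <- cfg$n_cell_lines
  cell_lines <- sprintf("CL%02d", seq_len(nC))
  tissue <- rep(seq_len(cfg$n_tissue_groups), length.out = nC)
  tissue <- sort(tissue)
  names(tissue) <- cell_lines

  prot_ids <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
  prot_ids[al$protein$kinase_prot] <- sprintf("KIN%d", seq_len(cfg$n_kinases))

  ## stream 1: combinatorial structure -------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  # p-site identities: each site lives on a protein group
  site_gene <- character(cfg$n_psites)
  site_gene[al$psite$kinase_sites] <-
    rep(prot_ids[al$protein$kinase_prot], each = 2L)
  host_pool <- prot_ids[al$protein$prot_background]
  if (!length(host_pool)) host_pool <- prot_ids
  other <- setdiff(seq_len(cfg$n_psites), al$psite$kinase_sites)
  site_gene[other] <- sample(host_pool, length(other), replace = TRUE)
  residue <- sample(c("S", "T", "Y"), cfg$n_psites, replace = TRUE,
                    prob = c(0.75, 0.15, 0.10))
  residue[al$psite$kinase_sites] <- "Y"
  # unique positions within each host gene
  position <- integer(cfg$n_psites)
  for (g in unique(site_gene)) {
    idx <- which(site_gene == g)
    position[idx] <- sample(10:999, length(idx))
  }
  psite_ids <- sprintf("%s_p%s%d", site_gene, residue, position)
  reg_class <- rep("unknown", cfg$n_psites)
  reg_class[al$psite$kinase_sites] <- "activating"
  bg <- al$psite$psite_background
  reg_class[bg] <- sample(c("unknown", "activating", "inhibitory"),
                          length(bg), replace = TRUE, prob = c(0.85, 0.1, 0.05))

  # pathways: 1 = planted active, 2 = differential-module annotation,
  # rest random background sets
  pathways <- list()
  if (cfg$n_pathways >= 1L)
    pathways[["PW1"]] <- prot_ids[al$protein$pathway1]
  if (cfg$n_pathways >= 2L && length(al$protein$diff))
    pathways[["PW2"]] <-
      prot_ids[al$protein$diff[seq_len(min(cfg$pathway_size, length(al$protein$diff)))]]
  if (cfg$n_pathways >= 3L) {
    for (k in 3:cfg$n_pathways) {
      pool <- prot_ids[al$protein$prot_background]
      pathways[[sprintf("PW%d", k)]] <-
        sample(pool, min(cfg$pathway_size, length(pool)))
    }
  }
  # kinase -> substrate-site map
  kin_ids <- prot_ids[al$protein$kinase_prot]
  kinase_substrates <- lapply(seq_len(cfg$n_kinases), function(k) {
    idx <- al$psite$substrates[seq.int((k - 1L) * cfg$substrates_per_kinase + 1L,
                                       length.out = cfg$substrates_per_kinase)]
    psite_ids[idx]
  })
  names(kinase_substrates) <- kin_ids
  active_line <- sample(nC, cfg$n_kinases)
  names(active_line) <- kin_ids
  # drugs: clusters first, then generic drugs sharing one common marker
  drug_ids <- sprintf("DRUG%02d", seq_len(cfg$n_drugs))
  cluster_labels <- integer(cfg$n_drugs)
  if (cfg$n_drug_clusters > 0L)
    cluster_labels[seq_len(cfg$n_drug_clusters * al$cluster_size)] <-
      rep(seq_len(cfg$n_drug_clusters), each = al$cluster_size)
  names(cluster_labels) <- drug_ids

  m <- cfg$n_planted_markers_per_drug
  pm <- prot_ids[al$protein$prot_markers]
  common_marker <- if (al$n_generic > 0L) pm[1L] else NA_character_
  marker_map <- vector("list", cfg$n_drugs)
  names(marker_map) <- drug_ids
  next_pm <- if (al$n_generic > 0L) 2L else 1L
  cluster_marker_sets <- list()
  if (cfg$n_drug_clusters >= 1L) {
    cluster_marker_sets[[1L]] <- pm[seq.int(next_pm, length.out = m)]
    next_pm <- next_pm + m
  }
  if (cfg$n_drug_clusters >= 2L) {
    for (k in 2:cfg$n_drug_clusters) {
      # second and later clusters draw markers from the p-site block so the
      # multiblock model has to use both blocks
      cluster_marker_sets[[k]] <- if (k == 2L && length(al$psite$psite_markers))
        psite_ids[al$psite$psite_markers]
      else pm[seq.int(next_pm, length.out = 0L)]
    }
  }
  for (d in seq_len(cfg$n_drugs)) {
    cl <- cluster_labels[d]
    if (cl > 0L) {
      set <- cluster_marker_sets[[cl]]
      marker_map[[d]] <- data.frame(feature = set, sign = 1,
                                    stringsAsFactors = FALSE)
    } else {
      own <- pm[seq.int(next_pm, length.out = m - 1L)]
      next_pm <- next_pm + (m - 1L)
      signs <- c(1, rep_len(c(1, -1), m - 1L))
      marker_map[[d]] <- data.frame(feature = c(common_marker, own),
                                    sign = signs, stringsAsFactors = FALSE)
    }
  }

  ## stream 2: baselines ----------------------------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  base_p <- stats::rnorm(cfg$n_proteins, cfg$baseline_mean, cfg$baseline_sd)
  base_s <- stats::rnorm(cfg$n_psites, cfg$baseline_mean, cfg$baseline_sd)
  planted_p <- c(al$protein$pathway1, al$protein$kinase_prot,
                 al$protein$prot_markers)
  planted_s <- c(al$psite$kinase_sites, al$psite$substrates,
                 al$psite$psite_markers, al$psite$outlier_carriers)
  base_p[planted_p] <- stats::rnorm(length(planted_p), SIM_PLANT_BASELINE,
                                    SIM_PLANT_BASELINE_SD)
  base_s[planted_s] <- stats::rnorm(length(planted_s), SIM_PLANT_BASELINE,
                                    SIM_PLANT_BASELINE_SD)

  ## stream 3: tissue-group covariance --------------------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  tshift_p <- matrix(stats::rnorm(cfg$n_proteins * cfg$n_tissue_groups,
                                  0, cfg$tissue_shift_sd),
                     cfg$n_proteins, cfg$n_tissue_groups)
  tshift_s <- matrix(stats::rnorm(cfg$n_psites * cfg$n_tissue_groups,
                                  0, cfg$tissue_shift_sd),
                     cfg$n_psites, cfg$n_tissue_groups)
  # planted correlation modules are defined purely by their latent factor
  tshift_p[c(al$protein$block_a, al$protein$diff), ] <- 0
  tshift_s[al$psite$block_b, ] <- 0

  ## stream 4: module latent factors ----------------------------------------
  set.seed(derive_seed(cfg$seed, 4L))
  fac_a <- rtruncnorm2(nC)
  fac_b <- rtruncnorm2(nC)
  fac_d <- rtruncnorm2(nC)

  ## stream 5: measurement noise --------------------------------------------
  set.seed(derive_seed(cfg$seed, 5L))
  noise_p <- matrix(stats::rnorm(cfg$n_proteins * nC, 0, cfg$noise_sd),
                    cfg$n_proteins, nC)
  noise_s <- matrix(stats::rnorm(cfg$n_psites * nC, 0, cfg$noise_sd),
                    cfg$n_psites, nC)
  mod_p <- c(al$protein$block_a, al$protein$diff)
  noise_p[mod_p, ] <- matrix(stats::rnorm(length(mod_p) * nC, 0, SIM_BLOCK_NOISE),
                             length(mod_p), nC)
  noise_s[al$psite$block_b, ] <-
    matrix(stats::rnorm(length(al$psite$block_b) * nC, 0, SIM_BLOCK_NOISE),
           length(al$psite$block_b), nC)

  ## stream 7: phenotype ------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 7L))
  n_pos <- max(1L, floor(cfg$phenotype_fraction * nC))
  phenotype <- stats::setNames(rep(FALSE, nC), cell_lines)
  phenotype[sample(nC, n_pos)] <- TRUE

  ## assemble true matrices ---------------------------------------------------
  X_p <- base_p + tshift_p[, tissue] + noise_p
  X_s <- base_s + tshift_s[, tissue] + noise_s
  X_p[al$protein$block_a, ] <- X_p[al$protein$block_a, , drop = FALSE] +
    SIM_BLOCK_LOADING * rep(fac_a, each = length(al$protein$block_a))
  X_s[al$psite$block_b, ] <- X_s[al$psite$block_b, , drop = FALSE] +
    SIM_BLOCK_LOADING * rep(fac_b, each = length(al$psite$block_b))
  if (length(al$protein$diff)) {
    X_p[al$protein$diff, ] <- X_p[al$protein$diff, , drop = FALSE] +
      SIM_BLOCK_LOADING * rep(fac_d, each = length(al$protein$diff)) +
      cfg$differential_shift * rep(as.numeric(phenotype), each = length(al$protein$diff))
  }
  # planted pathway activity: tissue group 1 shifted on all members
  grp1 <- which(tissue == 1L)
  X_p[al$protein$pathway1, grp1] <-
    X_p[al$protein$pathway1, grp1, drop = FALSE] + cfg$activity_shift
  # planted kinase activity: protein, own sites and substrate sites shifted
  # in the kinase's active cell line
  elevated <- list()
  for (k in seq_len(cfg$n_kinases)) {
    ln <- active_line[k]
    own <- al$psite$kinase_sites[c(2L * k - 1L, 2L * k)]
    sub <- al$psite$substrates[seq.int((k - 1L) * cfg$substrates_per_kinase + 1L,
                                       length.out = cfg$substrates_per_kinase)]
    X_p[al$protein$kinase_prot[k], ln] <-
      X_p[al$protein$kinase_prot[k], ln] + cfg$activity_shift
    X_s[c(own, sub), ln] <- X_s[c(own, sub), ln] + cfg$activity_shift
    elevated[[k]] <- data.frame(feature = psite_ids[c(own, sub)],
                                cell_line = cell_lines[ln],
                                shift = cfg$activity_shift,
                                stringsAsFactors = FALSE)
  }
  rownames(X_p) <- prot_ids; colnames(X_p) <- cell_lines
  rownames(X_s) <- psite_ids; colnames(X_s) <- cell_lines

  ## stream 6: drug responses (uses true, pre-missingness feature values) ----
  set.seed(derive_seed(cfg$seed, 6L))
  zp <- row_zscore(X_p)
  zs <- row_zscore(X_s)
  Y <- matrix(NA_real_, cfg$n_drugs, nC, dimnames = list(drug_ids, cell_lines))
  for (d in seq_len(cfg$n_drugs)) {
    mk <- marker_map[[d]]
    zmat <- rbind(zp[intersect(mk$feature, prot_ids), , drop = FALSE],
                  zs[intersect(mk$feature, psite_ids), , drop = FALSE])
    zmat <- zmat[mk$feature, , drop = FALSE]
    Y[d, ] <- cfg$marker_effect * colMeans(mk$sign * zmat) +
      stats::rnorm(nC, 0, SIM_DRUG_NOISE)
  }
  drug_na <- matrix(stats::runif(length(Y)) < SIM_DRUG_MISSING, nrow(Y), ncol(Y))
  Y[drug_na] <- NA_real_

  ## stream 8: MNAR missingness ----------------------------------------------
  set.seed(derive_seed(cfg$seed, 8L))
  p_miss <- function(x) stats::plogis(cfg$missing_steepness * (cfg$missing_midpoint - x))
  X_p[matrix(stats::runif(length(X_p)), nrow(X_p)) < p_miss(X_p)] <- NA_real_
  X_s[matrix(stats::runif(length(X_s)), nrow(X_s)) < p_miss(X_s)] <- NA_real_

  ## stream 9: outliers (injected last; exact excess in the emitted matrix) --
  set.seed(derive_seed(cfg$seed, 9L))
  outlier_positions <- data.frame(feature = character(0),
                                  cell_line = character(0),
                                  stringsAsFactors = FALSE)
  if (cfg$n_outliers > 0L) {
    out_lines <- sample(nC, cfg$n_outliers, replace = TRUE)
    for (i in seq_len(cfg$n_outliers)) {
      f <- al$psite$outlier_carriers[i]
      ln <- out_lines[i]
      others <- X_s[f, -ln]
      ref <- if (all(is.na(others))) base_s[f] else
        stats::median(others, na.rm = TRUE)
      X_s[f, ln] <- ref + cfg$outlier_shift
      outlier_positions <- rbind(outlier_positions,
                                 data.frame(feature = psite_ids[f],
                                            cell_line = cell_lines[ln],
                                            stringsAsFactors = FALSE))
    }
  }
  elevated <- do.call(rbind, c(elevated, list(
    if (nrow(outlier_positions)) cbind(outlier_positions, shift = cfg$outlier_shift))))
  if (is.null(elevated))
    elevated <- data.frame(feature = character(0), cell_line = character(0),
                           shift = numeric(0), stringsAsFactors = FALSE)

  module_labels <- c(
    stats::setNames(rep(1L, length(al$protein$block_a)), prot_ids[al$protein$block_a]),
    stats::setNames(rep(2L, length(al$psite$block_b)), psite_ids[al$psite$block_b]),
    stats::setNames(rep(3L, length(al$protein$diff)), prot_ids[al$protein$diff]))

  annotation <- psite_annotation(psite_ids, site_gene, residue, position, reg_class)

  truth <- list(
    outlier_positions = outlier_positions,
    elevated_positions = elevated,
    active_kinase_lines = stats::setNames(cell_lines[active_line], kin_ids),
    marker_map = marker_map,
    common_marker = common_marker,
    drug_cluster_labels = cluster_labels,
    cluster_marker_sets = cluster_marker_sets,
    differential_features = data.frame(
      feature = prot_ids[al$protein$diff],
      direction = rep("up_in_positive", length(al$protein$diff)),
      stringsAsFactors = FALSE),
    module_labels = module_labels,
    pathway_active = list(pathway = "PW1", tissue_group = 1L,
                          cell_lines = cell_lines[grp1]),
    tissue = tissue)

  list(protein = intensity_matrix(X_p, "protein"),
       psite = intensity_matrix(X_s, "psite"),
       pathways = pathways,
       kinase_substrates = kinase_substrates,
       annotation = annotation,
       drugs_sauc = drug_response_matrix(Y, higher_is_sensitive = TRUE),
       drugs_gi50 = drug_response_matrix(-Y - 6, higher_is_sensitive = FALSE),
       phenotype = phenotype,
       truth = truth,
       config = cfg)
}

#' Write a simulated dataset to a directory
#'
#' Emits protein.tsv, psites.tsv, pathways.gmt, kinase_substrates.gmt,
#' drugs.tsv (sAUC-like), drugs_gi50.tsv, phenotype.tsv, annotation.tsv and
#' truth.json.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_intensity_tsv(sim$protein, file.path(dir, "protein.tsv")),
    write_intensity_tsv(sim$psite, file.path(dir, "psites.tsv")),
    write_gmt(sim$pathways, file.path(dir, "pathways.gmt")),
    write_gmt(sim$kinase_substrates, file.path(dir, "kinase_substrates.gmt")),
    write_drug_tsv(sim$drugs_sauc, file.path(dir, "drugs.tsv")),
    write_annotation_tsv(sim$annotation, file.path(dir, "annotation.tsv")))
  gi50 <- data.frame(drug = rownames(sim$drugs_gi50), -unclass(sim$drugs_gi50),
                     check.names = FALSE)
  utils::write.table(gi50, file.path(dir, "drugs_gi50.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ph <- data.frame(cell_line = names(sim$phenotype),
                   phenotype = ifelse(sim$phenotype, "positive", "negative"))
  utils::write.table(ph, file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, c("drugs_gi50.tsv", "phenotype.tsv",
                                      "truth.json"))))
}
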