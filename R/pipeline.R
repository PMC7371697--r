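#' @title Config-driven pipeline and command-line interface
#' @description Runs the analysis stages in dependency order (aggregate ->
#'   normalize -> activity / modules / outliers -> associate / smbpls) from a
#'   YAML or JSON configuration, writing every artifact plus a manifest with
#'   checksums, parameters and seeds. Reruns with the same config reproduce
#'   identical checksums.
#' @name phosmarker-pipeline
NULL

#' Read a pipeline configuration
#'
#' YAML (or JSON) with top-level keys: `inputs` (paths: protein, psites,
#' pathways, kinase_substrates, annotation, drugs, phenotype),
#' `drug_orientation` ("sauc" = higher is sensitive, "gi50" = lower is
#' sensitive), `out` (output directory), `seed`, `stages` (named logical
#' toggles: activity, modules, outliers, associate, smbpls), and optional
#' per-stage parameter maps (`params$modules$beta`, ...). Referenced input
#' files must exist at validation time.
#'
#' @param path configuration file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$inputs) || is.null(cfg$out))
    stop("pipeline config: 'inputs' and 'out' are required")
  required <- c("protein", "psites")
  miss <- setdiff(required, names(cfg$inputs))
  if (length(miss)) stop("pipeline config: missing inputs: ",
                         paste(miss, collapse = ", "))
  for (f in names(cfg$inputs)) {
    if (!file.exists(cfg$inputs[[f]]))
      stop("pipeline config: input file not found: ", f, " = ", cfg$inputs[[f]])
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$drug_orientation <- cfg$drug_orientation %||% "sauc"
  defaults <- list(activity = TRUE, modules = TRUE, outliers = TRUE,
                   associate = TRUE, smbpls = TRUE)
  cfg$stages <- utils::modifyList(defaults, as.list(cfg$stages %||% list()))
  cfg$params <- cfg$params %||% list()
  cfg
}

stage_write <- function(obj, path, manifest_env, stage, params = list()) {
  if (file.exists(path)) stop("pipeline: refusing to overwrite ", path)
  if (is.data.frame(obj)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12,
                         pretty = TRUE, force = TRUE)
  }
  manifest_env$files[[length(manifest_env$files) + 1L]] <-
    list(path = basename(path), stage = stage,
         md5 = unname(tools::md5sum(path)), params = params)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' @param config a config list (see [read_pipeline_config()]) or a path to a
#'   YAML/JSON config file.
#' @return the manifest (list), invisibly; also written to
#'   `<out>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  else config <- validate_pipeline_config(config)
  t0 <- Sys.time()
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  man <- new.env()
  man$files <- list()
  log <- list()
  tick <- function(stage, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[stage]] <<- list(seconds = as.numeric(difftime(Sys.time(), st,
                                                        units = "secs")))
    res
  }
  prm <- function(stage) as.list(config$params[[stage]] %||% list())

  ## load ---------------------------------------------------------------
  protein <- tick("load", {
    read_intensity_tsv(config$inputs$protein, kind = "protein")
  })
  psite <- read_intensity_tsv(config$inputs$psites, kind = "psite")
  annotation <- if (!is.null(config$inputs$annotation))
    read_annotation_tsv(config$inputs$annotation) else NULL
  pathways <- if (!is.null(config$inputs$pathways))
    read_gmt(config$inputs$pathways) else NULL
  kin_map <- if (!is.null(config$inputs$kinase_substrates))
    read_gmt(config$inputs$kinase_substrates) else NULL
  drugs <- if (!is.null(config$inputs$drugs))
    read_drug_tsv(config$inputs$drugs,
                  higher_is_sensitive = config$drug_orientation == "sauc") else NULL
  phenotype <- NULL
  if (!is.null(config$inputs$phenotype)) {
    ph <- utils::read.delim(config$inputs$phenotype, stringsAsFactors = FALSE)
    phenotype <- stats::setNames(ph$phenotype == "positive", ph$cell_line)
  }

  ## aggregate + normalize ----------------------------------------------
  phospho <- NULL
  if (!is.null(annotation)) {
    phospho <- tick("aggregate", aggregate_phosphoprotein(psite, annotation))
    stage_write(data.frame(feature = rownames(phospho), unclass(phospho),
                           check.names = FALSE),
                file.path(out, "phosphoprotein.tsv"), man, "aggregate")
  }
  protein_n <- tick("normalize", median_center(protein))
  psite_n <- median_center(psite)
  stage_write(data.frame(feature = rownames(protein_n), unclass(protein_n),
                         check.names = FALSE),
              file.path(out, "protein_normalized.tsv"), man, "normalize")

  ## activity -------------------------------------------------------------
  if (isTRUE(config$stages$activity) && !is.null(pathways)) {
    act <- tick("activity", do.call(pathway_activity, c(
      list(protein = protein_n, psite = psite_n, pathways = pathways,
           annotation = annotation), prm("activity"))))
    stage_write(data.frame(entity = rownames(act$relative), act$relative,
                           check.names = FALSE),
                file.path(out, "pathway_activity.tsv"), man, "activity",
                prm("activity"))
    if (!is.null(kin_map) && !is.null(annotation)) {
      kact <- kinase_activity(protein_n, psite_n, kin_map, annotation)
      stage_write(data.frame(entity = rownames(kact$relative), kact$relative,
                             check.names = FALSE),
                  file.path(out, "kinase_activity.tsv"), man, "activity")
      land <- build_landscape(kact, seed = config$seed)
      stage_write(list(coordinates = as.data.frame(land$coordinates),
                       bandwidth = land$bandwidth),
                  file.path(out, "landscape.json"), man, "activity")
    }
  }

  ## modules --------------------------------------------------------------
  partition <- NULL
  if (isTRUE(config$stages$modules)) {
    combined <- rbind(unclass(protein_n), unclass(psite_n))
    combined <- combined[rowSums(!is.na(combined)) > 0L, , drop = FALSE]
    partition <- tick("modules", do.call(detect_modules,
                                         c(list(mat = combined), prm("modules"))))
    stage_write(data.frame(feature = names(partition$labels),
                           module = unname(partition$labels)),
                file.path(out, "modules.tsv"), man, "modules", prm("modules"))
    if (!is.null(phenotype) && !is.null(pathways) &&
        isTRUE(config$stages$associate)) {
      assoc <- tick("hive", associate_axes(partition, pathways, phenotype,
                                           combined))
      stage_write(assoc$edges, file.path(out, "hive_edges.tsv"), man, "hive")
      cand <- guilt_by_association(assoc, pathways)
      stage_write(cand, file.path(out, "candidates.tsv"), man, "hive")
    }
  }

  ## outliers -------------------------------------------------------------
  if (isTRUE(config$stages$outliers)) {
    calls <- tick("outliers", do.call(call_outliers, c(list(mat = psite),
                                                       prm("outliers"))))
    stage_write(calls, file.path(out, "outliers.tsv"), man, "outliers",
                prm("outliers"))
  }

  ## drug association ------------------------------------------------------
  if (isTRUE(config$stages$associate) && !is.null(drugs)) {
    markers <- tick("associate", do.call(correlation_screen, c(
      list(features = protein, drugs = drugs), prm("associate"))))
    stage_write(markers[!is.na(markers$q) & markers$q < 0.05, ],
                file.path(out, "markers.tsv"), man, "associate",
                prm("associate"))
  }

  ## smbpls ----------------------------------------------------------------
  if (isTRUE(config$stages$smbpls) && !is.null(drugs)) {
    sp <- prm("smbpls")
    model <- tick("smbpls", fit_smbpls(
      blocks = list(protein = t(unclass(protein)), psite = t(unclass(psite))),
      Y = drugs,
      n_components = sp$n_components %||% 5L,
      lambda_block = sp$lambda_block %||% 0.4,
      lambda_y = sp$lambda_y %||% 0.3,
      on_oversparse = "truncate", seed = config$seed))
    reports <- report_clusters(model, drugs)
    clusters <- do.call(rbind, lapply(reports, function(r)
      data.frame(component = r$component, r$drugs)))
    stage_write(clusters, file.path(out, "smbpls_clusters.tsv"), man,
                "smbpls", sp)
    edges <- do.call(rbind, lapply(reports, function(r)
      if (!is.null(r$edges)) data.frame(component = r$component, r$edges)))
    if (!is.null(edges))
      stage_write(edges, file.path(out, "smbpls_edges.tsv"), man, "smbpls")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phosmarker")),
    seed = config$seed,
    config_hash = digest_config(config),
    stages = log,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = man$files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(manifest)
}

digest_config <- function(config) {
  cfg <- config
  cfg$out <- NULL
  unname(tools::md5sum(
    local({
      f <- tempfile()
      writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE), f)
      f
    })))
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR --seed N [--config cfg.yaml]`,
#' `aggregate --psites F --annotation F --out F`,
#' `normalize --in F --kind K --out F`, and `run --config cfg.yaml`.
#' Installed as `inst/cli/phosmarker.R`:
#' `Rscript -e 'phosmarker::run_cli()' <subcommand> ...` or via the wrapper
#' script.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status 0 invisibly on success.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: phosmarker <simulate|aggregate|normalize|run> [options]")
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  switch(cmd,
    simulate = {
      cfg_args <- list()
      if (!is.null(opts$config)) cfg_args <- yaml::read_yaml(opts$config)
      if (!is.null(opts$seed)) cfg_args$seed <- as.integer(opts$seed)
      sim <- simulate_dataset(do.call(sim_config, cfg_args))
      write_dataset(sim, opts$out %||% ".")
      message("simulate: wrote dataset to ", opts$out %||% ".")
    },
    aggregate = {
      ps <- read_intensity_tsv(opts$psites, kind = "psite")
      ann <- read_annotation_tsv(opts$annotation)
      agg <- aggregate_phosphoprotein(ps, ann)
      write_intensity_tsv(agg, opts$out)
      message("aggregate: ", nrow(agg), " phosphoproteins -> ", opts$out)
    },
    normalize = {
      m <- read_intensity_tsv(opts[["in"]], kind = opts$kind %||% "protein")
      write_intensity_tsv(median_center(m), opts$out)
      message("normalize: -> ", opts$out)
    },
    run = {
      run_pipeline(opts$config)
      message("run: pipeline complete")
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (i + 1L > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}
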