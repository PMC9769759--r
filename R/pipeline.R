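#' Pipeline configuration
#'
#' Collects the input paths and stage parameters of a full analysis run.
#' All randomness (bootstrap resampling) derives from the single `seed`.
#'
#' @param taxa,kos,metadata,gmm Paths to the taxon profile TSV, stratified
#'   KO TSV, metadata TSV and GMM flat file.
#' @param out_dir Output directory.
#' @param ordination_rank Rank for Bray-Curtis / PCoA (default species).
#' @param core A [core_config()] (its seed is overridden by `seed`).
#' @param scoring A [module_scoring_config()].
#' @param alpha Significance level for the test cascade.
#' @param bh_scope `"global"` or `"per_module"` (see
#'   [differential_contributions()]).
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(taxa, kos, metadata, gmm, out_dir,
                            ordination_rank = "species",
                            core = core_config(),
                            scoring = module_scoring_config(),
                            alpha = 0.05,
                            bh_scope = "global",
                            seed = 1L) {
  structure(list(taxa = taxa, kos = kos, metadata = metadata, gmm = gmm,
                 out_dir = out_dir, ordination_rank = ordination_rank,
                 core = core, scoring = scoring, alpha = alpha,
                 bh_scope = bh_scope, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `core` and
#' `scoring` may be nested mappings of their constructors' arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("taxa", "kos", "metadata", "gmm", "out_dir")
  missing <- setdiff(req, names(y))
  if (length(missing) > 0) {
    abort(paste0("pipeline config missing required key(s): ",
                 paste(missing, collapse = ", ")))
  }
  pipeline_config(
    taxa = y$taxa, kos = y$kos, metadata = y$metadata, gmm = y$gmm,
    out_dir = y$out_dir,
    ordination_rank = y$ordination_rank %||% "species",
    core = do.call(core_config, y$core %||% list()),
    scoring = do.call(module_scoring_config, y$scoring %||% list()),
    alpha = y$alpha %||% 0.05,
    bh_scope = y$bh_scope %||% "global",
    seed = y$seed %||% 1L
  )
}

write_stage_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

find_clade <- function(profile, rank, label) {
  sub <- extract_rank(profile, rank)
  hits <- unique(sub$clade[clade_label(sub$clade) == label])
  if (length(hits) == 0) NULL else hits[[1]]
}

#' Run the full analysis pipeline
#'
#' Stages, in order: taxon ratios (Firmicutes/Bacteroidetes at phylum rank,
#' Prevotella/Bacteroides at genus rank, where the clades are present);
#' VANISH family aggregation; Bray-Curtis distance matrix and PCoA
#' ordination; bootstrap core taxa per cohort plus the shared core of the
#' first two cohorts; module scores (TOTAL and per-species); species
#' contributions; the differential-contribution test cascade. All result
#' tables are written as TSV under `config$out_dir` together with a JSON
#' run manifest (config hash, package version, seed).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of all stage results.
#' @export
run_all <- function(config) {
  for (p in c(config$taxa, config$kos, config$metadata, config$gmm)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  profile <- run_stage("read_taxa", read_taxon_profile(config$taxa))
  ko_table <- run_stage("read_kos", read_stratified_ko_table(config$kos))
  metadata <- run_stage("read_metadata", read_sample_metadata(config$metadata))
  catalogue <- run_stage("read_gmm", read_gmm_definitions(config$gmm))
  match_metadata(sample_ids(profile), metadata)

  ratios <- run_stage("ratios", {
    specs <- list(
      list(name = "firmicutes_bacteroidetes", rank = "phylum",
           num = "Firmicutes", den = "Bacteroidetes"),
      list(name = "prevotella_bacteroides", rank = "genus",
           num = "Prevotella", den = "Bacteroides")
    )
    purrr::map_dfr(specs, function(s) {
      nc <- find_clade(profile, s$rank, s$num)
      dc <- find_clade(profile, s$rank, s$den)
      if (is.null(nc) || is.null(dc)) {
        warn(paste0("ratio ", s$name, " skipped: clade not present"))
        return(tibble())
      }
      mutate(taxon_ratio(profile, nc, dc), ratio_name = s$name,
             .before = 1)
    })
  })
  write_stage_tsv(ratios, out("ratios.tsv"))

  families <- run_stage("families",
                        aggregate_families(profile, vanish_families()))
  write_stage_tsv(families, out("family_aggregates.tsv"))

  d <- run_stage("distance", bray_curtis(profile, config$ordination_rank))
  dist_tbl <- as_tibble(as.data.frame(unclass(d)), rownames = "sample_id")
  write_stage_tsv(dist_tbl, out("bray_curtis.tsv"))

  ord <- run_stage("ordination", pcoa(d, k = 2))
  write_stage_tsv(ord$coordinates, out("pcoa_coordinates.tsv"))

  core_cfg <- config$core
  core_cfg$seed <- derive_seed(config$seed, 11L)
  cohorts <- unique(metadata$cohort)
  cores <- run_stage("core", {
    purrr::map(setNames(cohorts, cohorts), function(coh) {
      ids <- metadata$sample_id[metadata$cohort == coh]
      core_taxa(profile[profile$sample_id %in% ids, ], core_cfg)
    })
  })
  core_tbl <- purrr::map_dfr(cores, ~ as_tibble(.x), .id = "cohort")
  writeLines(paste0("# core bootstrap seed: ", core_cfg$seed),
             out("core_taxa.tsv"))
  readr::write_tsv(core_tbl, out("core_taxa.tsv"), append = TRUE,
                   col_names = TRUE, progress = FALSE)
  shared <- if (length(cores) >= 2) {
    shared_core(cores[[1]], cores[[2]])
  } else NULL
  if (!is.null(shared)) {
    jsonlite::write_json(shared, out("shared_core.json"), auto_unbox = TRUE)
  }

  scores_total <- run_stage("score_total",
                            score_table(ko_table, catalogue, config$scoring,
                                        strata_mode = "total"))
  write_stage_tsv(scores_total, out("module_scores_total.tsv"))
  scores_species <- run_stage("score_species",
                              score_table(ko_table, catalogue, config$scoring,
                                          strata_mode = "per_species"))
  write_stage_tsv(scores_species, out("module_scores_species.tsv"))

  contrib <- run_stage("contributions", contributions(scores_species))
  write_stage_tsv(contrib, out("contributions.tsv"))

  tests <- run_stage("differential_contributions",
                     differential_contributions(contrib, metadata,
                                                alpha = config$alpha,
                                                bh_scope = config$bh_scope))
  write_stage_tsv(tests$omnibus, out("contribution_tests_omnibus.tsv"))
  write_stage_tsv(tests$pairwise, out("contribution_tests_pairwise.tsv"))

  params <- unclass(config)
  params <- params[setdiff(names(params),
                           c("taxa", "kos", "metadata", "gmm", "out_dir"))]
  manifest <- list(
    package = "gutmodules",
    version = as.character(utils::packageVersion("gutmodules")),
    seed = config$seed,
    config_hash = rlang::hash(params),
    alpha = config$alpha,
    bh_scope = config$bh_scope,
    ordination_rank = config$ordination_rank
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(list(ratios = ratios, families = families, distance = d,
                 ordination = ord, cores = cores, shared_core = shared,
                 scores_total = scores_total, scores_species = scores_species,
                 contributions = contrib, tests = tests,
                 manifest = manifest))
}
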