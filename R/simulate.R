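#' Default synthetic taxon panel
#'
#' Thirty prevalent stool species spanning six phyla, with Dirichlet
#' concentration parameters for westernized and non-westernized community
#' centroids. Westernized centroids put high mass on Bacteroidaceae and low
#' mass on the VANISH families (Prevotellaceae, Paraprevotellaceae,
#' Succinivibrionaceae, Spirochaetaceae); non-westernized centroids invert
#' that contrast, mirroring the loss of VANISH taxa with industrialisation.
#'
#' The tabulated values are centroid weights; they are rescaled so the
#' Dirichlet concentrations of each centroid sum to `concentration`. Larger
#' values give less sample-to-sample compositional dispersion; the default
#' (90) is milder than real stool cohorts, which keeps planted effects the
#' dominant source of group differences.
#'
#' @param concentration Total Dirichlet concentration per centroid
#'   (default 90).
#' @return Tibble with columns `lineage` (7-rank, pipe-delimited),
#'   `alpha_westernized`, `alpha_nonwesternized`, `prevalence`.
#' @export
default_taxa <- function(concentration = 90) {
  firm <- function(f, g, s) {
    paste0("k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__",
           f, "|g__", g, "|s__", s)
  }
  bact <- function(f, g, s) {
    paste0("k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__",
           f, "|g__", g, "|s__", s)
  }
  lin <- function(p, c, o, f, g, s) {
    paste0("k__Bacteria|p__", p, "|c__", c, "|o__", o, "|f__", f,
           "|g__", g, "|s__", s)
  }
  tibble::tribble(
    ~lineage, ~alpha_westernized, ~alpha_nonwesternized, ~prevalence,
    firm("Ruminococcaceae", "Faecalibacterium", "Faecalibacterium_prausnitzii"), 2.0, 1.8, 1.00,
    firm("Ruminococcaceae", "Ruminococcus", "Ruminococcus_bromii"), 1.0, 1.4, 0.95,
    firm("Ruminococcaceae", "Flavonifractor", "Flavonifractor_plautii"), 0.5, 0.4, 0.90,
    firm("Ruminococcaceae", "Oscillibacter", "Oscillibacter_sp_57_20"), 0.5, 0.6, 0.90,
    firm("Lachnospiraceae", "Roseburia", "Roseburia_intestinalis"), 0.8, 1.0, 0.95,
    firm("Lachnospiraceae", "Roseburia", "Roseburia_hominis"), 0.6, 0.7, 0.90,
    firm("Lachnospiraceae", "Agathobacter", "Eubacterium_rectale"), 1.4, 1.4, 0.95,
    firm("Lachnospiraceae", "Eubacterium", "Eubacterium_hallii"), 0.7, 0.6, 0.95,
    firm("Lachnospiraceae", "Blautia", "Blautia_wexlerae"), 0.9, 0.7, 0.95,
    firm("Lachnospiraceae", "Blautia", "Blautia_obeum"), 0.8, 0.7, 0.95,
    firm("Lachnospiraceae", "Dorea", "Dorea_longicatena"), 0.7, 0.6, 0.95,
    firm("Lachnospiraceae", "Coprococcus", "Coprococcus_catus"), 0.6, 0.7, 0.90,
    firm("Lachnospiraceae", "Anaerostipes", "Anaerostipes_hadrus"), 0.7, 0.6, 0.95,
    firm("Lachnospiraceae", "Mediterraneibacter", "Ruminococcus_torques"), 0.8, 0.6, 0.95,
    firm("Lachnospiraceae", "Butyrivibrio", "Butyrivibrio_crossotus"), 0.3, 0.8, 0.70,
    lin("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", "Streptococcus", "Streptococcus_thermophilus"), 0.5, 0.3, 0.85,
    lin("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae", "Dialister", "Dialister_invisus"), 0.5, 0.6, 0.80,
    bact("Bacteroidaceae", "Bacteroides", "Bacteroides_uniformis"), 2.0, 0.6, 1.00,
    bact("Bacteroidaceae", "Bacteroides", "Bacteroides_vulgatus"), 1.8, 0.7, 0.95,
    bact("Bacteroidaceae", "Bacteroides", "Bacteroides_ovatus"), 1.2, 0.5, 0.95,
    bact("Bacteroidaceae", "Bacteroides", "Bacteroides_dorei"), 1.0, 0.5, 0.90,
    bact("Rikenellaceae", "Alistipes", "Alistipes_putredinis"), 0.9, 0.5, 0.95,
    bact("Tannerellaceae", "Parabacteroides", "Parabacteroides_distasonis"), 0.8, 0.5, 0.95,
    bact("Prevotellaceae", "Prevotella", "Prevotella_copri"), 0.2, 4.0, 0.55,
    bact("Prevotellaceae", "Prevotella", "Prevotella_stercorea"), 0.1, 2.0, 0.45,
    bact("Paraprevotellaceae", "Paraprevotella", "Paraprevotella_clara"), 0.2, 1.0, 0.55,
    lin("Actinobacteria", "Actinomycetia", "Bifidobacteriales", "Bifidobacteriaceae", "Bifidobacterium", "Bifidobacterium_adolescentis"), 0.9, 0.7, 0.90,
    lin("Proteobacteria", "Gammaproteobacteria", "Enterobacterales", "Enterobacteriaceae", "Escherichia", "Escherichia_coli"), 0.5, 0.6, 0.85,
    lin("Proteobacteria", "Gammaproteobacteria", "Aeromonadales", "Succinivibrionaceae", "Succinivibrio", "Succinivibrio_dextrinosolvens"), 0.1, 1.5, 0.35,
    lin("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales", "Akkermansiaceae", "Akkermansia", "Akkermansia_muciniphila"), 0.6, 0.4, 0.80
  ) |>
    mutate(
      alpha_westernized = concentration * .data$alpha_westernized /
        sum(.data$alpha_westernized),
      alpha_nonwesternized = concentration * .data$alpha_nonwesternized /
        sum(.data$alpha_nonwesternized)
    )
}

#' Simulation configuration for synthetic diet-cohort studies
#'
#' The generator emulates the structure of a diet-stratified stool
#' metagenome study: per cohort, balanced diet groups; per sample, a
#' compositional taxon profile drawn from the cohort's Dirichlet centroid
#' restricted to present taxa; per species, log-normal KO abundances (RPK)
#' for the modules the species carries, scaled by the species' relative
#' abundance; optional planted fold-change effects on one species'
#' contribution to one module in one diet group.
#'
#' @param n_per_group Samples per diet group per cohort (default 35, so one
#'   4-group cohort has 140 samples).
#' @param cohorts Tibble with columns `cohort` and `westernized`.
#' @param taxa Taxon panel as in [default_taxa()].
#' @param n_modules Catalogue size (default 20).
#' @param max_steps,max_alternatives Upper bounds for per-module step count
#'   (uniform on 1..max_steps, default 8) and per-step alternatives (uniform
#'   on 1..max_alternatives, default 3).
#' @param complex_prob Probability that an alternative is a 2-3 member
#'   complex (default 0.2).
#' @param ko_meanlog,ko_sdlog Log-normal location/scale of per-KO RPK draws
#'   (defaults log(50) and 0.75).
#' @param carry_prob Probability that a species carries a module
#'   (default 0.7).
#' @param unclassified_fraction Fraction of each KO's total mass assigned to
#'   the UNCLASSIFIED stratum, in expectation (default 0.3).
#' @param planted_effects Tibble with columns `module_id`, `species`
#'   (species stratum token, e.g. `"s__Prevotella_copri"`), `diet_group`,
#'   `fold_change` (> 0); default none.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = 35,
                              cohorts = tibble(cohort = "diet-study",
                                               westernized = TRUE),
                              taxa = default_taxa(),
                              n_modules = 20,
                              max_steps = 8,
                              max_alternatives = 3,
                              complex_prob = 0.2,
                              ko_meanlog = log(50),
                              ko_sdlog = 0.75,
                              carry_prob = 0.7,
                              unclassified_fraction = 0.3,
                              planted_effects = NULL,
                              seed = 1L) {
  stopifnot_scalar_number(complex_prob, "complex_prob", 0, 1)
  stopifnot_scalar_number(carry_prob, "carry_prob", 0, 1)
  stopifnot_scalar_number(unclassified_fraction, "unclassified_fraction", 0, 1 - 1e-9)
  if (any(taxa$prevalence < 0 | taxa$prevalence > 1)) {
    abort("taxon prevalence probabilities must lie in [0, 1]")
  }
  if (is.null(planted_effects)) {
    planted_effects <- tibble(module_id = character(), species = character(),
                              diet_group = character(), fold_change = numeric())
  }
  planted_effects <- as_tibble(planted_effects)
  if (nrow(planted_effects) > 0 && any(planted_effects$fold_change <= 0)) {
    abort("planted fold-changes must be > 0")
  }
  structure(list(n_per_group = n_per_group, cohorts = as_tibble(cohorts),
                 taxa = as_tibble(taxa), n_modules = n_modules,
                 max_steps = max_steps, max_alternatives = max_alternatives,
                 complex_prob = complex_prob, ko_meanlog = ko_meanlog,
                 ko_sdlog = ko_sdlog, carry_prob = carry_prob,
                 unclassified_fraction = unclassified_fraction,
                 planted_effects = planted_effects,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# species stratum token: the terminal s__ segment of a lineage
species_token <- function(lineage) {
  vapply(strsplit(lineage, "|", fixed = TRUE),
         function(x) x[[length(x)]], character(1))
}

#' Simulate taxonomic profiles and matching metadata
#'
#' Per sample: taxon presence is Bernoulli with the panel's prevalence;
#' composition over present taxa is Dirichlet with the cohort's centroid
#' concentrations; values are scaled to percent. The returned profile
#' contains rows at every rank (ancestor clades carry the sums of their
#' descendants), as MetaPhlAn output does. A sample where every taxon is
#' absent is redrawn (up to 100 attempts, then an error). Deterministic for
#' a fixed `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with elements `profile` (a [taxon_profile()]) and
#'   `metadata` (a [sample_metadata()]).
#' @export
simulate_taxa <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  taxa <- config$taxa
  n_taxa <- nrow(taxa)
  samples <- character(0)
  diets <- character(0)
  cohs <- character(0)
  west <- logical(0)
  values <- list()
  for (ci in seq_len(nrow(config$cohorts))) {
    coh <- config$cohorts$cohort[[ci]]
    is_w <- isTRUE(config$cohorts$westernized[[ci]])
    alpha <- if (is_w) taxa$alpha_westernized else taxa$alpha_nonwesternized
    for (dg in DIET_GROUPS) {
      for (i in seq_len(config$n_per_group)) {
        sid <- paste0(coh, "_", substr(dg, 1, 4), "_", sprintf("%03d", i))
        comp <- NULL
        for (try in seq_len(100L)) {
          present <- stats::runif(n_taxa) < taxa$prevalence
          if (!any(present)) next
          g <- stats::rgamma(sum(present), shape = alpha[present], rate = 1)
          if (sum(g) <= 0) next
          comp <- numeric(n_taxa)
          comp[present] <- 100 * (g / sum(g))
          break
        }
        if (is.null(comp)) {
          abort(paste0("failed to draw a non-empty composition for sample ",
                       sid, " after 100 attempts"))
        }
        samples <- c(samples, sid)
        diets <- c(diets, dg)
        cohs <- c(cohs, coh)
        west <- c(west, is_w)
        values[[length(values) + 1L]] <- comp
      }
    }
  }
  vm <- do.call(rbind, values)  # samples x species, percent

  # expand species-level values to every ancestor rank
  segs <- strsplit(taxa$lineage, "|", fixed = TRUE)
  long <- purrr::map_dfr(seq_len(7L), function(depth) {
    anc <- vapply(segs, function(s) paste(s[seq_len(depth)], collapse = "|"),
                  character(1))
    agg <- rowsum(t(vm), group = anc)  # clades x samples
    tibble(clade = rep(rownames(agg), times = ncol(agg)),
           sample_id = rep(samples, each = nrow(agg)),
           abundance = as.vector(agg))
  })
  long <- long[long$abundance > 0 | clade_rank(long$clade) == "species", ]

  list(
    profile = taxon_profile(long),
    metadata = sample_metadata(tibble(sample_id = samples, diet_group = diets,
                                      cohort = cohs, westernized = west))
  )
}

#' Simulate a synthetic gut metabolic module catalogue
#'
#' Modules have 1 to `max_steps` steps, 1 to `max_alternatives` alternatives
#' per step, and complexes (2-3 members) with probability `complex_prob`;
#' KO ids are unique within the catalogue; categories are drawn from the
#' eight standard module categories (amino acid / carbohydrate /
#' glycoprotein / lipid degradation, acetate / propionate / butyrate /
#' lactate metabolism).
#'
#' @param config A [simulation_config()].
#' @return A [gmm_catalogue()] tibble.
#' @export
simulate_gmm_catalogue <- function(config) {
  set.seed(derive_seed(config$seed, 2L))
  # worst case KO usage: steps * alts * 3 members per module
  pool <- sprintf("K%05d", sample.int(99999L,
    min(99999L, config$n_modules * config$max_steps * config$max_alternatives * 3L)))
  next_ko <- 0L
  take_ko <- function(k) {
    out <- pool[next_ko + seq_len(k)]
    next_ko <<- next_ko + k
    out
  }
  recs <- purrr::map(seq_len(config$n_modules), function(i) {
    n_steps <- sample.int(config$max_steps, 1L)
    steps <- purrr::map(seq_len(n_steps), function(s) {
      n_alts <- sample.int(config$max_alternatives, 1L)
      purrr::map(seq_len(n_alts), function(a) {
        size <- if (stats::runif(1) < config$complex_prob) sample(2:3, 1L) else 1L
        take_ko(size)
      })
    })
    list(module_id = sprintf("MF%04d", i),
         name = paste0("synthetic module ", i),
         category = sample(GMM_CATEGORIES, 1L),
         steps = steps)
  })
  gmm_catalogue(tibble(
    module_id = vapply(recs, `[[`, character(1), "module_id"),
    name = vapply(recs, `[[`, character(1), "name"),
    category = vapply(recs, `[[`, character(1), "category"),
    steps = lapply(recs, `[[`, "steps")
  ))
}

#' Simulate a species-stratified KO abundance table
#'
#' Each species carries each module with probability `carry_prob` (planted
#' (module, species) pairs always carry their module). For a carried
#' module, every KO of the module gets, per sample, a log-normal RPK draw
#' scaled by the species' relative abundance in that sample. Planted
#' effects multiply the target species' KO rows of the target module by the
#' fold-change in samples of the target diet group. The UNCLASSIFIED
#' stratum of each KO is an independent log-normal mass sized so that its
#' expected share of the KO total is `unclassified_fraction` (exactly zero
#' when the fraction is zero), and TOTAL rows are exact sums over strata.
#'
#' @param config A [simulation_config()].
#' @param profile Taxon profile from [simulate_taxa()].
#' @param metadata Metadata from [simulate_taxa()].
#' @param catalogue Catalogue from [simulate_gmm_catalogue()].
#' @return A [stratified_ko()] tibble.
#' @export
simulate_stratified_kos <- function(config, profile, metadata, catalogue) {
  set.seed(derive_seed(config$seed, 3L))
  sp <- extract_rank(profile, "species")
  lineages <- unique(sp$clade)
  tokens <- species_token(lineages)
  samples <- sample_ids(profile)
  rel <- taxa_matrix(sp, samples)[, lineages, drop = FALSE] / 100

  eff <- config$planted_effects
  if (nrow(eff) > 0) {
    bad_m <- setdiff(eff$module_id, catalogue$module_id)
    bad_s <- setdiff(eff$species, tokens)
    if (length(bad_m) > 0) abort(paste0("planted effect references unknown module: ", bad_m[[1]]))
    if (length(bad_s) > 0) abort(paste0("planted effect references unknown species: ", bad_s[[1]]))
    if (any(!eff$diet_group %in% DIET_GROUPS)) abort("planted effect references unknown diet group")
  }

  carried <- matrix(stats::runif(length(tokens) * nrow(catalogue)) < config$carry_prob,
                    nrow = length(tokens), ncol = nrow(catalogue),
                    dimnames = list(tokens, catalogue$module_id))
  if (nrow(eff) > 0) {
    carried[cbind(match(eff$species, tokens),
                  match(eff$module_id, catalogue$module_id))] <- TRUE
  }

  module_kos <- lapply(catalogue$steps, function(s) unique(unlist(s)))
  names(module_kos) <- catalogue$module_id

  # (ko, species, module) rows for every carried pair
  idx <- which(carried, arr.ind = TRUE)
  pair_ko <- character(0); pair_sp <- character(0); pair_mod <- character(0)
  if (nrow(idx) > 0) {
    kos_per <- module_kos[colnames(carried)[idx[, 2]]]
    reps <- lengths(kos_per)
    pair_ko <- unlist(kos_per, use.names = FALSE)
    pair_sp <- rep(rownames(carried)[idx[, 1]], reps)
    pair_mod <- rep(colnames(carried)[idx[, 2]], reps)
  }
  n_pairs <- length(pair_ko)
  if (n_pairs == 0L) abort("no species carries any module; raise carry_prob")

  noise <- matrix(stats::rlnorm(n_pairs * length(samples),
                                meanlog = config$ko_meanlog,
                                sdlog = config$ko_sdlog),
                  nrow = n_pairs)
  vals <- noise * t(rel)[match(pair_sp, tokens), , drop = FALSE]

  meta <- match_metadata(samples, metadata)
  if (nrow(eff) > 0) {
    for (e in seq_len(nrow(eff))) {
      rows <- pair_sp == eff$species[[e]] & pair_mod == eff$module_id[[e]]
      cols <- meta$diet_group == eff$diet_group[[e]]
      vals[rows, cols] <- vals[rows, cols] * eff$fold_change[[e]]
    }
  }

  # collapse (ko, species) over modules (KOs are unique per module, so this
  # is a no-op for synthetic catalogues, but keeps the contract general)
  key <- paste(pair_ko, pair_sp, sep = "\r")
  vals <- rowsum(vals, group = key, reorder = FALSE)
  keys <- stringr::str_split_fixed(rownames(vals), "\r", 2)

  f <- config$unclassified_fraction
  ko_tot <- rowsum(vals, group = keys[, 1], reorder = FALSE)
  if (f > 0) {
    # independent unattributed mass: per (ko, sample) log-normal around the
    # KO's mean attributed mass, scaled to an expected share of f
    base <- rowMeans(ko_tot)
    lnoise <- matrix(stats::rlnorm(length(ko_tot),
                                   meanlog = -config$ko_sdlog^2 / 2,
                                   sdlog = config$ko_sdlog),
                     nrow = nrow(ko_tot))
    uncl <- (f / (1 - f)) * base * lnoise
  } else {
    uncl <- ko_tot * 0
  }
  total <- ko_tot + uncl

  long <- tibble(
    ko = c(rep(keys[, 1], times = length(samples)),
           rep(rownames(ko_tot), times = 2L * length(samples))),
    stratum = c(rep(keys[, 2], times = length(samples)),
                rep(STRATUM_UNCLASSIFIED, length(uncl)),
                rep(STRATUM_TOTAL, length(total))),
    sample_id = c(rep(samples, each = nrow(vals)),
                  rep(samples, each = nrow(ko_tot)),
                  rep(samples, each = nrow(ko_tot))),
    rpk = c(as.vector(vals), as.vector(uncl), as.vector(total))
  )
  new_stratified_ko(long)
}

#' Simulate a complete study bundle
#'
#' Runs [simulate_taxa()], [simulate_gmm_catalogue()] and
#' [simulate_stratified_kos()] under one configuration.
#'
#' @param config A [simulation_config()].
#' @return List with `profile`, `metadata`, `catalogue`, `ko_table` and
#'   `truth` (the planted-effects tibble).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  tax <- simulate_taxa(config)
  catalogue <- simulate_gmm_catalogue(config)
  ko_table <- simulate_stratified_kos(config, tax$profile, tax$metadata,
                                      catalogue)
  list(profile = tax$profile, metadata = tax$metadata, catalogue = catalogue,
       ko_table = ko_table, truth = config$planted_effects)
}

#' Draw a random planted-effect design
#'
#' Picks `n_effects` distinct modules and, for each, a target species, a
#' target diet group and the given fold-change. Target species are drawn
#' from the consistently-detected part of the panel (prevalence at least
#' `min_prevalence`): a contribution effect is only observable in samples
#' where the species is present, so power experiments plant effects in taxa
#' the profiler actually detects.
#'
#' @param catalogue A [gmm_catalogue()].
#' @param taxa Taxon panel (see [default_taxa()]).
#' @param n_effects Number of (module, species) features to perturb.
#' @param fold_change Multiplicative effect on the target species' KO rows.
#' @param min_prevalence Minimum panel prevalence for target species.
#' @param seed Integer seed.
#' @return Planted-effects tibble for [simulation_config()].
#' @export
plant_effects <- function(catalogue, taxa = default_taxa(), n_effects = 10,
                          fold_change = 4, min_prevalence = 0.9, seed = 1L) {
  set.seed(as.integer(seed))
  pool <- species_token(taxa$lineage[taxa$prevalence >= min_prevalence])
  if (length(pool) == 0L) abort("no species meet the prevalence floor")
  if (n_effects > nrow(catalogue)) abort("more effects than modules")
  tibble(
    module_id = sample(catalogue$module_id, n_effects),
    species = sample(pool, n_effects, replace = TRUE),
    diet_group = sample(DIET_GROUPS, n_effects, replace = TRUE),
    fold_change = fold_change
  )
}

#' Precision and recall of planted-effect recovery
#'
#' Compares the features flagged by a [differential_contributions()] run
#' (omnibus significant and at least one significant Dunn pair) with the
#' planted ground truth.
#'
#' @param result A `contrib_test` object.
#' @param truth Planted-effects tibble (columns `module_id`, `species`).
#' @return One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
recovery_rates <- function(result, truth) {
  flagged <- result$omnibus[result$omnibus$significant, c("module_id", "species")]
  with_pair <- unique(result$pairwise[result$pairwise$significant,
                                      c("module_id", "species")])
  flagged <- dplyr::semi_join(flagged, with_pair,
                              by = c("module_id", "species"))
  key <- function(d) paste(d$module_id, d$species)
  tp <- sum(key(flagged) %in% key(truth))
  fp <- nrow(flagged) - tp
  fn <- nrow(truth) - tp
  tibble(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         recall = if (nrow(truth) == 0) NA_real_ else tp / nrow(truth))
}

#' Simulate null contribution features
#'
#' Draws `n_features` (module, species) features whose contribution values
#' are independent logit-normal draws from one distribution for every
#' sample, regardless of diet group — the null model used to calibrate the
#' test cascade's type-I error.
#'
#' @param n_features Number of features (arranged on a module x species
#'   grid).
#' @param n_per_group Samples per diet group.
#' @param seed Integer seed.
#' @param sdlog Standard deviation of the latent normal (default 1).
#' @return List with `contrib` (a `contribution_table`) and `metadata`.
#' @export
simulate_null_contributions <- function(n_features = 1000, n_per_group = 35,
                                        seed = 1L, sdlog = 1) {
  set.seed(as.integer(seed))
  n_species <- 20L
  n_modules <- ceiling(n_features / n_species)
  feats <- tidyr::expand_grid(
    module_id = sprintf("MF%04d", seq_len(n_modules)),
    species = sprintf("s__Species_%02d", seq_len(n_species))
  )[seq_len(n_features), ]
  n_samples <- n_per_group * length(DIET_GROUPS)
  samples <- sprintf("S%03d", seq_len(n_samples))
  meta <- sample_metadata(tibble(
    sample_id = samples,
    diet_group = rep(DIET_GROUPS, each = n_per_group),
    cohort = "null-sim", westernized = TRUE
  ))
  latent <- stats::rnorm(n_features * n_samples, sd = sdlog)
  contrib <- tibble(
    sample_id = rep(samples, each = n_features),
    module_id = rep(feats$module_id, times = n_samples),
    species = rep(feats$species, times = n_samples),
    fraction = stats::plogis(latent)
  )
  contrib <- structure(contrib, class = c("contribution_table",
                                          class(tibble())))
  list(contrib = contrib, metadata = meta)
}

#' Write a simulated bundle to disk
#'
#' Emits the taxon profile, stratified KO table and metadata as TSV, the
#' catalogue as a GMM flat file, and the planted-effect ground truth as
#' JSON.
#'
#' @param sim A bundle from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_taxon_profile(sim$profile, file.path(dir, "taxa.tsv"))
  write_stratified_ko_table(sim$ko_table, file.path(dir, "kos.tsv"))
  write_sample_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_gmm_definitions(sim$catalogue, file.path(dir, "modules.gmm"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows")
  invisible(dir)
}
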