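# shared fixture builders; everything is generated in code

diet_levels <- c("omnivore", "pescatarian", "vegan", "vegetarian")

# minimal catalogue: one module, three steps
# step 1: single KO; step 2: two alternatives; step 3: a two-member complex
tiny_catalogue <- function() {
  gmm_catalogue(tibble::tibble(
    module_id = "MF0001",
    name = "toy module",
    category = "butyrate metabolism",
    steps = list(list(
      list("K00001"),
      list("K00002", "K00003"),
      list(c("K00004", "K00005"))
    ))
  ))
}

# long-format KO table with one sample and explicit strata
tiny_ko_table <- function() {
  stratified_ko(tibble::tibble(
    ko = rep(c("K00001", "K00002", "K00003", "K00004", "K00005"), each = 2),
    stratum = rep(c("s__A", "s__B"), times = 5),
    sample_id = "S1",
    rpk = c(6, 4, 1, 1, 2, 2, 4, 2, 3, 5)
  ))
}

# brute-force module scorer, written independently of the package's
# vectorised path: direct evaluation of the definition against a named
# KO vector
oracle_score_module <- function(steps, kovec, cutoff = 0.66,
                                agg = "median") {
  step_vals <- vapply(steps, function(step) {
    total <- 0
    for (alt in step) {
      member_vals <- vapply(alt, function(k) {
        if (k %in% names(kovec)) kovec[[k]] else 0
      }, numeric(1))
      total <- total + min(member_vals)
    }
    total
  }, numeric(1))
  coverage <- mean(step_vals > 0)
  aggregated <- if (agg == "median") stats::median(step_vals) else mean(step_vals)
  list(abundance = if (coverage >= cutoff) aggregated else 0,
       coverage = coverage)
}

# random small scoring instance: a catalogue plus a long KO table over a few
# samples and strata, with zeros and missing KOs mixed in
random_instance <- function(seed, n_modules = 5, n_species = 4,
                            n_samples = 6) {
  set.seed(seed)
  cfg <- simulation_config(n_modules = n_modules, max_steps = 6,
                           max_alternatives = 3, seed = seed)
  catalogue <- simulate_gmm_catalogue(cfg)
  kos <- unique(unlist(catalogue$steps))
  strata <- c(paste0("s__sp", seq_len(n_species)), STRATUM_UNCLASSIFIED)
  samples <- paste0("S", seq_len(n_samples))
  grid <- expand.grid(ko = kos, stratum = strata, sample_id = samples,
                      stringsAsFactors = FALSE)
  # drop ~40% of rows and zero ~20% of the rest
  keep <- runif(nrow(grid)) > 0.4
  grid <- grid[keep, , drop = FALSE]
  grid$rpk <- ifelse(runif(nrow(grid)) < 0.2, 0,
                     round(rlnorm(nrow(grid), log(10), 1), 4))
  tbl <- stratified_ko(tibble::as_tibble(grid))
  list(catalogue = catalogue, ko_table = tbl, samples = samples,
       strata = strata)
}

# named KO vector for one (sample, stratum) of a long table
ko_vector <- function(tbl, sample, stratum) {
  sub <- tbl[tbl$sample_id == sample & tbl$stratum == stratum, ]
  stats::setNames(sub$rpk, sub$ko)
}

# small metadata table over explicit samples
meta_for <- function(samples, diets, cohort = "C1", westernized = TRUE) {
  sample_metadata(tibble::tibble(
    sample_id = samples, diet_group = diets,
    cohort = cohort, westernized = westernized
  ))
}

# hand-built multi-rank taxon profile, two samples
toy_profile <- function() {
  taxon_profile(tibble::tibble(
    clade = rep(c(
      "k__Bacteria",
      "k__Bacteria|p__Firmicutes",
      "k__Bacteria|p__Bacteroidetes",
      "k__Bacteria|p__Firmicutes|c__Clostridia",
      "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Prevotellaceae",
      "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides",
      "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Prevotellaceae|g__Prevotella",
      "k__Bacteria|p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Ruminococcaceae|g__Faecalibacterium|s__Faecalibacterium_prausnitzii",
      "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides|s__Bacteroides_uniformis",
      "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Prevotellaceae|g__Prevotella|s__Prevotella_copri"
    ), 2),
    sample_id = rep(c("S1", "S2"), each = 10),
    abundance = c(
      100, 60, 20, 60, 4.2, 15, 4.2, 30, 15, 4.2,
      100, 45, 40, 45, 10.0, 20, 10.0, 25, 20, 10.0
    )
  ))
}
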