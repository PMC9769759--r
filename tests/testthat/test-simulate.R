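test_that("a single always-present taxon yields 100 percent everywhere", {
  taxa <- tibble::tibble(
    lineage = "k__B|p__P|c__C|o__O|f__F|g__G|s__Solo",
    alpha_westernized = 1, alpha_nonwesternized = 1, prevalence = 1
  )
  sim <- simulate_taxa(simulation_config(n_per_group = 2, taxa = taxa,
                                         seed = 3))
  sp <- extract_rank(sim$profile, "species")
  expect_true(all(sp$abundance == 100))
  expect_equal(nrow(sim$metadata), 8L)
  expect_setequal(sim$metadata$diet_group, diet_levels)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- simulation_config(n_per_group = 3, n_modules = 6, seed = 17)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(tibble::as_tibble(a$profile), tibble::as_tibble(b$profile))
  expect_identical(tibble::as_tibble(a$ko_table),
                   tibble::as_tibble(b$ko_table))
  expect_identical(a$catalogue$steps, b$catalogue$steps)

  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_simulation_bundle(a, dir_a)
  write_simulation_bundle(b, dir_b)
  for (f in list.files(dir_a)) {
    expect_identical(readBin(file.path(dir_a, f), "raw", 1e7),
                     readBin(file.path(dir_b, f), "raw", 1e7))
  }
})

test_that("generated tables satisfy the full format validators", {
  cfg <- simulation_config(n_per_group = 3, n_modules = 8, seed = 23)
  sim <- simulate_dataset(cfg)
  expect_s3_class(taxon_profile(tibble::as_tibble(sim$profile)),
                  "taxon_profile")
  expect_s3_class(stratified_ko(tibble::as_tibble(sim$ko_table)),
                  "stratified_ko")
  expect_s3_class(sample_metadata(tibble::as_tibble(sim$metadata)),
                  "sample_metadata")
  expect_s3_class(gmm_catalogue(tibble::as_tibble(sim$catalogue)),
                  "gmm_catalogue")
})

test_that("separated centroids produce cohort structure in Bray-Curtis space", {
  cfg <- simulation_config(
    n_per_group = 5,
    cohorts = tibble::tibble(cohort = c("west", "nonwest"),
                             westernized = c(TRUE, FALSE)),
    seed = 29
  )
  sim <- simulate_taxa(cfg)
  d <- bray_curtis(sim$profile)
  ids <- sim$metadata$sample_id
  west <- ids[sim$metadata$westernized]
  nonw <- ids[!sim$metadata$westernized]
  within <- c(d[west, west][upper.tri(diag(length(west)))],
              d[nonw, nonw][upper.tri(diag(length(nonw)))])
  between <- as.vector(d[west, nonw])
  expect_lt(mean(within), mean(between))

  # non-westernized samples carry more Prevotellaceae
  fam <- aggregate_families(sim$profile, "Prevotellaceae")
  fam <- dplyr::left_join(fam, tibble::as_tibble(sim$metadata),
                          by = "sample_id")
  expect_gt(mean(fam$abundance[!fam$westernized]),
            mean(fam$abundance[fam$westernized]))
})

test_that("a lone carrier species owns the module contribution minus unclassified", {
  taxa <- tibble::tibble(
    lineage = paste0("k__B|p__P|c__C|o__O|f__F|g__G|s__Sp", 1:2),
    alpha_westernized = c(1, 1), alpha_nonwesternized = c(1, 1),
    prevalence = c(1, 1)
  )
  cfg <- simulation_config(n_per_group = 2, taxa = taxa, n_modules = 1,
                           carry_prob = 1, unclassified_fraction = 0,
                           seed = 5)
  sim <- simulate_dataset(cfg)
  sc <- score_table(sim$ko_table, sim$catalogue, strata_mode = "per_species")
  ct <- contributions(sc)
  # both species carry the module, fractions sum to 1 with no unclassified
  sums <- ct |>
    dplyr::filter(!is.na(fraction), species != "UNCLASSIFIED") |>
    dplyr::group_by(sample_id, module_id) |>
    dplyr::summarise(total = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$total - 1) < 1e-9))

  # zero unclassified mass: strata sum exactly to TOTAL
  kt <- tibble::as_tibble(sim$ko_table)
  strata_sum <- kt |>
    dplyr::filter(stratum != "TOTAL") |>
    dplyr::group_by(ko, sample_id) |>
    dplyr::summarise(s = sum(rpk), .groups = "drop")
  totals <- kt |>
    dplyr::filter(stratum == "TOTAL") |>
    dplyr::select(ko, sample_id, t = rpk)
  cmp <- dplyr::inner_join(strata_sum, totals, by = c("ko", "sample_id"))
  expect_equal(cmp$s, cmp$t, tolerance = 1e-12)
})

test_that("planted effects reference checking and realized effect size hold", {
  cfg0 <- simulation_config(n_modules = 3, seed = 41)
  catalogue <- simulate_gmm_catalogue(cfg0)
  tax <- simulate_taxa(simulation_config(n_per_group = 2, seed = 41))
  bad_mod <- simulation_config(
    n_per_group = 2, n_modules = 3, seed = 41,
    planted_effects = tibble::tibble(module_id = "MF9999", species = "s__X",
                                     diet_group = "vegan", fold_change = 4))
  expect_error(
    simulate_stratified_kos(bad_mod, tax$profile, tax$metadata, catalogue),
    "unknown module"
  )
  bad_sp <- simulation_config(
    n_per_group = 2, n_modules = 3, seed = 41,
    planted_effects = tibble::tibble(module_id = "MF0001", species = "s__X",
                                     diet_group = "vegan", fold_change = 4))
  expect_error(
    simulate_stratified_kos(bad_sp, tax$profile, tax$metadata, catalogue),
    "unknown species"
  )

  # realized mean contribution ratio between target and other groups stays
  # near the planted fold-change (Monte-Carlo over 50 seeds)
  eff <- tibble::tibble(module_id = "MF0002",
                        species = "s__Bacteroides_uniformis",
                        diet_group = "vegan", fold_change = 4)
  ratios <- vapply(1:50, function(s) {
    cfg <- simulation_config(n_per_group = 6, n_modules = 5,
                             planted_effects = eff, seed = 1000 + s)
    sim <- simulate_dataset(cfg)
    sc <- score_table(sim$ko_table, sim$catalogue,
                      strata_mode = "per_species")
    ct <- contributions(sc)
    feat <- ct[ct$module_id == "MF0002" &
                 ct$species == "s__Bacteroides_uniformis", ]
    feat <- dplyr::left_join(feat, tibble::as_tibble(sim$metadata),
                             by = "sample_id")
    mean(feat$fraction[feat$diet_group == "vegan"], na.rm = TRUE) /
      mean(feat$fraction[feat$diet_group != "vegan"], na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(ratios), 3)
  expect_lt(mean(ratios), 5)
})
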