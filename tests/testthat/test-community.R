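test_that("extract_rank keeps only clades terminating at the requested rank", {
  tp <- toy_profile()
  ph <- extract_rank(tp, "phylum")
  expect_setequal(unique(ph$clade),
                  c("k__Bacteria|p__Firmicutes", "k__Bacteria|p__Bacteroidetes"))
  expect_equal(ph$abundance[ph$clade == "k__Bacteria|p__Firmicutes" &
                              ph$sample_id == "S1"], 60)

  expect_equal(nrow(extract_rank(tp, "order")), 0L)
  expect_error(extract_rank(tp, "tribe"), "unknown rank")

  # five phyla built by hand stay five rows
  five <- taxon_profile(tibble::tibble(
    clade = paste0("k__Bacteria|p__P", 1:5),
    sample_id = "S1", abundance = rep(20, 5)
  ))
  expect_equal(nrow(extract_rank(five, "phylum")), 5L)
})

test_that("taxon ratios follow the zero policy and scale invariance", {
  tp <- toy_profile()
  fb <- taxon_ratio(tp, "k__Bacteria|p__Firmicutes",
                    "k__Bacteria|p__Bacteroidetes")
  expect_equal(fb$ratio[fb$sample_id == "S1"], 3)

  pb <- taxon_ratio(
    tp,
    "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Prevotellaceae|g__Prevotella",
    "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides"
  )
  expect_equal(pb$ratio[pb$sample_id == "S1"], 4.2 / 15)

  expect_error(taxon_ratio(tp, "p__Missing", "k__Bacteria|p__Firmicutes"),
               "Missing")
  expect_error(taxon_ratio(tp, "k__Bacteria",
                           "k__Bacteria|p__Firmicutes"), "same rank")

  # zero denominator / zero numerator
  z <- taxon_profile(tibble::tibble(
    clade = rep(c("p__A", "p__B"), 2),
    sample_id = rep(c("S1", "S2"), each = 2),
    abundance = c(5, 0, 0, 5)
  ))
  r <- taxon_ratio(z, "p__A", "p__B")
  expect_false(r$defined[r$sample_id == "S1"])
  expect_true(is.na(r$ratio[r$sample_id == "S1"]))
  expect_equal(r$ratio[r$sample_id == "S2"], 0)
  rp <- taxon_ratio(z, "p__A", "p__B", zero_policy = "pseudocount")
  expect_true(all(rp$defined))

  # scaling a sample leaves the ratio unchanged
  scaled <- taxon_profile(dplyr::mutate(tibble::as_tibble(tp),
                                        abundance = abundance * 0.5))
  fb2 <- taxon_ratio(scaled, "k__Bacteria|p__Firmicutes",
                     "k__Bacteria|p__Bacteroidetes")
  expect_equal(fb2$ratio, fb$ratio)
})

test_that("family aggregation sums families and reports absences as zero", {
  tp <- toy_profile()
  agg <- aggregate_families(tp, c("Prevotellaceae", "Spirochaetaceae"))
  expect_equal(agg$abundance[agg$family == "Prevotellaceae" &
                               agg$sample_id == "S1"], 4.2)
  expect_equal(agg$abundance[agg$family == "Spirochaetaceae" &
                               agg$sample_id == "S1"], 0)
  expect_equal(nrow(agg), 4L)  # 2 families x 2 samples, absences kept

  two <- aggregate_families(tp, c("Prevotellaceae", "Bacteroidaceae"))
  s2 <- two[two$sample_id == "S2", ]
  # Prevotellaceae has a family-rank row (10.0); Bacteroidaceae does not
  expect_setequal(s2$abundance, c(10, 0))
})

test_that("Bray-Curtis matches hand-computed values and its invariants", {
  mk <- function(vals) {
    taxon_profile(tibble::tibble(
      clade = rep(paste0("k__B|p__P|c__C|o__O|f__F|g__G|s__T", 1:3), 2),
      sample_id = rep(c("X", "Y"), each = 3),
      abundance = vals * 100
    ))
  }
  d <- bray_curtis(mk(c(0.6, 0.4, 0, 0.2, 0.3, 0.5)))
  expect_equal(d["X", "Y"], 0.5)
  expect_equal(d["Y", "X"], 0.5)
  expect_equal(diag(d), c(X = 0, Y = 0))

  ident <- bray_curtis(mk(c(0.5, 0.3, 0.2, 0.5, 0.3, 0.2)))
  expect_equal(ident["X", "Y"], 0)

  disjoint <- bray_curtis(mk(c(0.6, 0.4, 0, 0, 0, 1)))
  expect_equal(disjoint["X", "Y"], 1)

  zero <- mk(c(1, 0, 0, 0, 0, 0))
  zero$abundance[4:6] <- 0
  expect_error(bray_curtis(taxon_profile(zero)), "all-zero")
})

test_that("Bray-Curtis is symmetric, bounded and order-invariant on simulated data", {
  sim <- simulate_taxa(simulation_config(n_per_group = 3, seed = 5))
  d <- bray_curtis(sim$profile)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  perm <- sample(sample_ids(sim$profile))
  reordered <- tibble::as_tibble(sim$profile)
  reordered <- reordered[order(match(reordered$sample_id, perm)), ]
  d2 <- bray_curtis(taxon_profile(reordered))
  expect_equal(d[perm, perm], d2[perm, perm], tolerance = 1e-12)
})

test_that("PCoA embeds known geometries", {
  # three mutually equidistant samples: regular triangle, distances preserved
  d3 <- matrix(1, 3, 3, dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  diag(d3) <- 0
  ord3 <- pcoa(d3, k = 2)
  xy <- as.matrix(ord3$coordinates[, c("axis1", "axis2")])
  emb <- as.matrix(dist(xy))
  expect_equal(emb[upper.tri(emb)], rep(1, 3), tolerance = 1e-9)

  # Euclidean-embeddable matrix from known 2-D points reproduces inputs
  pts <- rbind(c(0, 0), c(0.3, 0), c(0, 0.4), c(0.3, 0.4))
  rownames(pts) <- paste0("P", 1:4)
  dE <- as.matrix(dist(pts))
  ordE <- pcoa(dE, k = 2)
  embE <- as.matrix(dist(as.matrix(ordE$coordinates[, c("axis1", "axis2")])))
  expect_equal(unname(embE), unname(dE), tolerance = 1e-9)
  expect_true(all(diff(ordE$eigenvalues) <= 1e-12))
  expect_lte(sum(ordE$variance_explained), 1 + 1e-12)

  # identical samples coincide
  d0 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  ord0 <- pcoa(d0, k = 2)
  c0 <- as.matrix(ord0$coordinates[, -1])
  expect_equal(sqrt(sum((c0[1, ] - c0[2, ])^2)), 0, tolerance = 1e-6)

  expect_error(pcoa(d3, k = 3), "k must be")
})

test_that("cohort similarity averages 1 - Bray-Curtis against target cohorts", {
  lin <- paste0("k__B|p__P|c__C|o__O|f__F|g__G|s__T", 1:4)
  tp <- taxon_profile(tibble::tibble(
    clade = rep(lin, 4),
    sample_id = rep(c("R1", "A1", "A2", "B1"), each = 4),
    abundance = c(50, 50, 0, 0,   # reference
                  50, 50, 0, 0,   # identical copy in cohort A
                  25, 25, 50, 0,  # half-overlapping in cohort A
                  0, 0, 0, 100)   # disjoint cohort B
  ))
  md <- sample_metadata(tibble::tibble(
    sample_id = c("R1", "A1", "A2", "B1"),
    diet_group = "omnivore",
    cohort = c("REF", "A", "A", "B"),
    westernized = TRUE
  ))
  cs <- cohort_similarity(tp, md, "REF")
  simA <- cs$similarity[cs$cohort == "A"]
  # BC(R1, A1) = 0, BC(R1, A2) = 0.5 -> mean similarity 0.75
  expect_equal(simA, mean(c(1, 0.5)))
  expect_equal(cs$similarity[cs$cohort == "B"], 0)
  expect_error(cohort_similarity(tp, md, "nope"), "reference cohort")
})
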