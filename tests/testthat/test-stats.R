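# exact two-sided Wilcoxon p by full enumeration of rank assignments
enumerate_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  observed <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  center <- n1 * length(b) / 2
  min(1, mean(abs(stats - center) >= abs(observed - center)))
}

test_that("Wilcoxon rank-sum matches exhaustive enumeration for small groups", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, enumerate_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$p_value, 0.1)  # 2 of the 20 assignments are as extreme

  set.seed(99)
  for (i in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    vals <- sample(1000, n1 + n2)  # untied
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, enumerate_wilcoxon_p(a, b))
  }
})

test_that("Wilcoxon degenerate and symmetry conventions hold", {
  expect_equal(wilcoxon_rank_sum(c(2, 2), c(2, 2, 2))$p_value, 1)
  a <- rlnorm(10); b <- rlnorm(12)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(b, a)$p_value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("Kruskal-Wallis H matches the rank formula", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(res$statistic, 2.4)

  same <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  g <- list(rnorm(5), rnorm(7), rnorm(4))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(rev(g))$statistic)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Dunn z scores match a hand-rank computation", {
  # groups {1,2,3}, {4,5,6}, {7,8,9}: pooled ranks equal the values,
  # mean ranks 2, 5, 8; no ties so the variance core is N(N+1)/12 = 7.5;
  # z_12 = (2-5)/sqrt(7.5 * (1/3 + 1/3)) = -3/sqrt(5)
  dn <- dunn_posthoc(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9)))
  expect_equal(dn$z, c(-3, -6, -3) / sqrt(5))
  expect_equal(dn$p_value, 2 * pnorm(-abs(dn$z)))

  # permuting the group list flips the sign of the affected pair
  dn_rev <- dunn_posthoc(list(g2 = c(4, 5, 6), g1 = c(1, 2, 3),
                              g3 = c(7, 8, 9)))
  z21 <- dn_rev$z[dn_rev$group1 == "g2" & dn_rev$group2 == "g1"]
  z12 <- dn$z[dn$group1 == "g1" & dn$group2 == "g2"]
  expect_equal(z21, -z12)

  equal_groups <- dunn_posthoc(list(a = c(1, 5, 9), b = c(1, 5, 9)))
  expect_equal(equal_groups$z, 0)
  expect_equal(equal_groups$p_value, 1)

  # tie correction: with ties the variance core shrinks
  tied <- dunn_posthoc(list(a = c(1, 1, 2), b = c(2, 3, 3)))
  N <- 6
  tie_term <- sum(sapply(c(2, 2, 2), function(t) t^3 - t)) / (12 * (N - 1))
  r <- rank(c(1, 1, 2, 2, 3, 3))
  z_hand <- (mean(r[1:3]) - mean(r[4:6])) /
    sqrt((N * (N + 1) / 12 - tie_term) * (2 / 3))
  expect_equal(tied$z[[1]], z_hand)

  expect_error(dunn_posthoc(list(1:3)), "2 groups")
  expect_error(dunn_posthoc(list(1:3, numeric(0))), "non-empty")
})

test_that("Benjamini-Hochberg step-up adjustment behaves as specified", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))

  set.seed(4)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_false(is.unsorted(adj[order(p)]))  # order-preserving

  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the cascade flags a planted four-fold vegan shift and nothing constant", {
  catalogue <- simulate_gmm_catalogue(simulation_config(seed = 31))
  eff <- tibble::tibble(module_id = "MF0003",
                        species = "s__Faecalibacterium_prausnitzii",
                        diet_group = "vegan", fold_change = 4)
  sim <- simulate_dataset(simulation_config(planted_effects = eff, seed = 31))
  sc <- score_table(sim$ko_table, sim$catalogue, strata_mode = "per_species")
  res <- suppressWarnings(
    differential_contributions(contributions(sc), sim$metadata)
  )
  hit <- res$omnibus[res$omnibus$module_id == "MF0003" &
                       res$omnibus$species == "s__Faecalibacterium_prausnitzii", ]
  expect_true(hit$significant)
  vegan_pairs <- res$pairwise[res$pairwise$module_id == "MF0003" &
                                res$pairwise$species == "s__Faecalibacterium_prausnitzii" &
                                (res$pairwise$group1 == "vegan" |
                                   res$pairwise$group2 == "vegan"), ]
  expect_equal(nrow(vegan_pairs), 3L)
  expect_true(all(vegan_pairs$significant))

  # constant contributions -> ties everywhere -> zero flags
  const <- structure(
    tibble::tibble(
      sample_id = rep(sim$metadata$sample_id, times = 2),
      module_id = "MF0001",
      species = rep(c("s__A", "s__B"), each = nrow(sim$metadata)),
      fraction = 0.5
    ),
    class = c("contribution_table", class(tibble::tibble()))
  )
  res0 <- differential_contributions(const, sim$metadata)
  expect_equal(sum(res0$omnibus$significant), 0L)
  expect_equal(nrow(res0$pairwise), 0L)
})

test_that("features with too-small groups are skipped with a warning", {
  md <- meta_for(sprintf("S%02d", 1:13),
                 c(rep("omnivore", 5), rep("pescatarian", 5),
                   rep("vegan", 2), "vegetarian"))
  set.seed(8)
  contrib <- structure(
    tibble::tibble(sample_id = md$sample_id, module_id = "MF0001",
                   species = "s__A", fraction = runif(13)),
    class = c("contribution_table", class(tibble::tibble()))
  )
  expect_warning(res <- differential_contributions(contrib, md), "skipped")
  expect_equal(nrow(res$omnibus), 0L)
  expect_equal(nrow(res$skipped), 1L)
})

test_that("per-module BH scope adjusts within modules", {
  set.seed(12)
  md <- meta_for(sprintf("S%02d", 1:40), rep(diet_levels, each = 10))
  contrib <- structure(
    tidyr::expand_grid(
      module_id = c("MF0001", "MF0002"),
      species = paste0("s__sp", 1:4),
      sample_id = md$sample_id
    ) |>
      dplyr::mutate(fraction = runif(dplyr::n())),
    class = c("contribution_table", class(tibble::tibble()))
  )
  res_g <- differential_contributions(contrib, md, bh_scope = "global")
  res_m <- differential_contributions(contrib, md, bh_scope = "per_module")
  expect_equal(res_g$omnibus$p_value, res_m$omnibus$p_value)
  m1 <- res_m$omnibus[res_m$omnibus$module_id == "MF0001", ]
  expect_equal(m1$p_adj, benjamini_hochberg(m1$p_value))
})

test_that("tidy and glance summarise a cascade result", {
  res <- simulate_null_contributions(n_features = 12, n_per_group = 8,
                                     seed = 3)
  fit <- differential_contributions(res$contrib, res$metadata)
  td <- tidy(fit)
  expect_true(all(c("module_id", "species", "test", "statistic",
                    "p_value", "p_adj", "significant") %in% names(td)))
  expect_equal(sum(td$test == "kruskal_wallis"), 12L)
  gl <- glance(fit)
  expect_equal(gl$n_features, 12L)
  expect_equal(gl$alpha, 0.05)
})
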