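#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-values for small untied groups, normal approximation with
#' continuity correction otherwise (the defaults of [stats::wilcox.test()]).
#' When every value in both groups is identical the test is degenerate and
#' p = 1 by convention.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return List with `statistic` (rank-sum W) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) abort("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  fit <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(fit$statistic), p_value = min(fit$p.value, 1))
}

#' Kruskal-Wallis omnibus test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' (number of groups - 1) degrees of freedom. When all values are identical
#' H = 0 and p = 1.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   non-empty).
#' @return List with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) abort("need at least 2 groups")
  if (any(lengths(groups) < 1L)) abort("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::kruskal.test(values, g)
  list(statistic = unname(fit$statistic), p_value = unname(fit$p.value))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Rank-based pairwise z tests on the pooled ranks following a significant
#' Kruskal-Wallis omnibus test:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with the
#' tie term T = sum(t^3 - t) / (12 (N - 1)) over tie groups of size t; ties
#' receive average ranks; p-values are two-sided normal.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2,
#'   each non-empty).
#' @return Tibble with columns `group1`, `group2`, `z`, `p_value`, one row
#'   per unordered pair (in list order).
#' @export
dunn_posthoc <- function(groups) {
  if (length(groups) < 2L) abort("need at least 2 groups")
  if (any(lengths(groups) < 1L)) abort("every group must be non-empty")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  n_i <- lengths(groups)
  N <- length(values)
  r <- rank(values)  # average ranks for ties
  idx <- rep(seq_along(groups), n_i)
  rbar <- tapply(r, idx, mean)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(seq_along(groups), 2)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_core * (1 / n_i[[i]] + 1 / n_i[[j]]))
    if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
  }, numeric(1))
  tibble(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    z = z,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: adj_i = min over j >= rank(i) of m * p_(j) / j,
#' clipped at 1; stable under ties and idempotent.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   preserved).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential species contributions across diet groups
#'
#' The test cascade for (module, species) contribution features: per
#' feature, a tie-corrected Kruskal-Wallis test across the four diet groups;
#' Benjamini-Hochberg adjustment of the omnibus p-values (across all
#' features, or within each module when `bh_scope = "per_module"`); for
#' features significant at `alpha`, Dunn's pairwise tests between diet
#' groups, BH-adjusted within the feature. Samples with undefined
#' contributions (the module absent from the sample) are excluded per
#' feature, never imputed; the UNCLASSIFIED stratum is not tested.
#'
#' @param contrib A [contributions()] tibble.
#' @param metadata A [sample_metadata()] tibble covering all samples.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param bh_scope Family for the omnibus BH adjustment: `"global"` (all
#'   features, default) or `"per_module"`.
#' @param min_group_size Features where any diet group has fewer usable
#'   samples than this are skipped with a warning (default 3).
#' @return A `contrib_test` object: list with tibbles `omnibus` (module_id,
#'   species, n_samples, statistic, p_value, p_adj, significant) and
#'   `pairwise` (module_id, species, group1, group2, z, p_value, p_adj,
#'   significant; only for significant features), plus `alpha`, `bh_scope`
#'   and `skipped` (features dropped for small groups).
#' @export
differential_contributions <- function(contrib, metadata, alpha = 0.05,
                                       bh_scope = c("global", "per_module"),
                                       min_group_size = 3L) {
  bh_scope <- match.arg(bh_scope)
  meta <- match_metadata(unique(contrib$sample_id), metadata)
  groups_present <- sort(unique(meta$diet_group))
  if (length(groups_present) < 2L) abort("need at least 2 diet groups")

  dat <- as_tibble(contrib) |>
    filter(.data$species != STRATUM_UNCLASSIFIED, !is.na(.data$fraction)) |>
    left_join(as_tibble(metadata)[, c("sample_id", "diet_group")],
              by = "sample_id")

  nested <- dat |>
    group_by(.data$module_id, .data$species) |>
    tidyr::nest() |>
    ungroup()

  run_one <- function(df) {
    split(df$fraction, factor(df$diet_group, levels = groups_present))
  }
  res <- purrr::map(nested$data, function(df) {
    g <- run_one(df)
    if (any(lengths(g) < min_group_size)) {
      return(list(skip = TRUE))
    }
    kw <- kruskal_wallis(g)
    list(skip = FALSE, n = nrow(df), statistic = kw$statistic,
         p_value = kw$p_value, groups = g)
  })
  skip <- vapply(res, `[[`, logical(1), "skip")
  if (any(skip)) {
    warn(paste0(sum(skip), " feature(s) skipped: a diet group has fewer than ",
                min_group_size, " usable samples"))
  }
  keep <- nested[!skip, ]
  res <- res[!skip]

  omnibus <- tibble(
    module_id = keep$module_id,
    species = keep$species,
    n_samples = vapply(res, `[[`, numeric(1), "n"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value")
  )
  if (bh_scope == "global") {
    omnibus$p_adj <- benjamini_hochberg(omnibus$p_value)
  } else {
    omnibus <- omnibus |>
      group_by(.data$module_id) |>
      mutate(p_adj = benjamini_hochberg(.data$p_value)) |>
      ungroup()
  }
  omnibus$significant <- omnibus$p_adj < alpha

  pairwise <- purrr::map_dfr(which(omnibus$significant), function(i) {
    dn <- dunn_posthoc(res[[i]]$groups)
    dn$p_adj <- benjamini_hochberg(dn$p_value)
    dplyr::bind_cols(
      tibble(module_id = omnibus$module_id[[i]],
             species = omnibus$species[[i]])[rep(1, nrow(dn)), ],
      dn
    ) |>
      mutate(significant = .data$p_adj < alpha)
  })
  if (nrow(pairwise) == 0L) {
    pairwise <- tibble(module_id = character(), species = character(),
                       group1 = character(), group2 = character(),
                       z = numeric(), p_value = numeric(), p_adj = numeric(),
                       significant = logical())
  }

  structure(list(omnibus = omnibus, pairwise = pairwise, alpha = alpha,
                 bh_scope = bh_scope,
                 skipped = nested[skip, c("module_id", "species")]),
            class = "contrib_test")
}

#' @export
print.contrib_test <- function(x, ...) {
  cat("Differential contribution test cascade\n")
  cat("  features tested:     ", nrow(x$omnibus), "\n")
  cat("  significant (adj p < ", x$alpha, "): ", sum(x$omnibus$significant),
      "\n", sep = "")
  cat("  BH scope:            ", x$bh_scope, "\n")
  if (nrow(x$skipped) > 0) {
    cat("  skipped (small groups):", nrow(x$skipped), "\n")
  }
  invisible(x)
}
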