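#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the results of a differential-contribution cascade
#'
#' Binds omnibus and pairwise results into one long tibble with a `test`
#' column (`"kruskal_wallis"` or `"dunn"`); pairwise rows carry `group1` /
#' `group2`, omnibus rows leave them `NA`.
#'
#' @param x A `contrib_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.contrib_test <- function(x, ...) {
  omni <- x$omnibus |>
    mutate(test = "kruskal_wallis", group1 = NA_character_,
           group2 = NA_character_) |>
    select("module_id", "species", "test", "group1", "group2",
           statistic = "statistic", "p_value", "p_adj", "significant")
  pair <- x$pairwise |>
    mutate(test = "dunn") |>
    select("module_id", "species", "test", "group1", "group2",
           statistic = "z", "p_value", "p_adj", "significant")
  bind_rows(omni, pair)
}

#' One-row summary of a differential-contribution cascade
#'
#' @param x A `contrib_test` object.
#' @param ... Unused.
#' @return Tibble with feature counts and significance tallies.
#' @export
glance.contrib_test <- function(x, ...) {
  tibble(
    n_features = nrow(x$omnibus),
    n_significant = sum(x$omnibus$significant),
    n_pairs_significant = sum(x$pairwise$significant),
    n_skipped = nrow(x$skipped),
    alpha = x$alpha,
    bh_scope = x$bh_scope
  )
}

#' Tidy PCoA coordinates
#'
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return The coordinates tibble (`sample_id`, `axis1`, ...).
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' One-row summary of a PCoA
#'
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return Tibble with axis count and cumulative variance explained.
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(
    k = ncol(x$coordinates) - 1L,
    variance_explained = sum(x$variance_explained),
    n_negative_eigenvalues = sum(x$eigenvalues < 0)
  )
}
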