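#' Per-species relative contributions to module abundances
#'
#' For every (sample, module), each stratum's contribution is its module
#' abundance divided by the sum of module abundances over all strata
#' (species plus UNCLASSIFIED; the TOTAL stratum is excluded from both
#' numerator and denominator so fractions are exactly normalised). When no
#' stratum has positive abundance the fractions are undefined and returned
#' as `NA`.
#'
#' @param scores A per-species `module_scores` tibble from
#'   [score_table()] (`strata_mode = "per_species"`).
#' @return A `contribution_table` tibble with columns `sample_id`,
#'   `module_id`, `species` (a species stratum or UNCLASSIFIED) and
#'   `fraction`; per (sample, module) with positive total, fractions sum
#'   to 1.
#' @export
contributions <- function(scores) {
  if (any(scores$abundance < 0)) abort("negative module abundance")
  strat <- scores[scores$stratum != STRATUM_TOTAL, ]
  if (nrow(strat) == 0L) {
    abort("no species strata in module scores; run score_table(strata_mode = \"per_species\")")
  }
  out <- strat |>
    group_by(.data$sample_id, .data$module_id) |>
    mutate(total = sum(.data$abundance)) |>
    ungroup() |>
    mutate(fraction = ifelse(.data$total > 0,
                             .data$abundance / .data$total, NA_real_)) |>
    select("sample_id", "module_id", species = "stratum", "fraction")
  structure(out, class = c("contribution_table", class(tibble())))
}
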