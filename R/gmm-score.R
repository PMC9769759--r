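#' Module scoring configuration
#'
#' Controls the rule-based scorer: a module's abundance in a sample (or a
#' species stratum of a sample) is the `step_aggregation` (default median)
#' over its step abundances, where each step abundance is the sum over the
#' step's alternatives of the minimum over complex members. Coverage is the
#' fraction of steps with positive abundance; modules whose coverage falls
#' below `coverage_cutoff` report abundance 0 (their true coverage is still
#' reported, so cutoff sensitivity can be examined).
#'
#' @param coverage_cutoff Minimum fraction of steps (in `[0, 1]`) that must
#'   have positive abundance for the module to be scored; default 0.66.
#' @param step_aggregation How step abundances are combined: `"median"`
#'   (default) or `"mean"`.
#' @return A `module_scoring_config` list. The within-step rules (sum over
#'   alternatives, min over complex members) are fixed.
#' @export
module_scoring_config <- function(coverage_cutoff = 0.66,
                                  step_aggregation = c("median", "mean")) {
  stopifnot_scalar_number(coverage_cutoff, "coverage_cutoff", 0, 1)
  step_aggregation <- match.arg(step_aggregation)
  structure(list(coverage_cutoff = coverage_cutoff,
                 step_aggregation = step_aggregation,
                 alternative_aggregation = "sum",
                 complex_aggregation = "min"),
            class = "module_scoring_config")
}

#' Score a single reaction step
#'
#' A step is satisfiable by any of its alternatives; an alternative with
#' several KOs is an orthologue complex limited by its scarcest member. The
#' step abundance is therefore the sum over alternatives of the minimum over
#' each alternative's members. KOs absent from `ko_abundances` count as 0.
#'
#' @param step List of character vectors (alternatives; complexes have
#'   length > 1).
#' @param ko_abundances Named numeric vector of KO abundances.
#' @return Step abundance (scalar).
#' @export
#' @examples
#' score_step(list("K00002", c("K00003", "K00004")),
#'            c(K00002 = 2, K00003 = 4, K00004 = 1))
score_step <- function(step, ko_abundances) {
  val <- 0
  for (alt in step) {
    v <- ko_abundances[alt]
    v[is.na(v)] <- 0
    val <- val + min(v)
  }
  unname(val)
}

#' Score one module against a KO abundance vector
#'
#' @param steps Ordered list of steps (see [score_step()]), or a one-row
#'   slice of a [gmm_catalogue()] `steps` entry.
#' @param ko_abundances Named numeric vector of KO abundances.
#' @param config A [module_scoring_config()].
#' @return List with elements `abundance` and `coverage`.
#' @export
score_module <- function(steps, ko_abundances,
                         config = module_scoring_config()) {
  vals <- vapply(steps, score_step, numeric(1), ko_abundances = ko_abundances)
  coverage <- mean(vals > 0)
  agg <- switch(config$step_aggregation,
                median = median(vals),
                mean = mean(vals))
  abundance <- if (coverage >= config$coverage_cutoff) agg else 0
  list(abundance = abundance, coverage = coverage)
}

# column medians via one order() pass; agrees with stats::median (even row
# counts average the two middle order statistics with long-double summation)
col_medians <- function(m) {
  k <- nrow(m)
  if (k == 1L) return(m[1, ])
  o <- order(col(m), m)
  ms <- matrix(m[o], nrow = k)
  if (k %% 2L == 1L) {
    ms[(k + 1L) %/% 2L, ]
  } else {
    colMeans(ms[c(k %/% 2L, k %/% 2L + 1L), , drop = FALSE])
  }
}

#' Score a module catalogue over a stratified KO table
#'
#' In `"total"` mode each sample is scored from its TOTAL rows. In
#' `"per_species"` mode every stratum (each species, UNCLASSIFIED, and
#' TOTAL) is scored independently from its own KO rows: a species lacking a
#' module's steps gets no credit for the module, and the TOTAL stratum is
#' scored from the TOTAL rows rather than as a sum of species scores.
#'
#' @param ko_table A [stratified_ko()] tibble.
#' @param catalogue A [gmm_catalogue()] tibble (non-empty).
#' @param config A [module_scoring_config()].
#' @param strata_mode `"total"` or `"per_species"`.
#' @param extra_species Optional character vector of strata to include in the
#'   output even if they have no KO rows (scored 0, coverage 0).
#' @return A `module_scores` tibble with columns `sample_id`, `module_id`,
#'   `stratum`, `abundance`, `coverage`.
#' @export
score_table <- function(ko_table, catalogue,
                        config = module_scoring_config(),
                        strata_mode = c("total", "per_species"),
                        extra_species = NULL) {
  strata_mode <- match.arg(strata_mode)
  if (!inherits(catalogue, "gmm_catalogue")) catalogue <- gmm_catalogue(catalogue)
  if (nrow(catalogue) == 0L) abort("empty module catalogue")

  samples <- sample_ids(ko_table)
  if (strata_mode == "total") {
    strata <- STRATUM_TOTAL
  } else {
    strata <- unique(c(setdiff(unique(ko_table$stratum), STRATUM_TOTAL),
                       STRATUM_UNCLASSIFIED, extra_species, STRATUM_TOTAL))
  }
  sub <- ko_table[ko_table$stratum %in% strata, ]

  kos <- catalogue_kos(catalogue)
  # KO x (sample, stratum) value matrix; KOs outside the catalogue are ignored
  ncols <- length(samples) * length(strata)
  col_of <- function(sample, stratum) {
    (match(stratum, strata) - 1L) * length(samples) + match(sample, samples)
  }
  m <- matrix(0, nrow = length(kos), ncol = ncols)
  keep <- sub$ko %in% kos
  m[cbind(match(sub$ko[keep], kos), col_of(sub$sample_id[keep], sub$stratum[keep]))] <-
    sub$rpk[keep]

  row_or_zero <- function(ko) {
    i <- match(ko, kos)
    if (is.na(i)) numeric(ncols) else m[i, ]
  }

  res <- vector("list", nrow(catalogue))
  for (j in seq_len(nrow(catalogue))) {
    steps <- catalogue$steps[[j]]
    step_vals <- matrix(0, nrow = length(steps), ncol = ncols)
    for (s in seq_along(steps)) {
      sv <- numeric(ncols)
      for (alt in steps[[s]]) {
        av <- row_or_zero(alt[[1]])
        for (member in alt[-1]) av <- pmin(av, row_or_zero(member))
        sv <- sv + av
      }
      step_vals[s, ] <- sv
    }
    coverage <- colMeans(step_vals > 0)
    agg <- switch(config$step_aggregation,
                  median = col_medians(step_vals),
                  mean = colMeans(step_vals))
    abundance <- ifelse(coverage >= config$coverage_cutoff, agg, 0)
    res[[j]] <- tibble(
      sample_id = rep(samples, times = length(strata)),
      module_id = catalogue$module_id[[j]],
      stratum = rep(strata, each = length(samples)),
      abundance = abundance,
      coverage = coverage
    )
  }
  out <- bind_rows(res)
  structure(out, class = c("module_scores", class(tibble())), config = config)
}
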