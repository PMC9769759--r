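#' Configuration for bootstrap core-microbiota detection
#'
#' Defaults follow the usual core definition for stool metagenomes: a taxon
#' is detected in a sample when its relative abundance (as a fraction of the
#' sample) strictly exceeds `min_relative_abundance` (default 1e-6, i.e.
#' 0.0001%); it qualifies in a bootstrap resample when detected in at least
#' `min_prevalence` (default 75%) of the resampled samples; it is core when
#' it qualifies in at least `bootstrap_retention` (default all) of
#' `n_bootstraps` (default 100) resamples.
#'
#' @param min_relative_abundance Detection threshold as a fraction in
#'   `[0, 1]`.
#' @param min_prevalence Prevalence threshold as a fraction in `[0, 1]`.
#' @param n_bootstraps Number of bootstrap resamples (>= 1).
#' @param bootstrap_retention Fraction of bootstraps in which a taxon must
#'   qualify.
#' @param seed Integer seed for the resampling RNG.
#' @return A `core_config` list.
#' @export
core_config <- function(min_relative_abundance = 1e-6,
                        min_prevalence = 0.75,
                        n_bootstraps = 100,
                        bootstrap_retention = 1,
                        seed = 1L) {
  stopifnot_scalar_number(min_relative_abundance, "min_relative_abundance", 0, 1)
  stopifnot_scalar_number(min_prevalence, "min_prevalence", 0, 1)
  stopifnot_scalar_number(bootstrap_retention, "bootstrap_retention", 0, 1)
  stopifnot_scalar_number(n_bootstraps, "n_bootstraps", 1)
  structure(list(min_relative_abundance = min_relative_abundance,
                 min_prevalence = min_prevalence,
                 n_bootstraps = as.integer(n_bootstraps),
                 bootstrap_retention = bootstrap_retention,
                 seed = as.integer(seed)),
            class = "core_config")
}

#' Bootstrap detection of core taxa
#'
#' Samples are resampled with replacement (same n) `n_bootstraps` times;
#' in each resample a taxon qualifies if its prevalence at the detection
#' threshold reaches `min_prevalence`. Taxa qualifying in at least
#' `bootstrap_retention` of resamples are core. Each sample is renormalised
#' to proportions before thresholding, so percent and proportion tables
#' behave identically. Deterministic under a fixed `config$seed`.
#'
#' @param profile A species-rank [taxon_profile()] tibble (clades at other
#'   ranks are dropped).
#' @param config A [core_config()].
#' @return A `core_result` tibble with columns `clade`, `prevalence`
#'   (observed, full cohort), `bootstrap_fraction` and `is_core`; the config
#'   is attached as an attribute.
#' @export
core_taxa <- function(profile, config = core_config()) {
  sub <- extract_rank(profile, "species")
  if (nrow(sub) == 0L) abort("no species-rank clades in profile")
  m <- taxa_matrix(sub)  # samples x taxa
  n <- nrow(m)
  if (n < 2L) abort("core detection needs at least 2 samples")
  detected <- (m / rowSums(m)) > config$min_relative_abundance

  set.seed(config$seed)
  qualify <- matrix(FALSE, nrow = config$n_bootstraps, ncol = ncol(m))
  for (b in seq_len(config$n_bootstraps)) {
    idx <- sample.int(n, n, replace = TRUE)
    prev <- colMeans(detected[idx, , drop = FALSE])
    qualify[b, ] <- prev >= config$min_prevalence
  }
  frac <- colMeans(qualify)
  out <- tibble(
    clade = colnames(m),
    prevalence = unname(colMeans(detected)),
    bootstrap_fraction = unname(frac),
    is_core = unname(frac >= config$bootstrap_retention)
  )
  structure(out, class = c("core_result", class(tibble())), config = config)
}

#' Overlap between the core sets of two cohorts
#'
#' Reports the shared core taxa and the overlap fraction under three
#' denominators (union, cohort A's core, cohort B's core), since "x (y%)
#' shared" statements are ambiguous about the denominator.
#'
#' @param core_a,core_b `core_result` tibbles from [core_taxa()] on a common
#'   taxonomy.
#' @return List with `taxa` (intersection), `n_shared`, `union_fraction`
#'   (|A n B| / |A u B|), `fraction_of_a`, `fraction_of_b`.
#' @export
shared_core <- function(core_a, core_b) {
  a <- core_a$clade[core_a$is_core]
  b <- core_b$clade[core_b$is_core]
  both <- intersect(a, b)
  uni <- union(a, b)
  list(
    taxa = both,
    n_shared = length(both),
    union_fraction = if (length(uni) == 0) 0 else length(both) / length(uni),
    fraction_of_a = if (length(a) == 0) 0 else length(both) / length(a),
    fraction_of_b = if (length(b) == 0) 0 else length(both) / length(b)
  )
}
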