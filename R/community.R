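#' Restrict a taxon profile to clades terminating at one rank
#'
#' @param profile A [taxon_profile()] tibble.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return A `taxon_profile` tibble containing only clades whose deepest
#'   segment is at `rank`; values unchanged. May be empty.
#' @export
extract_rank <- function(profile, rank) {
  if (!rank %in% names(RANK_PREFIXES)) {
    abort(paste0("unknown rank '", rank, "'"))
  }
  out <- profile[clade_rank(profile$clade) == rank, ]
  structure(as_tibble(out), class = class(profile))
}

#' Per-sample abundance ratio of two clades
#'
#' Computes, per sample, numerator / denominator abundance — e.g. the
#' Firmicutes/Bacteroidetes ratio at phylum rank or the
#' Prevotella/Bacteroides ratio at genus rank. The ratio is scale-invariant,
#' so percent and proportion tables give identical results.
#'
#' @param profile A [taxon_profile()] tibble.
#' @param numerator,denominator Clade strings (must terminate at the same
#'   rank and be present in the table).
#' @param zero_policy What to do when the denominator is 0: `"undefined"`
#'   (default; ratio is `NA` and `defined` is `FALSE`) or `"pseudocount"`
#'   (add `epsilon` to both terms).
#' @param epsilon Pseudocount used when `zero_policy = "pseudocount"`.
#' @return Tibble with columns `sample_id`, `numerator`, `denominator`,
#'   `ratio`, `defined`.
#' @export
taxon_ratio <- function(profile, numerator, denominator,
                        zero_policy = c("undefined", "pseudocount"),
                        epsilon = 1e-6) {
  zero_policy <- match.arg(zero_policy)
  for (clade in c(numerator, denominator)) {
    if (!clade %in% profile$clade) {
      abort(paste0("clade not present in profile: '", clade, "'"))
    }
  }
  if (clade_rank(numerator) != clade_rank(denominator)) {
    abort("numerator and denominator must terminate at the same rank")
  }
  samples <- sample_ids(profile)
  val_of <- function(clade) {
    sub <- profile[profile$clade == clade, ]
    v <- setNames(rep(0, length(samples)), samples)
    v[sub$sample_id] <- sub$abundance
    v
  }
  num <- val_of(numerator)
  den <- val_of(denominator)
  if (zero_policy == "pseudocount") {
    ratio <- (num + epsilon) / (den + epsilon)
    defined <- rep(TRUE, length(samples))
  } else {
    defined <- den > 0
    ratio <- ifelse(defined, num / den, NA_real_)
  }
  tibble(sample_id = samples, numerator = unname(num),
         denominator = unname(den), ratio = unname(ratio),
         defined = unname(defined))
}

#' Per-sample summed abundance of a list of families
#'
#' Used for VANISH taxa (families volatile and/or negatively associated with
#' industrialised societies: Succinivibrionaceae, Paraprevotellaceae,
#' Prevotellaceae, Spirochaetaceae) and user-supplied BloSSUM lists. A family
#' absent from the table is reported with abundance 0, not dropped.
#'
#' @param profile A [taxon_profile()] tibble.
#' @param families Character vector of family names (without the `f__`
#'   prefix).
#' @return Tibble with columns `sample_id`, `family`, `abundance`.
#' @export
aggregate_families <- function(profile, families) {
  fam_rows <- profile[clade_rank(profile$clade) == "family", ]
  fam_rows$family <- clade_label(fam_rows$clade)
  samples <- sample_ids(profile)
  grid <- tidyr::expand_grid(sample_id = samples, family = families)
  sums <- fam_rows |>
    filter(.data$family %in% families) |>
    group_by(.data$sample_id, .data$family) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop")
  grid |>
    left_join(sums, by = c("sample_id", "family")) |>
    mutate(abundance = tidyr::replace_na(.data$abundance, 0))
}

#' Default VANISH family list
#' @return Character vector of the four VANISH families.
#' @export
vanish_families <- function() {
  c("Succinivibrionaceae", "Paraprevotellaceae", "Prevotellaceae",
    "Spirochaetaceae")
}

#' Bray-Curtis dissimilarity between samples
#'
#' Profiles are restricted to `rank` and each sample renormalised to sum 1
#' before computing BC(x, y) = sum|x - y| / sum(x + y), so tables with
#' unequal unclassified mass are comparable.
#'
#' @param profile A [taxon_profile()] tibble.
#' @param rank Taxonomic rank at which to compare (default `"species"`).
#' @return A symmetric `dist_matrix` (base `matrix` with samples as
#'   dimnames), entries in `[0, 1]`, zero diagonal.
#' @export
bray_curtis <- function(profile, rank = "species") {
  sub <- extract_rank(profile, rank)
  m <- taxa_matrix(sub)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    abort(paste0("all-zero sample at rank ", rank, ": '",
                 rownames(m)[totals <= 0][[1]], "'"))
  }
  m <- m / totals
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' Classical principal-coordinates analysis of a distance matrix
#'
#' Performs metric multidimensional scaling (Gower's PCoA). Negative
#' eigenvalues, which arise because Bray-Curtis is not Euclidean, are
#' clamped to zero when reporting the proportion of variance explained; no
#' correction is applied to the coordinates.
#'
#' @param d A square symmetric distance matrix with sample dimnames (e.g.
#'   from [bray_curtis()]).
#' @param k Number of axes to return (default 2).
#' @return A `pcoa_result` list: `coordinates` (tibble `sample_id`,
#'   `axis1`..`axisk`), `eigenvalues` (all, decreasing) and
#'   `variance_explained` (per returned axis, sums to <= 1).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 1 || k > n - 1) {
    abort(paste0("k must be between 1 and ", n - 1, " (n samples - 1)"))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- pmax(eig, 0)
  coords <- fit$points
  # cmdscale drops trailing zero-variance axes; pad so k columns always exist
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, nrow = n, ncol = k - ncol(coords)))
  }
  coord_tbl <- as_tibble(coords, .name_repair = ~ paste0("axis", seq_len(k)))
  coord_tbl <- dplyr::bind_cols(tibble(sample_id = rownames(d)), coord_tbl)
  structure(list(
    coordinates = coord_tbl,
    eigenvalues = eig,
    variance_explained = pos[seq_len(k)] / sum(pos)
  ), class = "pcoa_result")
}

#' Mean similarity of reference samples to other cohorts
#'
#' For each sample of the reference cohort, computes 1 - Bray-Curtis
#' similarity to every sample of each other cohort and averages within
#' cohort — the per-sample similarity profile used to compare a study
#' population against external westernized and non-westernized cohorts.
#' Profiles are aligned on the union of taxa (absent taxa count as 0).
#'
#' @param profile A [taxon_profile()] covering all cohorts.
#' @param metadata A [sample_metadata()] tibble.
#' @param reference_cohort Cohort label of the reference samples.
#' @param rank Rank at which to compare (default `"species"`).
#' @return Tibble with columns `sample_id` (reference sample), `cohort`
#'   (target cohort) and `similarity` (mean 1 - BC).
#' @export
cohort_similarity <- function(profile, metadata, reference_cohort,
                              rank = "species") {
  meta <- match_metadata(sample_ids(profile), metadata)
  if (!reference_cohort %in% meta$cohort) {
    abort(paste0("no samples in reference cohort '", reference_cohort, "'"))
  }
  others <- setdiff(unique(meta$cohort), reference_cohort)
  if (length(others) == 0L) abort("no non-reference cohorts present")
  d <- bray_curtis(profile, rank = rank)
  ref <- meta$sample_id[meta$cohort == reference_cohort]
  purrr::map_dfr(others, function(coh) {
    target <- meta$sample_id[meta$cohort == coh]
    tibble(sample_id = ref, cohort = coh,
           similarity = unname(rowMeans(1 - d[ref, target, drop = FALSE])))
  })
}
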