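#' Construct and validate a taxonomic profile table
#'
#' A taxon profile is a long tibble with columns `clade` (rank-prefixed,
#' pipe-delimited lineage), `sample_id` and `abundance` (relative abundance in
#' percent, 0-100). Clades at every rank may coexist (as in MetaPhlAn output);
#' [extract_rank()] selects one rank.
#'
#' Invariants enforced: no negative abundance; per sample, abundances at any
#' single rank sum to at most 100 (tolerance 1e-6); one row per
#' (clade, sample).
#'
#' @param data Data frame with columns `clade`, `sample_id`, `abundance`.
#' @return A `taxon_profile` tibble.
#' @export
taxon_profile <- function(data) {
  data <- as_tibble(data)
  req <- c("clade", "sample_id", "abundance")
  if (!all(req %in% names(data))) {
    abort("taxon profile needs columns clade, sample_id, abundance")
  }
  data <- data[, req]
  check_lineages(unique(data$clade))
  if (any(data$abundance < 0)) {
    bad <- data[data$abundance < 0, ][1, ]
    abort(paste0("negative abundance for clade '", bad$clade,
                 "' in sample '", bad$sample_id, "'"))
  }
  if (anyDuplicated(data[, c("clade", "sample_id")])) {
    abort("duplicate (clade, sample) rows in taxon profile")
  }
  rank_sums <- data |>
    mutate(rank = clade_rank(.data$clade)) |>
    group_by(.data$sample_id, .data$rank) |>
    summarise(total = sum(.data$abundance), .groups = "drop")
  if (any(rank_sums$total > 100 + 1e-6)) {
    bad <- rank_sums[rank_sums$total > 100 + 1e-6, ][1, ]
    abort(paste0("abundances at rank ", bad$rank, " sum to ", bad$total,
                 " (> 100) in sample '", bad$sample_id, "'"))
  }
  structure(data, class = c("taxon_profile", class(tibble())))
}

#' Read a MetaPhlAn-style taxonomic profile
#'
#' Expects a tab-separated file whose first column (`clade_name`) holds
#' lineage strings and whose remaining columns are samples; values are
#' relative abundances in percent. Lines starting with `#` are comments.
#'
#' @param path Path to a TSV file.
#' @return A [taxon_profile()] tibble.
#' @export
read_taxon_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(wide) < 2L) abort("taxon profile file needs a clade column and at least one sample column")
  names(wide)[1] <- "clade"
  long <- tidyr::pivot_longer(wide, -"clade",
                              names_to = "sample_id", values_to = "abundance")
  taxon_profile(long)
}

#' Write a taxonomic profile as MetaPhlAn-style TSV
#'
#' @param x A `taxon_profile` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxon_profile <- function(x, path) {
  wide <- tidyr::pivot_wider(as_tibble(x), names_from = "sample_id",
                             values_from = "abundance", values_fill = 0)
  names(wide)[1] <- "clade_name"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Samples present in a profile or KO table
#' @param x A `taxon_profile` or `stratified_ko` tibble.
#' @return Character vector of sample ids, in first-appearance order.
#' @export
sample_ids <- function(x) unique(x$sample_id)

# samples x clades abundance matrix (zero-filled)
taxa_matrix <- function(x, samples = sample_ids(x)) {
  clades <- unique(x$clade)
  m <- matrix(0, nrow = length(samples), ncol = length(clades),
              dimnames = list(samples, clades))
  m[cbind(match(x$sample_id, samples), match(x$clade, clades))] <- x$abundance
  m
}
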