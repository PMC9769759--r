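#' Construct and validate a stratified KO abundance table
#'
#' A stratified KO table is a long tibble with columns `ko` (KEGG orthologue,
#' `K` + 5 digits), `stratum` (a species lineage, [STRATUM_UNCLASSIFIED] or
#' [STRATUM_TOTAL]), `sample_id` and `rpk` (reads per kilobase,
#' non-negative). The TOTAL row of a KO carries its community-wide abundance
#' and may exceed the sum of its strata (unmapped mass), but never fall short
#' of it by more than the tolerance.
#'
#' @param data Data frame with columns `ko`, `stratum`, `sample_id`, `rpk`.
#' @param synthesize_total If `TRUE`, KOs lacking a TOTAL row get one,
#'   computed as the sum of their strata; these KOs are recorded in the
#'   `synthesized_total` attribute.
#' @param tol Tolerance for the TOTAL-vs-strata consistency check.
#' @return A `stratified_ko` tibble.
#' @export
stratified_ko <- function(data, synthesize_total = TRUE, tol = 1e-6) {
  data <- as_tibble(data)
  req <- c("ko", "stratum", "sample_id", "rpk")
  if (!all(req %in% names(data))) {
    abort("stratified KO table needs columns ko, stratum, sample_id, rpk")
  }
  data <- data[, req]
  bad_ko <- !is_ko_id(data$ko)
  if (any(bad_ko)) {
    abort(paste0("invalid KO id: '", data$ko[bad_ko][[1]], "'"))
  }
  if (any(data$rpk < 0)) abort("negative RPK value in stratified KO table")
  if (anyDuplicated(data[, c("ko", "stratum", "sample_id")])) {
    abort("duplicate (ko, stratum) rows in stratified KO table")
  }

  synthesized <- character(0)
  has_total <- unique(data$ko[data$stratum == STRATUM_TOTAL])
  missing_total <- setdiff(unique(data$ko), has_total)
  if (length(missing_total) > 0) {
    if (!synthesize_total) {
      abort(paste0("KO without TOTAL row: ", missing_total[[1]]))
    }
    totals <- data |>
      filter(.data$ko %in% missing_total) |>
      group_by(.data$ko, .data$sample_id) |>
      summarise(rpk = sum(.data$rpk), .groups = "drop") |>
      mutate(stratum = STRATUM_TOTAL)
    data <- bind_rows(data, totals[, req])
    synthesized <- missing_total
  }

  chk <- data |>
    mutate(part = ifelse(.data$stratum == STRATUM_TOTAL, "total", "strat")) |>
    group_by(.data$ko, .data$sample_id, .data$part) |>
    summarise(rpk = sum(.data$rpk), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "part", values_from = "rpk",
                       values_fill = 0)
  if (!"strat" %in% names(chk)) chk$strat <- 0
  short <- chk$total < chk$strat - tol
  if (any(short)) {
    bad <- chk[short, ][1, ]
    abort(paste0("stratified rows of ", bad$ko, " in sample '", bad$sample_id,
                 "' sum to ", bad$strat, " but TOTAL is ", bad$total))
  }
  structure(data, class = c("stratified_ko", class(tibble())),
            synthesized_total = synthesized)
}

# fast internal constructor: caller guarantees the invariants (used by the
# generator, whose output is checked against the full validator in tests)
new_stratified_ko <- function(data, synthesized = character(0)) {
  structure(data, class = c("stratified_ko", class(tibble())),
            synthesized_total = synthesized)
}

#' Read a HUMAnN-style stratified gene-family table
#'
#' Row names are `"K00001"` (community total) or `"K00001|<stratum>"`, where
#' the stratum is a species lineage or the literal `unclassified` (normalised
#' to [STRATUM_UNCLASSIFIED]); values are RPK. KOs without an unstratified
#' row get a TOTAL row synthesised as the sum of their strata.
#'
#' @param path Path to a TSV file (first column row names, then samples).
#' @return A [stratified_ko()] tibble.
#' @export
read_stratified_ko_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(wide) < 2L) abort("KO table file needs a row-name column and at least one sample column")
  names(wide)[1] <- "row"
  parts <- stringr::str_split_fixed(wide$row, stringr::fixed("|"), 2)
  wide$ko <- parts[, 1]
  wide$stratum <- ifelse(parts[, 2] == "", STRATUM_TOTAL,
                         ifelse(parts[, 2] == "unclassified",
                                STRATUM_UNCLASSIFIED, parts[, 2]))
  long <- wide |>
    select(-"row") |>
    tidyr::pivot_longer(-c("ko", "stratum"),
                        names_to = "sample_id", values_to = "rpk")
  stratified_ko(long)
}

#' Write a stratified KO table as HUMAnN-style TSV
#'
#' @param x A `stratified_ko` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stratified_ko_table <- function(x, path) {
  rows <- as_tibble(x) |>
    mutate(row = dplyr::case_when(
      .data$stratum == STRATUM_TOTAL ~ .data$ko,
      .data$stratum == STRATUM_UNCLASSIFIED ~ paste0(.data$ko, "|unclassified"),
      TRUE ~ paste0(.data$ko, "|", .data$stratum)
    )) |>
    select("row", "sample_id", "rpk") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpk",
                       values_fill = 0)
  names(rows)[1] <- "gene_family"
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' KOs whose TOTAL row was synthesised on load
#' @param x A `stratified_ko` tibble.
#' @return Character vector of KO ids.
#' @export
synthesized_totals <- function(x) attr(x, "synthesized_total") %||% character(0)
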