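#' Construct and validate a sample metadata table
#'
#' Metadata rows pair each sample with its diet group (one of omnivore,
#' pescatarian, vegan, vegetarian), cohort label and westernization flag.
#'
#' @param data Data frame with columns `sample_id`, `diet_group`, `cohort`,
#'   `westernized`.
#' @return A `sample_metadata` tibble.
#' @export
sample_metadata <- function(data) {
  data <- as_tibble(data)
  req <- c("sample_id", "diet_group", "cohort", "westernized")
  if (!all(req %in% names(data))) {
    abort("metadata needs columns sample_id, diet_group, cohort, westernized")
  }
  data <- data[, req]
  if (anyDuplicated(data$sample_id)) abort("duplicate sample_id in metadata")
  bad <- !data$diet_group %in% DIET_GROUPS
  if (any(bad)) {
    abort(paste0("unknown diet group '", data$diet_group[bad][[1]],
                 "' (expected one of: ", paste(DIET_GROUPS, collapse = ", "), ")"))
  }
  data$westernized <- as.logical(data$westernized)
  if (anyNA(data$westernized)) abort("westernized flag must be logical")
  structure(data, class = c("sample_metadata", class(tibble())))
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `diet_group`, `cohort`, `westernized`.
#' @return A [sample_metadata()] tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  sample_metadata(readr::read_tsv(path, comment = "#",
                                  show_col_types = FALSE, progress = FALSE))
}

#' Write sample metadata as TSV
#' @param x A `sample_metadata` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

# check that every sample in `ids` has exactly one metadata row
match_metadata <- function(ids, metadata) {
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples without metadata: ",
                 paste(utils::head(missing, 3), collapse = ", ")))
  }
  metadata[match(ids, metadata$sample_id), ]
}
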