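GMM_CATEGORIES <- c(
  "amino acid degradation", "carbohydrate degradation",
  "glycoprotein degradation", "lipid degradation",
  "acetate metabolism", "propionate metabolism",
  "butyrate metabolism", "lactate metabolism"
)

#' Construct a gut metabolic module catalogue
#'
#' A catalogue is a tibble with one row per module: `module_id`, `name`,
#' `category`, and a `steps` list-column. `steps[[i]]` is the ordered list of
#' reaction steps of module *i*; each step is a list of alternatives; each
#' alternative is a non-empty character vector of KO ids (a complex when it
#' has more than one member).
#'
#' @param data Data frame with columns `module_id`, `name`, `category`,
#'   `steps`.
#' @return A `gmm_catalogue` tibble.
#' @export
gmm_catalogue <- function(data) {
  data <- as_tibble(data)
  req <- c("module_id", "name", "category", "steps")
  if (!all(req %in% names(data))) {
    abort("catalogue needs columns module_id, name, category, steps")
  }
  data <- data[, req]
  if (anyDuplicated(data$module_id)) abort("duplicate module_id in catalogue")
  for (i in seq_len(nrow(data))) {
    steps <- data$steps[[i]]
    if (length(steps) < 1L) {
      abort(paste0("module ", data$module_id[[i]], " has no steps"))
    }
    for (step in steps) {
      if (length(step) < 1L) {
        abort(paste0("module ", data$module_id[[i]], " has a step with no alternatives"))
      }
      for (alt in step) {
        if (length(alt) < 1L || !all(is_ko_id(alt))) {
          abort(paste0("module ", data$module_id[[i]],
                       " has an invalid alternative (KO ids must match K + 5 digits)"))
        }
      }
    }
  }
  structure(data, class = c("gmm_catalogue", class(tibble())))
}

#' Read gut metabolic module definitions from a flat file
#'
#' The dialect: each record starts with a header line `"<ID>\t<Name>"`,
#' optionally followed by a line `"category\t<category>"`, then one line per
#' ordered reaction step, and ends with a line `"///"`. Within a step line,
#' alternatives are comma-separated and members of an orthologue complex are
#' joined with `+` (e.g. `"K00002,K00003+K00004"` is one step with two
#' alternatives, the second a two-member complex). Blank lines between
#' records and trailing whitespace are ignored.
#'
#' @param path Path to the flat file.
#' @return A [gmm_catalogue()] tibble, in file order.
#' @export
read_gmm_definitions <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE), which = "right")
  recs <- list()
  cur <- NULL  # list(module_id, name, category, steps)
  for (ln in lines) {
    if (is.null(cur)) {
      if (ln == "") next  # blank line between records
      header <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(header) < 2L) {
        abort(paste0("malformed record header: '", ln, "'"))
      }
      cur <- list(module_id = header[[1]], name = header[[2]],
                  category = NA_character_, steps = list())
    } else if (ln == "///") {
      if (length(cur$steps) == 0L) {
        abort(paste0("module ", cur$module_id, " has no step lines"))
      }
      recs[[length(recs) + 1L]] <- cur
      cur <- NULL
    } else if (startsWith(ln, "category\t")) {
      cur$category <- sub("^category\t", "", ln)
    } else if (ln == "") {
      abort(paste0("empty step line in record ", cur$module_id))
    } else {
      alts <- strsplit(ln, ",", fixed = TRUE)[[1]]
      step <- lapply(alts, function(a) {
        kos <- trimws(strsplit(a, "+", fixed = TRUE)[[1]])
        if (length(kos) == 0L || any(kos == "")) {
          abort(paste0("empty alternative in record ", cur$module_id))
        }
        kos
      })
      cur$steps[[length(cur$steps) + 1L]] <- step
    }
  }
  if (!is.null(cur)) {
    abort(paste0("missing record terminator '///' for module ", cur$module_id))
  }
  if (length(recs) == 0L) abort("no module records found")
  gmm_catalogue(tibble(
    module_id = vapply(recs, `[[`, character(1), "module_id"),
    name = vapply(recs, `[[`, character(1), "name"),
    category = vapply(recs, `[[`, character(1), "category"),
    steps = lapply(recs, `[[`, "steps")
  ))
}

#' Write a module catalogue in the flat-file dialect of [read_gmm_definitions()]
#'
#' @param x A `gmm_catalogue` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmm_definitions <- function(x, path) {
  out <- character(0)
  for (i in seq_len(nrow(x))) {
    out <- c(out, paste0(x$module_id[[i]], "\t", x$name[[i]]))
    if (!is.na(x$category[[i]])) {
      out <- c(out, paste0("category\t", x$category[[i]]))
    }
    for (step in x$steps[[i]]) {
      out <- c(out, paste(vapply(step, paste, character(1), collapse = "+"),
                          collapse = ","))
    }
    out <- c(out, "///")
  }
  writeLines(out, path)
  invisible(path)
}

# all KO ids referenced by a catalogue
catalogue_kos <- function(x) {
  unique(unlist(x$steps, use.names = FALSE))
}
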