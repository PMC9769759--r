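#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join distinct bind_rows across all_of n
#' @importFrom stats median setNames
NULL

# rank prefixes used in MetaPhlAn-style lineage strings, in taxonomic order
RANK_PREFIXES <- c(
  kingdom = "k", phylum = "p", class = "c", order = "o",
  family = "f", genus = "g", species = "s"
)

#' Reserved stratum tokens
#'
#' `STRATUM_TOTAL` marks the community-wide (unstratified) row of a KO table;
#' `STRATUM_UNCLASSIFIED` marks abundance that could not be attributed to a
#' species.
#'
#' @export
STRATUM_TOTAL <- "TOTAL"

#' @rdname STRATUM_TOTAL
#' @export
STRATUM_UNCLASSIFIED <- "UNCLASSIFIED"

DIET_GROUPS <- c("omnivore", "pescatarian", "vegan", "vegetarian")

#' Terminal rank of a lineage string
#'
#' A clade string such as `"k__Bacteria|p__Firmicutes"` terminates at the rank
#' of its last `|`-separated segment (here, phylum).
#'
#' @param clade Character vector of rank-prefixed, pipe-delimited lineages.
#' @return Character vector of rank names (`"kingdom"` ... `"species"`).
#' @export
#' @examples
#' clade_rank("k__Bacteria|p__Firmicutes")
clade_rank <- function(clade) {
  last <- vapply(strsplit(clade, "|", fixed = TRUE),
                 function(x) x[[length(x)]], character(1))
  prefix <- substr(last, 1L, 1L)
  ok <- substr(last, 2L, 3L) == "__" & prefix %in% RANK_PREFIXES
  if (!all(ok)) {
    abort(paste0("malformed lineage string: ", clade[!ok][[1]]))
  }
  names(RANK_PREFIXES)[match(prefix, RANK_PREFIXES)]
}

# last segment of a lineage with its rank prefix stripped
clade_label <- function(clade) {
  last <- vapply(strsplit(clade, "|", fixed = TRUE),
                 function(x) x[[length(x)]], character(1))
  sub("^[a-z]__", "", last)
}

# validate that every segment of every lineage is rank-prefixed
check_lineages <- function(clade) {
  segs <- strsplit(clade, "|", fixed = TRUE)
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    bad <- !grepl("^[kpcofgs]__", s)
    if (length(s) == 0L || any(bad)) {
      abort(paste0("malformed lineage string at entry ", i, ": '",
                   clade[[i]], "'"))
    }
  }
  invisible(clade)
}

is_ko_id <- function(x) grepl("^K[0-9]{5}$", x)

# derive a per-stage 32-bit seed from a base seed (keeps values < 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483647L
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(paste0("`", name, "` must be a single number in [", lo, ", ", hi, "]"))
  }
  invisible(x)
}
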