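#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Ordination scatter plot
#'
#' First two principal coordinates, optionally coloured by a metadata
#' column.
#'
#' @param object A `pcoa_result`.
#' @param metadata Optional [sample_metadata()] tibble.
#' @param colour Metadata column to map to colour (default `"cohort"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_result <- function(object, metadata = NULL, colour = "cohort",
                                 ...) {
  dat <- object$coordinates
  mapping <- aes(x = .data$axis1, y = .data$axis2)
  if (!is.null(metadata)) {
    dat <- left_join(dat, as_tibble(metadata), by = "sample_id")
    mapping <- aes(x = .data$axis1, y = .data$axis2,
                   colour = .data[[colour]])
  }
  pct <- round(100 * object$variance_explained[1:2], 1)
  ggplot(dat, mapping) +
    geom_point(alpha = 0.8) +
    labs(x = paste0("PCo1 (", pct[[1]], "%)"),
         y = paste0("PCo2 (", pct[[2]], "%)")) +
    theme_minimal()
}

#' Core-detection diagnostic plot
#'
#' Observed prevalence against the fraction of bootstraps in which each
#' taxon qualified, with the prevalence threshold marked.
#'
#' @param object A `core_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.core_result <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot(as_tibble(object),
         aes(x = .data$prevalence, y = .data$bootstrap_fraction,
             colour = .data$is_core)) +
    geom_point() +
    geom_hline(yintercept = cfg$bootstrap_retention, linetype = "dashed") +
    labs(x = "observed prevalence", y = "fraction of bootstraps qualifying",
         colour = "core") +
    theme_minimal()
}

#' Stacked species-contribution plot for one module
#'
#' @param contrib A [contributions()] tibble.
#' @param module_id Module to display.
#' @return A ggplot (per-sample stacked contribution fractions).
#' @export
plot_contributions <- function(contrib, module_id) {
  dat <- contrib |>
    filter(.data$module_id == !!module_id, !is.na(.data$fraction))
  if (nrow(dat) == 0L) abort(paste0("no defined contributions for module ",
                                    module_id))
  ggplot(dat, aes(x = .data$sample_id, y = .data$fraction,
                  fill = .data$species)) +
    geom_col() +
    labs(x = NULL, y = "contribution fraction", title = module_id) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Significance overview of a test cascade
#'
#' Omnibus -log10 adjusted p per (module, species) feature, significant
#' features highlighted.
#'
#' @param object A `contrib_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contrib_test <- function(object, ...) {
  dat <- object$omnibus |>
    mutate(neglog = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot(dat, aes(x = .data$species, y = .data$neglog,
                  colour = .data$significant)) +
    geom_point() +
    geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    facet_wrap(~ .data$module_id) +
    labs(x = NULL, y = "-log10 adjusted p") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
  }
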