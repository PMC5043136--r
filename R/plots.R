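# Plotting and broom-style summaries.

#' Histogram of pairwise Ks values
#'
#' @param kaks_tbl A [kaks_table()] result (needs a `Ks` column).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(kaks_tbl, bins = 30) {
  dat <- kaks_tbl[!is.na(kaks_tbl$Ks), ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$Ks)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::labs(x = "Ks (synonymous substitutions per synonymous site)",
                  y = "gene pairs") +
    ggplot2::theme_minimal()
}

#' Retention-matrix tile plot
#'
#' One tile per (ancestral group, species slot), colored by retained /
#' sub-functionalized / lost.
#'
#' @param object A `duphist_retention` from [build_retention_matrix()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot duphist_retention
#' @export
autoplot.duphist_retention <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       column = paste0(.data$species, ".", .data$slot))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$column, y = .data$group,
                                    fill = .data$status)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.5) +
    ggplot2::scale_fill_manual(values = c(
      retained = "#2b8cbe", subfunctionalized = "#fec44f", lost = "grey85"
    )) +
    ggplot2::labs(x = "species / duplicate slot", y = "ancestral locus") +
    ggplot2::theme_minimal()
}

#' Long-format retention matrix
#'
#' @param x A `duphist_retention`.
#' @param ... Ignored.
#' @return The retention cells as a plain tibble.
#' @method tidy duphist_retention
#' @export
tidy.duphist_retention <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a pipeline run
#'
#' @param x A `duphist_run`.
#' @param ... Ignored.
#' @return A one-row tibble of headline counts.
#' @method glance duphist_run
#' @export
glance.duphist_run <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$species),
    n_genes = sum(vapply(x$catalogs, nrow, integer(1))),
    n_family = sum(vapply(x$catalogs, function(c) sum(c$is_family),
                          integer(1))),
    n_paralog_pairs = nrow(x$paralogs),
    n_ortholog_pairs = nrow(x$orthologs),
    n_blocks_within = nrow(x$blocks_within),
    n_blocks_cross = nrow(x$blocks_cross),
    n_tandem_pairs = nrow(x$tandem_pairs),
    n_groups = length(unique(x$groups$group))
  )
}

#' @export
print.duphist_run <- function(x, ...) {
  cat("<duphist pipeline run>\n")
  print(glance.duphist_run(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
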