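#' Histogram of estimated insertion ages
#'
#' @param object A `retro_dates` tibble from [date_elements()].
#' @param binwidth Bin width in million years.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot retro_dates
#' @export
autoplot.retro_dates <- function(object, binwidth = 0.25, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$status == "dated")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$T_mya)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white", boundary = 0) +
    ggplot2::labs(x = "Insertion age (MYA)", y = "Elements",
                  title = "LTR-divergence insertion ages") +
    ggplot2::theme_minimal()
}

#' Bar chart of sequence composition
#'
#' @param object A `composition_report` from [composition_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composition_report
#' @export
autoplot.composition_report <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  keep <- c("gypsy", "copia", "unknown_LTR", "non_LTR", "class_II", "MITE",
            "tandem_repeats", "genes", "unassigned")
  dat <- dat[dat$category %in% keep, ]
  dat$category <- factor(dat$category, levels = rev(keep))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction_pct, y = .data$category)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Fraction of sequence (%)", y = NULL,
                  title = "Annotation composition") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap tree with genome-group colouring
#'
#' Thin wrapper over [ape::plot.phylo()]: draws the tree with bootstrap
#' supports on internal nodes and tip labels coloured by genome.
#'
#' @param tree An [ape::phylo] tree, e.g. from [bootstrap_support()].
#' @param labels Optional tibble (`id`, `genome`) for tip colouring.
#' @param min_support Only supports at or above this value are printed.
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_grouped_tree <- function(tree, labels = NULL, min_support = 50, ...) {
  cols <- "black"
  if (!is.null(labels)) {
    lab <- stats::setNames(labels$genome, labels$id)
    gen <- lab[tree$tip.label]
    pal <- stats::setNames(grDevices::hcl.colors(max(3L, length(unique(stats::na.omit(gen)))), "Dark 3"),
                           sort(unique(stats::na.omit(gen))))
    cols <- ifelse(is.na(gen), "grey50", pal[gen])
  }
  ape::plot.phylo(tree, tip.color = cols, ...)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    show <- !is.na(sup) & sup >= min_support
    if (any(show)) {
      ape::nodelabels(text = tree$node.label[show],
                      node = (length(tree$tip.label) + 1L:tree$Nnode)[show],
                      frame = "none", adj = c(1.2, -0.3), cex = 0.7)
    }
  }
  invisible(tree)
}
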