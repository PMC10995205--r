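#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_tile
#'   geom_hline geom_vline labs theme_minimal scale_colour_viridis_c
#'   coord_equal
#' @export
ggplot2::autoplot

#' Plot an unconstrained ordination
#'
#' @param object A `magniche_pcoa` object.
#' @param groups Optional factor used to colour samples.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.magniche_pcoa <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  axes <- colnames(object$scores)[1:2]
  pv <- 100 * object$prop_var[1:2]
  if (!is.null(groups)) df$group <- groups
  p <- ggplot(df, aes(x = .data[[axes[1]]], y = .data[[axes[2]]]))
  p <- if (is.null(groups)) p + geom_point(size = 2) else
    p + geom_point(aes(colour = .data$group), size = 2)
  p + coord_equal() + theme_minimal() +
    labs(x = sprintf("%s (%.1f%%)", axes[1], pv[1]),
         y = sprintf("%s (%.1f%%)", axes[2], pv[2]),
         colour = NULL)
}

#' Plot a constrained ordination, optionally with fitted vectors
#'
#' @param object A `magniche_dbrda` object.
#' @param envfit Optional `magniche_envfit` tibble; arrows are drawn scaled
#'   by the square root of each variable's R².
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.magniche_dbrda <- function(object, envfit = NULL, ...) {
  df <- tidy(object)
  axes <- colnames(object$scores)[1:2]
  cn <- object$constraints[[1]]
  df$group <- if (is.factor(cn) || is.character(cn)) as.character(cn) else NULL
  p <- ggplot(df, aes(x = .data[[axes[1]]], y = .data[[axes[2]]]))
  p <- if (is.null(df$group)) p + geom_point(size = 2) else
    p + geom_point(aes(colour = .data$group), size = 2)
  if (!is.null(envfit) && nrow(envfit) > 0) {
    sc <- max(abs(df[[axes[1]]]), abs(df[[axes[2]]]))
    arr <- dplyr::mutate(envfit,
                         xend = .data$axis1 * sqrt(.data$r_squared) * sc,
                         yend = .data$axis2 * sqrt(.data$r_squared) * sc)
    p <- p +
      geom_segment(data = arr,
                   aes(x = 0, y = 0, xend = .data$xend, yend = .data$yend),
                   arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                   inherit.aes = FALSE) +
      ggplot2::geom_text(data = arr,
                         aes(x = .data$xend * 1.08, y = .data$yend * 1.08,
                             label = .data$variable),
                         inherit.aes = FALSE, size = 3)
  }
  p + coord_equal() + theme_minimal() +
    labs(x = axes[1], y = axes[2], colour = NULL)
}

#' Prevalence-abundance plot of specificity calls
#'
#' Mean coral abundance against maximum seawater abundance, coloured by
#' label, with the 0.1% seawater-abundance criterion marked.
#'
#' @param spec Result of [classify_specificity()].
#' @return A ggplot.
#' @export
plot_specificity <- function(spec) {
  ggplot(spec, aes(x = .data$max_seawater_abund,
                   y = .data$mean_abund_coral,
                   colour = .data$label)) +
    geom_point(alpha = 0.8) +
    geom_vline(xintercept = 0.1, linetype = 2) +
    ggplot2::scale_x_continuous(trans = "sqrt") +
    ggplot2::scale_y_continuous(trans = "sqrt") +
    theme_minimal() +
    labs(x = "max relative abundance in seawater (%)",
         y = "mean relative abundance in coral (%)", colour = NULL)
}

#' Enrichment proportion plot
#'
#' Presence proportion in each specificity group per feature, coloured by
#' adjusted p-value (the layout used for functional-enrichment overviews).
#'
#' @param enr Result of [fisher_enrichment()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enr) {
  ggplot(enr, aes(x = .data$prop_seawater, y = .data$prop_host,
                  colour = .data$adjusted_p)) +
    geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    scale_colour_viridis_c(direction = -1) +
    coord_equal() + theme_minimal() +
    labs(x = "proportion of seawater-specific MAGs",
         y = "proportion of host-specific MAGs",
         colour = "adj. p")
}

#' Module completeness heatmap
#'
#' @param mc Result of [completeness_report()].
#' @return A ggplot.
#' @export
plot_module_completeness <- function(mc) {
  ggplot(mc, aes(x = .data$module_id, y = .data$mag_id,
                 fill = .data$completeness)) +
    geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank()) +
    labs(x = NULL, y = "genome", fill = "completeness (%)")
}
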