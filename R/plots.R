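#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression fit
#'
#' @param object A `poma_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.poma_de <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log_fold_change,
                                    y = -log10(.data$p_adjusted),
                                    colour = .data$is_de)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 name = "DE") +
    ggplot2::labs(x = "log2 fold change (disease - control)",
                  y = "-log10 adjusted p")
}

#' NOD vs TFP scatter of a candidate selection
#'
#' Each point is one miRNA of the condition network; selected candidates
#' are highlighted.
#'
#' @param object A `poma_candidates` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.poma_candidates <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$nod, y = .data$tfp,
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "candidate") +
    ggplot2::labs(x = "novel out-degree (NOD)",
                  y = "TF percentage of targets (TFP)",
                  title = attr(object, "label"))
}

#' Bar chart of the top enriched pathways
#'
#' @param object A `poma_enrichment` object.
#' @param n Number of top pathways (by raw p) to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.poma_enrichment <- function(object, n = 10, ...) {
  tab <- utils::head(tidy(object), n)
  tab$pathway <- factor(tab$pathway, levels = rev(tab$pathway))
  ggplot2::ggplot(tab, ggplot2::aes(x = -log10(.data$p_raw), y = .data$pathway,
                                    fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                               name = "enriched") +
    ggplot2::labs(x = "-log10 p (hypergeometric)", y = NULL)
}
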