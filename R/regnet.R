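#' Build a condition-specific regulatory network
#'
#' Restricts the reference network to the differentially expressed miRNAs
#' and the union of their targets (the induced bipartite subgraph). DE
#' miRNAs absent from the reference are dropped with a message.
#'
#' @param reference A [mirna_network].
#' @param de_mirnas Character vector of DE miRNA IDs.
#' @param label Condition label (e.g. `"AMI"`).
#' @return An object of class `condition_network`: list with `network`
#'   (the induced [mirna_network]) and `label`.
#' @export
build_condition_network <- function(reference, de_mirnas, label = "condition") {
  stopifnot(inherits(reference, "mirna_network"))
  de_mirnas <- unique(de_mirnas)
  kept <- intersect(de_mirnas, reference$mirnas)
  dropped <- length(de_mirnas) - length(kept)
  if (length(kept) == 0) {
    stop("no DE miRNA maps to the reference network", call. = FALSE)
  }
  if (dropped > 0) {
    message(sprintf("%d DE miRNA(s) absent from the reference were dropped", dropped))
  }
  edges <- dplyr::filter(reference$edges, .data$mirna %in% kept)
  sub <- suppressWarnings(mirna_network(edges, reference$tf_genes))
  structure(list(network = sub, label = label), class = "condition_network")
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf("<condition_network '%s'> ", x$label))
  print(x$network)
  invisible(x)
}

#' Per-miRNA network statistics: N, NOD, TF count, TFP
#'
#' For each miRNA of a condition-specific network computes the number of
#' targets N, the novel out-degree NOD (targets whose in-degree within the
#' condition network is exactly 1, i.e. genes this miRNA alone regulates),
#' the count of transcription-factor targets, and the TF percentage
#' TFP = TF targets / N (stored at full precision; round only for
#' presentation). Rows are ordered by decreasing NOD, ties broken by
#' decreasing TFP then miRNA ID.
#'
#' @param cond A [build_condition_network()] result (or a bare
#'   [mirna_network], treated as a single-condition network).
#' @return A tibble with columns `mirna`, `n_targets`, `nod`, `tf_targets`,
#'   `tfp`.
#' @export
compute_stats <- function(cond) {
  net <- as_network(cond)
  edges <- net$edges
  edges <- dplyr::mutate(edges,
    unique_target = !(duplicated(.data$gene) | duplicated(.data$gene, fromLast = TRUE)),
    is_tf = .data$gene %in% net$tf_genes)
  out <- dplyr::summarise(dplyr::group_by(edges, .data$mirna),
    n_targets = dplyr::n(),
    nod = sum(.data$unique_target),
    tf_targets = sum(.data$is_tf),
    .groups = "drop")
  out <- dplyr::mutate(out, tfp = .data$tf_targets / .data$n_targets)
  dplyr::arrange(out, dplyr::desc(.data$nod), dplyr::desc(.data$tfp), .data$mirna)
}

as_network <- function(x) {
  if (inherits(x, "condition_network")) x$network
  else if (inherits(x, "mirna_network")) x
  else stop("expected a condition_network or mirna_network", call. = FALSE)
}

#' Genes uniquely regulated by one miRNA
#'
#' The NOD gene set itself: targets of `mirna` whose in-degree in the
#' condition network is exactly 1.
#'
#' @param cond A condition network (or [mirna_network]).
#' @param mirna A single miRNA ID present in the network.
#' @return Character vector of gene IDs (length equals the miRNA's NOD).
#' @export
unique_targets <- function(cond, mirna) {
  net <- as_network(cond)
  if (!mirna %in% net$mirnas) {
    stop("miRNA not present in the network: ", mirna, call. = FALSE)
  }
  indeg <- table(net$edges$gene)
  tg <- net$edges$gene[net$edges$mirna == mirna]
  sort(tg[indeg[tg] == 1])
}
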