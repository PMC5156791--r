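#' Upper-tail hypergeometric probability
#'
#' `P(X >= overlap)` for X hypergeometric: drawing `query_size` genes from a
#' universe of `universe_size` of which `set_size` belong to the pathway.
#' Computed through the log-space tail of `stats::phyper` for stability.
#'
#' @param overlap Observed overlap count.
#' @param query_size Number of query genes in the universe.
#' @param set_size Number of pathway genes in the universe.
#' @param universe_size Size of the gene universe.
#' @return The tail probability.
#' @export
hypergeom_tail <- function(overlap, query_size, set_size, universe_size) {
  if (overlap < 0 || overlap > min(query_size, set_size) ||
      set_size > universe_size || query_size > universe_size) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  if (overlap == 0) return(1)
  exp(stats::phyper(overlap - 1, set_size, universe_size - set_size,
                    query_size, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric pathway enrichment of a query gene set
#'
#' Over-representation of `query` within each pathway, against a fixed gene
#' universe (by default the regulatory network's genes, which define the
#' sampling frame targets arise from). Query genes outside the universe are
#' dropped with a message; pathway gene sets are intersected with the
#' universe and pathways with no gene in the universe are skipped.
#' Raw p-values come from [hypergeom_tail()]; FDR is Benjamini-Hochberg
#' over the tested pathways; a pathway is flagged enriched when both
#' `p_raw < p_cut` and `fdr < fdr_cut`.
#'
#' @param query Character vector of gene IDs.
#' @param sets A [gene_sets] collection.
#' @param universe Character vector of gene IDs.
#' @param p_cut,fdr_cut Double threshold for the enriched flag (defaults 0.05).
#' @return An object of class `poma_enrichment`: tibble with columns
#'   `pathway`, `set_size`, `query_size`, `overlap`, `p_raw`, `fdr`,
#'   `enriched`, sorted by ascending `p_raw`.
#' @export
enrich <- function(query, sets, universe, p_cut = 0.05, fdr_cut = 0.05) {
  stopifnot(inherits(sets, "gene_sets"))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    message(sprintf("%d query gene(s) outside the universe were dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) {
    stop("empty query after restricting to the universe", call. = FALSE)
  }
  rows <- purrr::imap(sets$sets, function(members, nm) {
    in_univ <- intersect(members, universe)
    if (length(in_univ) == 0) return(NULL)
    ov <- length(intersect(in_univ, query))
    tibble::tibble(
      pathway = nm,
      set_size = length(in_univ),
      query_size = length(query),
      overlap = ov,
      p_raw = hypergeom_tail(ov, length(query), length(in_univ),
                             length(universe))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no pathway intersects the universe", call. = FALSE)
  out$fdr <- adjust_bh(out$p_raw)
  out$enriched <- out$p_raw < p_cut & out$fdr < fdr_cut
  out <- dplyr::arrange(out, .data$p_raw, .data$pathway)
  structure(out, class = c("poma_enrichment", class(out)),
            universe_size = length(universe))
}

#' Tidy an enrichment result
#'
#' @param x A `poma_enrichment` object.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.poma_enrichment <- function(x, ...) tibble::as_tibble(unclass(x))

#' One-row summary of an enrichment result
#'
#' @param x A `poma_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble with pathway and enrichment counts.
#' @export
glance.poma_enrichment <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x),
    n_enriched = sum(x$enriched),
    universe_size = attr(x, "universe_size")
  )
}

#' Per-miRNA coverage of the enriched pathways
#'
#' For each selected candidate miRNA, the number of significantly enriched
#' pathways whose gene set intersects that miRNA's uniquely regulated
#' targets (or all its targets with `targets = "all"`), and the
#' corresponding fraction of all enriched pathways.
#'
#' @param cond The condition network the candidates came from.
#' @param cand A `poma_candidates` object (or character vector of miRNA IDs).
#' @param enrichment A `poma_enrichment` result.
#' @param sets The [gene_sets] collection used for enrichment.
#' @param targets `"unique"` (default) to intersect with each miRNA's
#'   unique-target set, `"all"` for its full target set.
#' @return A tibble with columns `mirna`, `n_regulated`, `n_enriched_total`,
#'   `fraction`; empty (with a warning) when nothing is enriched.
#' @export
pathway_coverage <- function(cond, cand, enrichment, sets,
                             targets = c("unique", "all")) {
  targets <- match.arg(targets)
  ids <- if (inherits(cand, "poma_candidates")) candidates(cand) else unique(cand)
  enriched <- enrichment$pathway[enrichment$enriched]
  if (length(enriched) == 0) {
    warning("no enriched pathways; coverage is empty", call. = FALSE)
    return(tibble::tibble(mirna = character(), n_regulated = integer(),
                          n_enriched_total = integer(), fraction = numeric()))
  }
  net <- as_network(cond)
  purrr::map_dfr(ids, function(m) {
    tg <- if (targets == "unique") unique_targets(cond, m) else {
      net$edges$gene[net$edges$mirna == m]
    }
    n_reg <- sum(vapply(enriched, function(p) {
      length(intersect(sets$sets[[p]], tg)) > 0
    }, logical(1)))
    tibble::tibble(mirna = m, n_regulated = n_reg,
                   n_enriched_total = length(enriched),
                   fraction = n_reg / length(enriched))
  })
}
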