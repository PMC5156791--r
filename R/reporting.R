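#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.165 -> 0.17), the convention used
#' for the reported TFP, coverage and precision figures; base `round()`
#' rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Prediction precision against a literature-reported list
#'
#' The percentage of predicted candidate miRNAs that appear among
#' literature-reported biomarkers. IDs are normalised before intersecting,
#' so duplicates and case/prefix differences do not affect the result; the
#' denominator is the predicted set.
#'
#' @param predicted Character vector of predicted miRNA IDs (non-empty).
#' @param reported Character vector (or [read_reported_biomarkers()] tibble)
#'   of reported biomarker IDs.
#' @return A list with `overlap` (sorted shared IDs), `n_predicted`, and
#'   `percent` (one decimal, half-up).
#' @export
precision <- function(predicted, reported) {
  if (is.data.frame(reported)) reported <- reported$mirna
  predicted <- unique(normalize_mirna_id(predicted))
  if (length(predicted) == 0) stop("empty predicted set", call. = FALSE)
  reported <- unique(normalize_mirna_id(reported))
  overlap <- sort(intersect(predicted, reported))
  list(overlap = overlap,
       n_predicted = length(predicted),
       percent = round_half_up(100 * length(overlap) / length(predicted), 1))
}

#' Shared and condition-specific candidates across two subtypes
#'
#' @param candidates_a,candidates_b Character vectors of miRNA IDs.
#' @return A list of three disjoint sorted sets `shared`, `only_a`,
#'   `only_b` partitioning the union.
#' @export
cross_overlap <- function(candidates_a, candidates_b) {
  a <- unique(normalize_mirna_id(candidates_a))
  b <- unique(normalize_mirna_id(candidates_b))
  list(shared = sort(intersect(a, b)),
       only_a = sort(setdiff(a, b)),
       only_b = sort(setdiff(b, a)))
}

#' Format the per-candidate summary table
#'
#' The presentation table of a condition's candidates: targets N, novel
#' out-degree NOD, TF-target count, TFP rounded to two decimals, the number
#' of enriched pathways the miRNA regulates, and that count as a fraction
#' of all enriched pathways (two decimals). Candidates with no coverage row
#' (nothing enriched) get zeros.
#'
#' @param stats A stats tibble with columns `mirna`, `n_targets`, `nod`,
#'   `tf_targets` (and optionally `tfp`; recomputed when absent).
#' @param coverage Optional [pathway_coverage()] tibble.
#' @return A tibble with columns `mirna`, `N`, `NOD`, `TF`, `TFP`,
#'   `pathways`, `pathway_fraction`, ordered by decreasing NOD.
#' @export
format_candidate_table <- function(stats, coverage = NULL) {
  tab <- tibble::tibble(
    mirna = stats$mirna,
    N = stats$n_targets,
    NOD = stats$nod,
    TF = stats$tf_targets,
    TFP = round_half_up(stats$tf_targets / stats$n_targets, 2)
  )
  if (!is.null(coverage) && nrow(coverage) > 0) {
    cov <- tibble::tibble(mirna = coverage$mirna,
                          pathways = coverage$n_regulated,
                          pathway_fraction = round_half_up(coverage$fraction, 2))
    tab <- dplyr::left_join(tab, cov, by = "mirna")
    tab$pathways[is.na(tab$pathways)] <- 0L
    tab$pathway_fraction[is.na(tab$pathway_fraction)] <- 0
  } else {
    tab$pathways <- 0L
    tab$pathway_fraction <- 0
  }
  dplyr::arrange(tab, dplyr::desc(.data$NOD), dplyr::desc(.data$TFP), .data$mirna)
}

#' Assemble the run report
#'
#' Collects every stage's headline numbers, the per-condition validation
#' against reported biomarkers, the cross-condition overlap, and — when a
#' planted truth is supplied — sensitivity and false-discovery proportion
#' of the selected set. The report is a plain list, deterministic given
#' identical inputs, suitable for `jsonlite::write_json`.
#'
#' @param de A `poma_de` object.
#' @param cand A `poma_candidates` object.
#' @param enrichment A `poma_enrichment` object (or NULL).
#' @param coverage A [pathway_coverage()] tibble (or NULL).
#' @param reported Reported-biomarker IDs (or NULL).
#' @param truth A synthetic truth list (or NULL).
#' @param seed The run's master seed.
#' @param params Named list of run parameters to record.
#' @return A list of class `poma_report`.
#' @export
build_report <- function(de, cand, enrichment = NULL, coverage = NULL,
                         reported = NULL, truth = NULL, seed = NA,
                         params = list()) {
  missing_stage <- c(de = missing(de) || is.null(de),
                     candidates = missing(cand) || is.null(cand))
  if (any(missing_stage)) {
    stop("missing stage output: ", paste(names(missing_stage)[missing_stage],
                                         collapse = ", "), call. = FALSE)
  }
  sel <- candidates(cand)
  rep <- list(
    seed = seed,
    params = params,
    de = as.list(glance(de)),
    selection = as.list(glance(cand)),
    candidates = sel
  )
  if (!is.null(enrichment)) rep$enrichment <- as.list(glance(enrichment))
  if (!is.null(coverage)) rep$coverage <- as.data.frame(coverage)
  if (!is.null(reported)) {
    pr <- precision(sel, reported)
    rep$validation <- list(n_predicted = pr$n_predicted,
                           n_overlap = length(pr$overlap),
                           overlap = pr$overlap,
                           precision_percent = pr$percent)
  }
  if (!is.null(truth)) {
    planted <- normalize_mirna_id(truth$planted_biomarkers)
    tp <- length(intersect(sel, planted))
    rep$truth_recovery <- list(
      n_planted = length(planted),
      n_selected = length(sel),
      sensitivity = if (length(planted) > 0) tp / length(planted) else NA,
      false_discovery_proportion =
        if (length(sel) > 0) (length(sel) - tp) / length(sel) else 0
    )
  }
  structure(rep, class = "poma_report")
}

#' Write a run report to disk
#'
#' Emits `report.json` plus a per-candidate `candidates.tsv` in the
#' presentation layout of [format_candidate_table()].
#'
#' @param report A `poma_report`.
#' @param cand The `poma_candidates` object behind it.
#' @param dir Output directory (created if needed).
#' @param coverage Optional coverage tibble for the table.
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, cand, dir, coverage = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sel <- tidy(cand)[tidy(cand)$selected, ]
  readr::write_tsv(format_candidate_table(sel, coverage),
                   file.path(dir, "candidates.tsv"), progress = FALSE)
  invisible(dir)
}
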