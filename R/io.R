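#' @importFrom rlang .data
NULL

# strip '#' comment lines and blank lines from raw lines, keeping original
# line numbers alongside for error messages
filter_content_lines <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Construct an expression matrix object
#'
#' Bundles a features x samples matrix of log2-scale abundances with a
#' control/disease group label per sample.
#'
#' @param values Numeric matrix, miRNAs in rows (rownames are feature IDs),
#'   samples in columns (colnames are sample IDs).
#' @param groups Named character vector mapping every sample ID to
#'   `"control"` or `"disease"`.
#' @return An object of class `mirna_expr`.
#' @export
mirna_expr <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature IDs after normalisation", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing) > 0) {
    stop("no group label for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("control", "disease"))
  if (length(bad) > 0) {
    stop("group labels must be 'control' or 'disease', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, groups = groups), class = "mirna_expr")
}

#' @export
print.mirna_expr <- function(x, ...) {
  cat(sprintf("<mirna_expr> %d miRNAs x %d samples (%d control / %d disease)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "disease")))
  invisible(x)
}

#' Read a miRNA expression matrix with sample groups
#'
#' The matrix file is a TSV with a header row of sample IDs and feature IDs
#' in the first column; `#`-prefixed lines are ignored. The groups file is a
#' two-column TSV (sample, label) with labels `control`/`disease`. Duplicate
#' feature rows (after ID normalisation) are collapsed by their mean, with a
#' warning.
#'
#' @param matrix_path Path to the expression TSV.
#' @param groups_path Path to the sample-group TSV.
#' @return A [mirna_expr] object.
#' @export
read_expression_matrix <- function(matrix_path, groups_path) {
  tab <- readr::read_tsv(matrix_path, comment = "#", col_types = readr::cols(),
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) stop("expression matrix needs at least one sample column", call. = FALSE)
  feature_raw <- as.character(tab[[1]])
  vals <- tab[-1]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     col[bad[1]], bad[1], names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- normalize_mirna_id(feature_raw)

  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    warning(sprintf("collapsed %d duplicated feature ID(s) by mean: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")),
            call. = FALSE)
    m <- rowsum(m, group = rownames(m)) / as.vector(table(rownames(m))[unique(rownames(m))])
    # rowsum orders by group; restore a stable order
    m <- m[order(rownames(m)), , drop = FALSE]
  }

  grp <- read_groups(groups_path)
  missing <- setdiff(colnames(m), names(grp))
  if (length(missing) > 0) {
    stop("sample(s) missing from groups file: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mirna_expr(m, grp)
}

read_groups <- function(path) {
  raw <- filter_content_lines(readr::read_lines(path, progress = FALSE))
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  if (length(parts) > 0 &&
      tolower(parts[[1]][1]) %in% c("sample", "sample_id")) {
    parts <- parts[-1]
  }
  if (length(parts) == 0) stop("empty groups file", call. = FALSE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0) {
    stop(sprintf("groups file: expected 2 tab-separated fields at line %d",
                 raw$lineno[bad[1]]), call. = FALSE)
  }
  stats::setNames(tolower(vapply(parts, `[[`, "", 2L)),
                  vapply(parts, `[[`, "", 1L))
}

#' Construct a miRNA-mRNA regulatory network
#'
#' A bipartite edge set from miRNAs to target genes, with a subset of genes
#' flagged as transcription factors. IDs are assumed already normalised;
#' duplicate edges are dropped (with a message) and TF genes not present in
#' the network are dropped with a warning.
#'
#' @param edges Data frame with columns `mirna` and `gene`.
#' @param tf_genes Character vector of transcription-factor gene IDs.
#' @return An object of class `mirna_network` with fields `edges` (tibble),
#'   `tf_genes`, and derived `mirnas`/`genes`.
#' @export
mirna_network <- function(edges, tf_genes = character()) {
  edges <- tibble::as_tibble(edges)[c("mirna", "gene")]
  if (nrow(edges) == 0) stop("empty network", call. = FALSE)
  ndup <- sum(duplicated(edges))
  if (ndup > 0) {
    message(sprintf("dropped %d duplicate edge(s)", ndup))
    edges <- dplyr::distinct(edges)
  }
  extra_tf <- setdiff(tf_genes, edges$gene)
  if (length(extra_tf) > 0) {
    warning(sprintf("%d TF gene(s) absent from the network were dropped",
                    length(extra_tf)), call. = FALSE)
  }
  structure(list(
    edges = edges,
    mirnas = sort(unique(edges$mirna)),
    genes = sort(unique(edges$gene)),
    tf_genes = sort(intersect(unique(tf_genes), edges$gene))
  ), class = "mirna_network")
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("<mirna_network> %d miRNAs, %d genes (%d TF), %d edges\n",
              length(x$mirnas), length(x$genes), length(x$tf_genes),
              nrow(x$edges)))
  invisible(x)
}

#' Read a miRNA-target edge list and TF gene list
#'
#' @param path Two-column TSV (`mirna`, `gene`), `#` comments allowed.
#' @param tf_path Optional plain-text file, one TF gene ID per line.
#' @return A [mirna_network] object.
#' @export
read_edge_list <- function(path, tf_path = NULL) {
  raw <- filter_content_lines(readr::read_lines(path, progress = FALSE))
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  if (length(parts) > 0 && identical(tolower(parts[[1]]), c("mirna", "gene"))) {
    parts <- parts[-1]
  }
  if (length(parts) == 0) stop("empty network", call. = FALSE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad) > 0) {
    stop(sprintf("edge list: expected 2 tab-separated fields at line %d",
                 raw$lineno[bad[1]]), call. = FALSE)
  }
  edges <- tibble::tibble(
    mirna = normalize_mirna_id(vapply(parts, `[[`, "", 1L)),
    gene  = normalize_gene_id(vapply(parts, `[[`, "", 2L))
  )
  tf <- character()
  if (!is.null(tf_path)) {
    tf_lines <- filter_content_lines(readr::read_lines(tf_path, progress = FALSE))$lines
    if (length(tf_lines) > 0) tf <- normalize_gene_id(tf_lines)
  }
  mirna_network(edges, tf)
}

#' Write a regulatory network to TSV
#'
#' @param network A [mirna_network].
#' @param path Output edge-list path.
#' @param tf_path Optional output path for the TF gene list.
#' @return `network`, invisibly.
#' @export
write_edge_list <- function(network, path, tf_path = NULL) {
  edges <- dplyr::arrange(network$edges, .data$mirna, .data$gene)
  readr::write_tsv(edges, path, col_names = TRUE, progress = FALSE)
  if (!is.null(tf_path)) {
    readr::write_lines(network$tf_genes, tf_path)
  }
  invisible(network)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (pathway name -> member genes).
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `gene_sets`.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (length(sets) == 0) stop("no gene sets", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene-set names must be unique and non-empty", call. = FALSE)
  }
  sets <- lapply(sets, function(g) sort(unique(g)))
  if (any(lengths(sets) == 0)) stop("empty gene set", call. = FALSE)
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets, sizes %d-%d\n", length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB gene1 TAB ...`.
#' Gene IDs are case-folded; duplicate members within a set are stored once.
#'
#' @param path Path to the GMT file.
#' @return A [gene_sets] object.
#' @export
read_gene_sets <- function(path) {
  raw <- filter_content_lines(readr::read_lines(path, progress = FALSE))
  if (length(raw$lines) == 0) stop("empty GMT file", call. = FALSE)
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0) {
    stop(sprintf("GMT: fewer than 3 fields at line %d", raw$lineno[bad[1]]),
         call. = FALSE)
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate pathway name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  sets <- stats::setNames(lapply(parts, function(p) normalize_gene_id(p[-(1:2)])), nm)
  desc <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  gene_sets(sets, desc)
}

#' Write gene sets to GMT
#'
#' @param x A [gene_sets] object.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_gene_sets <- function(x, path) {
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(x)
}

#' Read a literature-reported biomarker list
#'
#' TSV with at least a miRNA ID column (named `mirna`, `id`, or the first
#' column); optional `role` (diagnostic/prognostic/both) and `direction`
#' (up/down/mixed) columns. Unrecognised or absent values default to
#' `"unknown"`. A `subtype` column, if present, is carried through.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `mirna`, `role`, `direction` (and `subtype`
#'   if present), IDs normalised.
#' @export
read_reported_biomarkers <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) stop("empty reported-biomarker file", call. = FALSE)
  names(tab) <- tolower(names(tab))
  id_col <- intersect(c("mirna", "mirna_id", "id"), names(tab))
  id_col <- if (length(id_col) > 0) id_col[1] else names(tab)[1]
  out <- tibble::tibble(mirna = normalize_mirna_id(tab[[id_col]]))
  out$role <- parse_enum(tab[["role"]], c("diagnostic", "prognostic", "both"), nrow(tab))
  out$direction <- parse_enum(tab[["direction"]], c("up", "down", "mixed"), nrow(tab))
  if ("subtype" %in% names(tab)) out$subtype <- tab[["subtype"]]
  out
}

parse_enum <- function(x, levels, n) {
  if (is.null(x)) return(rep("unknown", n))
  x <- tolower(trimws(x))
  x[is.na(x) | !(x %in% levels)] <- "unknown"
  x
}

#' Write an expression matrix and its group labels
#'
#' @param expr A [mirna_expr] object.
#' @param matrix_path Output TSV path for the matrix.
#' @param groups_path Output TSV path for the sample groups.
#' @return `expr`, invisibly.
#' @export
write_expression_matrix <- function(expr, matrix_path, groups_path) {
  tab <- tibble::as_tibble(expr$values, rownames = "mirna")
  readr::write_tsv(tab, matrix_path, progress = FALSE)
  grp <- tibble::tibble(sample = names(expr$groups), label = unname(expr$groups))
  readr::write_tsv(grp, groups_path, progress = FALSE)
  invisible(expr)
}
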