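#' One-sample Wilcoxon signed-rank p-value
#'
#' Tests whether the median of `values` exceeds (`alternative = "greater"`)
#' or falls below (`"less"`) a fixed `location`. Zero differences are
#' dropped (the Wilcoxon convention) and tied absolute differences receive
#' average ranks. With 25 or fewer nonzero differences the null
#' distribution of the positive-rank sum is enumerated exactly by dynamic
#' programming over doubled ranks (average ranks are half-integers, so
#' doubling makes them integral); beyond that a normal approximation with
#' tie-corrected variance and a continuity correction of 1/2 is used.
#'
#' @param values Numeric vector.
#' @param location Null median.
#' @param alternative `"greater"` or `"less"`.
#' @param exact_max Largest number of nonzero differences for which the
#'   exact null distribution is enumerated.
#' @return A single p-value.
#' @export
signed_rank_pvalue <- function(values, location = 0,
                               alternative = c("greater", "less"),
                               exact_max = 25) {
  alternative <- match.arg(alternative)
  d <- values - location
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate test: all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    w2 <- as.integer(round(2 * w))
    total <- sum(r2)
    # f[k+1] = number of sign assignments with doubled rank-sum k
    f <- numeric(total + 1)
    f[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), f[seq_len(total + 1 - rr)])
      f <- f + shifted
    }
    probs <- f / 2^n
    if (alternative == "greater") {
      sum(probs[(w2 + 1):(total + 1)])
    } else {
      sum(probs[1:(w2 + 1)])
    }
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (alternative == "greater") {
      stats::pnorm((w - mu - 0.5) / sqrt(v), lower.tail = FALSE)
    } else {
      stats::pnorm((w - mu + 0.5) / sqrt(v))
    }
  }
}

#' Select candidate biomarker miRNAs by NOD and TFP
#'
#' A miRNA is a candidate when both its novel out-degree and its TF
#' percentage are significantly large relative to the other miRNAs of the
#' condition network. In the default `signed-rank` mode each miRNA's value
#' is treated as the null location for a one-sided, one-sample Wilcoxon
#' signed-rank test of all other miRNAs' values (`alternative = "less"`):
#' a small p means the rest of the population sits significantly below that
#' miRNA. Selection requires raw `p_nod < alpha` and `p_tfp < alpha` (no
#' multiplicity correction). The alternative `permutation` mode replaces
#' the signed-rank null by an empirical null from degree-preserving edge
#' rewiring of the condition network.
#'
#' @param stats A [compute_stats()] tibble (ignored when `cond` is given in
#'   permutation mode, where stats are recomputed).
#' @param alpha Significance cutoff, default 0.05.
#' @param mode `"signed-rank"` (default) or `"permutation"`.
#' @param cond The condition network; required for permutation mode.
#' @param perm_iters Number of rewired networks in permutation mode.
#' @param seed Seed for permutation mode.
#' @return An object of class `poma_candidates`: the stats tibble plus
#'   `p_nod`, `p_tfp`, `selected`, ordered by decreasing NOD (ties:
#'   decreasing TFP, then ID), with attributes `alpha`, `mode`, `label`.
#' @export
select_candidates <- function(stats, alpha = 0.05,
                              mode = c("signed-rank", "permutation"),
                              cond = NULL, perm_iters = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (inherits(stats, "condition_network")) {
    cond <- stats
    stats <- compute_stats(cond)
  }
  if (nrow(stats) < 3) stop("need at least 3 miRNAs", call. = FALSE)
  label <- if (!is.null(cond)) cond$label else NA_character_

  if (mode == "signed-rank") {
    p_for <- function(x) {
      vapply(seq_along(x), function(i) {
        others <- x[-i]
        if (all(others == x[i])) return(NA_real_)
        signed_rank_pvalue(others, location = x[i], alternative = "less")
      }, numeric(1))
    }
    p_nod <- p_for(stats$nod)
    p_tfp <- p_for(stats$tfp)
  } else {
    if (is.null(cond)) {
      stop("permutation mode needs the condition network", call. = FALSE)
    }
    null_counts <- permutation_null_counts(cond, stats, perm_iters, seed)
    p_nod <- (1 + null_counts$nod) / (perm_iters + 1)
    p_tfp <- (1 + null_counts$tfp) / (perm_iters + 1)
  }

  n_degen <- sum(is.na(p_nod) | is.na(p_tfp))
  if (n_degen > 0) {
    message(sprintf("%d miRNA(s) with degenerate tests treated as non-candidates",
                    n_degen))
  }
  out <- dplyr::mutate(stats, p_nod = p_nod, p_tfp = p_tfp,
    selected = !is.na(p_nod) & !is.na(p_tfp) & p_nod < alpha & p_tfp < alpha)
  out <- dplyr::arrange(out, dplyr::desc(.data$nod), dplyr::desc(.data$tfp),
                        .data$mirna)
  structure(out, class = c("poma_candidates", class(out)),
            alpha = alpha, mode = mode, label = label)
}

# count, per miRNA, how many rewired networks reach its observed NOD / TFP
permutation_null_counts <- function(cond, stats, perm_iters, seed) {
  net <- as_network(cond)
  nod_ct <- stats::setNames(numeric(nrow(stats)), stats$mirna)
  tfp_ct <- nod_ct
  with_local_seed(split_seed(seed, "permutation"), {
    for (b in seq_len(perm_iters)) {
      perm <- rewire_edges(net$edges)
      pnet <- structure(list(edges = perm,
                             mirnas = net$mirnas, genes = net$genes,
                             tf_genes = net$tf_genes), class = "mirna_network")
      ps <- compute_stats(pnet)
      ps <- ps[match(stats$mirna, ps$mirna), ]
      nod_ct <- nod_ct + as.numeric(ps$nod >= stats$nod)
      tfp_ct <- tfp_ct + as.numeric(ps$tfp >= stats$tfp)
    }
  })
  list(nod = nod_ct, tfp = tfp_ct)
}

# degree-preserving rewiring of a bipartite edge list by double edge swaps;
# attempts 2|E| swaps, rejecting any that would duplicate an edge
rewire_edges <- function(edges) {
  m <- edges$mirna
  g <- edges$gene
  key_env <- new.env(hash = TRUE, size = length(m) * 2)
  for (i in seq_along(m)) assign(paste(m[i], g[i]), TRUE, envir = key_env)
  n_attempt <- 2L * length(m)
  ij <- matrix(sample.int(length(m), 2 * n_attempt, replace = TRUE), ncol = 2)
  for (a in seq_len(n_attempt)) {
    i <- ij[a, 1]; j <- ij[a, 2]
    if (i == j || m[i] == m[j] || g[i] == g[j]) next
    k1 <- paste(m[i], g[j]); k2 <- paste(m[j], g[i])
    if (exists(k1, envir = key_env, inherits = FALSE) ||
        exists(k2, envir = key_env, inherits = FALSE)) next
    rm(list = c(paste(m[i], g[i]), paste(m[j], g[j])), envir = key_env)
    tmp <- g[i]; g[i] <- g[j]; g[j] <- tmp
    assign(k1, TRUE, envir = key_env)
    assign(k2, TRUE, envir = key_env)
  }
  tibble::tibble(mirna = m, gene = g)
}

#' Selected candidate miRNA IDs
#'
#' @param x A `poma_candidates` object.
#' @return Character vector of selected miRNA IDs, in ranking order.
#' @export
candidates <- function(x) {
  stopifnot(inherits(x, "poma_candidates"))
  x$mirna[x$selected]
}

#' Tidy a candidate-selection result
#'
#' @param x A `poma_candidates` object.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.poma_candidates <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a candidate selection
#'
#' @param x A `poma_candidates` object.
#' @param ... Unused.
#' @return A one-row tibble with counts, cutoff and mode.
#' @export
glance.poma_candidates <- function(x, ...) {
  tibble::tibble(
    n_mirnas = nrow(x),
    n_selected = sum(x$selected),
    alpha = attr(x, "alpha"),
    mode = attr(x, "mode"),
    label = attr(x, "label")
  )
}
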