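# All generators are pure functions of their arguments: the RNG state is
# saved, seeded locally, and restored on exit. A master seed is split into
# per-generator substreams by fixed offsets so components stay independent.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# substream offsets for the master seed
SEED_OFFSETS <- c(network = 101L, expression = 211L, gene_sets = 307L,
                  permutation = 401L)

split_seed <- function(seed, stream) {
  (as.integer(seed) + SEED_OFFSETS[[stream]]) %% .Machine$integer.max
}

# Poisson truncated at >= 1, by inverse-CDF on a uniform restricted above P(0)
rtpois <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

#' Simulate a reference miRNA-mRNA network with planted biomarkers
#'
#' Builds a bipartite regulatory network in which a chosen number of
#' "planted" miRNAs are engineered to have the signature the selection stage
#' looks for: each receives a block of private genes targeted by no other
#' miRNA (guaranteeing novel out-degree at least
#' `private_targets_per_planted` in any network containing it) and a boosted
#' fraction of transcription-factor targets. All other targeting is uniform
#' with out-degree drawn from a Poisson truncated at 1.
#'
#' @param n_mirna,n_gene Numbers of miRNAs and genes.
#' @param tf_fraction Fraction of genes flagged as transcription factors.
#' @param mean_out_degree Mean of the (truncated) Poisson out-degree.
#' @param n_planted Number of planted biomarker miRNAs.
#' @param private_targets_per_planted Private (singly-targeted) genes given
#'   to each planted miRNA.
#' @param planted_tf_boost Fraction of each planted miRNA's targets forced
#'   to be TF genes.
#' @param seed Integer seed; generation is a pure function of it.
#' @return A list with elements `network` ([mirna_network]) and `truth`
#'   (list with `planted_biomarkers`, `seed`, and the generator parameters).
#' @export
simulate_network <- function(n_mirna = 200, n_gene = 2000, tf_fraction = 0.1,
                             mean_out_degree = 8, n_planted = 10,
                             private_targets_per_planted = 15,
                             planted_tf_boost = 0.3, seed = 1) {
  stopifnot(n_mirna >= 1, n_gene >= 1, mean_out_degree > 0,
            tf_fraction >= 0, tf_fraction <= 1,
            planted_tf_boost >= 0, planted_tf_boost <= 1)
  if (n_planted > n_mirna) stop("n_planted exceeds n_mirna", call. = FALSE)
  if (n_planted * private_targets_per_planted > n_gene) {
    stop("infeasible: private-target demand exceeds the gene pool", call. = FALSE)
  }
  with_local_seed(split_seed(seed, "network"), {
    mirnas <- sprintf("mir-%04d", seq_len(n_mirna))
    genes <- sprintf("G%05d", seq_len(n_gene))
    planted <- if (n_planted > 0) sort(sample(mirnas, n_planted)) else character()

    n_private <- n_planted * private_targets_per_planted
    private_pool <- if (n_private > 0) sample(genes, n_private) else character()
    public_pool <- setdiff(genes, private_pool)

    deg <- rtpois(n_mirna, mean_out_degree)
    names(deg) <- mirnas
    target_list <- lapply(mirnas, function(m) {
      sample(public_pool, min(deg[[m]], length(public_pool)))
    })
    names(target_list) <- mirnas
    if (n_planted > 0) {
      blocks <- split(private_pool,
                      rep(seq_len(n_planted), each = private_targets_per_planted))
      for (i in seq_len(n_planted)) {
        m <- planted[i]
        target_list[[m]] <- union(target_list[[m]], blocks[[i]])
      }
    }

    # TF flags: a tf_fraction share of all genes; planted miRNAs first claim
    # a planted_tf_boost share of their own targets, the remainder of the TF
    # quota is spread uniformly over undecided genes
    n_tf <- round(tf_fraction * n_gene)
    forced_tf <- character()
    for (m in planted) {
      tg <- target_list[[m]]
      want <- round(planted_tf_boost * length(tg))
      have <- sum(tg %in% forced_tf)
      need <- max(0, want - have)
      avail <- setdiff(tg, forced_tf)
      if (need > 0 && length(avail) > 0) {
        forced_tf <- c(forced_tf, sample(avail, min(need, length(avail))))
      }
    }
    forced_tf <- utils::head(forced_tf, n_tf)
    rest <- setdiff(genes, forced_tf)
    tf_genes <- c(forced_tf, sample(rest, max(0, n_tf - length(forced_tf))))

    edges <- tibble::tibble(
      mirna = rep(mirnas, lengths(target_list)),
      gene = unlist(target_list, use.names = FALSE)
    )
    # untargeted genes may carry a TF flag; they are outside the network
    net <- suppressWarnings(mirna_network(edges, tf_genes))
    truth <- list(
      planted_biomarkers = planted,
      seed = seed,
      params = list(n_mirna = n_mirna, n_gene = n_gene,
                    tf_fraction = tf_fraction,
                    mean_out_degree = mean_out_degree, n_planted = n_planted,
                    private_targets_per_planted = private_targets_per_planted,
                    planted_tf_boost = planted_tf_boost)
    )
    list(network = net, truth = truth)
  })
}

#' Simulate case/control miRNA expression on a network
#'
#' Draws, for every miRNA in the network, a gene-wise variance from the
#' scaled inverse-chi-square prior `s0sq * d0 / chisq(d0)` — the model the
#' empirical-Bayes moderated-t estimator assumes — then samples control
#' values Normal(mu_g, sigma_g^2) and shifts case samples by a signed log2
#' fold change for the differentially expressed subset. Planted biomarkers
#' are always differentially expressed; when `lfc_magnitude` is zero the DE
#' set is empty by construction (a pure null).
#'
#' @param network A [mirna_network]; its miRNAs become the features.
#' @param n_control,n_case Samples per group (each at least 2).
#' @param de_fraction Fraction of miRNAs given a nonzero group effect.
#' @param lfc_magnitude Absolute log2 fold change of DE miRNAs.
#' @param d0,s0sq Prior degrees of freedom and prior variance of the
#'   inverse-chi-square variance model.
#' @param seed Integer seed.
#' @param planted Character vector of planted-biomarker miRNAs that must be
#'   DE (e.g. `truth$planted_biomarkers` from [simulate_network()]).
#' @return A list with elements `expr` ([mirna_expr]) and `truth` (list with
#'   `de_mirnas`, `effect_sizes`, `variance_prior`, `planted_biomarkers`,
#'   `seed`).
#' @export
simulate_expression <- function(network, n_control = 20, n_case = 20,
                                de_fraction = 0.3, lfc_magnitude = 1.5,
                                d0 = 4, s0sq = 0.05, seed = 1,
                                planted = character()) {
  stopifnot(n_control >= 2, n_case >= 2, d0 > 0, s0sq > 0, lfc_magnitude >= 0)
  if (de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must be in [0, 1]", call. = FALSE)
  }
  mirnas <- network$mirnas
  if (!all(planted %in% mirnas)) {
    stop("planted miRNA(s) absent from the network", call. = FALSE)
  }
  with_local_seed(split_seed(seed, "expression"), {
    m <- length(mirnas)
    if (lfc_magnitude == 0) {
      de <- character()
    } else {
      n_de <- max(round(de_fraction * m), length(planted))
      extra <- setdiff(mirnas, planted)
      de <- sort(c(planted, sample(extra, max(0, n_de - length(planted)))))
    }
    effects <- stats::setNames(numeric(m), mirnas)
    effects[de] <- sample(c(-1, 1), length(de), replace = TRUE) * lfc_magnitude

    mu <- stats::rnorm(m, mean = 7, sd = 1)
    sigma2 <- s0sq * d0 / stats::rchisq(m, df = d0)
    n_tot <- n_control + n_case
    vals <- matrix(stats::rnorm(m * n_tot, mean = mu, sd = sqrt(sigma2)),
                   nrow = m, ncol = n_tot)
    case_cols <- n_control + seq_len(n_case)
    vals[, case_cols] <- vals[, case_cols] + effects
    rownames(vals) <- mirnas
    colnames(vals) <- c(sprintf("ctrl_%02d", seq_len(n_control)),
                        sprintf("case_%02d", seq_len(n_case)))
    groups <- stats::setNames(
      rep(c("control", "disease"), c(n_control, n_case)), colnames(vals))
    truth <- list(
      planted_biomarkers = planted,
      de_mirnas = de,
      effect_sizes = effects,
      variance_prior = list(d0 = d0, s0sq = s0sq),
      seed = seed
    )
    list(expr = mirna_expr(vals, groups), truth = truth)
  })
}

#' Simulate pathway gene sets, optionally enriched for chosen miRNAs
#'
#' Background sets are uniform draws from the network's genes. For each
#' miRNA in `enriched_for`, one additional set draws an
#' `enrichment_strength` share of its members from that miRNA's uniquely
#' targeted genes (novel out-degree set in the full network), the rest
#' uniformly from the remaining genes.
#'
#' @param network A [mirna_network].
#' @param n_sets Number of background sets.
#' @param size_low,size_high Set-size range (inclusive, uniform).
#' @param enriched_for Character vector of miRNA IDs to plant enrichment for.
#' @param enrichment_strength Fraction of a planted set drawn from the
#'   miRNA's unique targets.
#' @param seed Integer seed.
#' @return A [gene_sets] object; planted sets are named
#'   `planted_<mirna>`.
#' @export
simulate_gene_sets <- function(network, n_sets = 20, size_low = 20,
                               size_high = 50, enriched_for = character(),
                               enrichment_strength = 0.8, seed = 1) {
  stopifnot(size_low <= size_high, n_sets >= 0,
            enrichment_strength >= 0, enrichment_strength <= 1)
  genes <- network$genes
  if (size_high > length(genes)) {
    stop("size_high exceeds the number of network genes", call. = FALSE)
  }
  unknown <- setdiff(enriched_for, network$mirnas)
  if (length(unknown) > 0) {
    stop("enriched_for contains unknown miRNA(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_local_seed(split_seed(seed, "gene_sets"), {
    sets <- list()
    for (i in seq_len(n_sets)) {
      sz <- sample(size_low:size_high, 1)
      sets[[sprintf("background_%03d", i)]] <- sample(genes, sz)
    }
    indeg <- table(network$edges$gene)
    for (m in enriched_for) {
      tg <- network$edges$gene[network$edges$mirna == m]
      uniq <- tg[indeg[tg] == 1]
      sz <- sample(size_low:size_high, 1)
      n_from <- min(round(enrichment_strength * sz), length(uniq))
      members <- c(sample(uniq, n_from),
                   sample(setdiff(genes, uniq), sz - n_from))
      sets[[paste0("planted_", m)]] <- members
    }
    desc <- stats::setNames(
      ifelse(grepl("^planted_", names(sets)), "planted enrichment", "background"),
      names(sets))
    gene_sets(sets, desc)
  })
}
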