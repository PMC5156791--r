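pipeline_defaults <- function() {
  list(
    seed = 1,
    simulate = TRUE,
    # input paths (used when simulate = FALSE)
    matrix = NULL, groups = NULL, network = NULL, tf = NULL,
    gmt = NULL, reported = NULL,
    label = "condition",
    alpha_de = 0.05,
    alpha_select = 0.05,
    selection_mode = "signed-rank",
    perm_iters = 1000,
    coverage_targets = "unique",
    universe = "network",
    # synthetic-data parameters (see simulate_* defaults)
    n_mirna = 200, n_gene = 2000, tf_fraction = 0.1, mean_out_degree = 8,
    n_planted = 10, private_targets_per_planted = 15, planted_tf_boost = 0.3,
    n_control = 20, n_case = 20, de_fraction = 0.3, lfc_magnitude = 1.5,
    d0 = 4, s0sq = 0.05,
    n_sets = 20, size_low = 20, size_high = 50, enrichment_strength = 0.8
  )
}

#' Read and validate a pipeline configuration file
#'
#' YAML (or one `key: value` per line) with any subset of the documented
#' keys; unknown keys are rejected before any computation. See
#' [run_pipeline()] for the schema and defaults.
#'
#' @param path Path to the config file.
#' @return A complete named list of parameters.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, cfg)
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes simulate (or load) -> differential expression -> condition
#' network -> NOD/TFP statistics -> candidate selection -> pathway
#' enrichment -> coverage -> validation -> report, writing each stage's
#' output as TSV/JSON into `out_dir` so any stage can be rerun or inspected
#' standalone. Every random draw derives from the single `seed` in the
#' config; two runs with the same config and inputs produce identical
#' outputs.
#'
#' @param config A config list, or a path readable by [read_run_config()].
#'   Keys (all optional): `seed`; `simulate` (TRUE to generate synthetic
#'   inputs; otherwise give paths `matrix`, `groups`, `network`, `tf`, and
#'   optionally `gmt`, `reported`); `label`; `alpha_de`, `alpha_select`;
#'   `selection_mode` (`signed-rank`/`permutation`) and `perm_iters`;
#'   `coverage_targets` (`unique`/`all`); `universe` (`network`/
#'   `gmt-union`); and the synthetic-data parameters of [simulate_network()],
#'   [simulate_expression()] and [simulate_gene_sets()].
#' @param out_dir Output directory for stage files.
#' @return The `poma_report`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pomanet_run_")) {
  cfg <- if (is.character(config)) read_run_config(config) else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  net <- NULL
  expr <- NULL
  truth <- NULL
  reported <- NULL
  sets <- NULL
  if (isTRUE(cfg$simulate)) {
    stage("simulate", {
      sim_net <- simulate_network(
        n_mirna = cfg$n_mirna, n_gene = cfg$n_gene,
        tf_fraction = cfg$tf_fraction, mean_out_degree = cfg$mean_out_degree,
        n_planted = cfg$n_planted,
        private_targets_per_planted = cfg$private_targets_per_planted,
        planted_tf_boost = cfg$planted_tf_boost, seed = cfg$seed)
      net <- sim_net$network
      sim_ex <- simulate_expression(net,
        n_control = cfg$n_control, n_case = cfg$n_case,
        de_fraction = cfg$de_fraction, lfc_magnitude = cfg$lfc_magnitude,
        d0 = cfg$d0, s0sq = cfg$s0sq, seed = cfg$seed,
        planted = sim_net$truth$planted_biomarkers)
      expr <- sim_ex$expr
      truth <- utils::modifyList(sim_net$truth, sim_ex$truth)
      sets <- simulate_gene_sets(net,
        n_sets = cfg$n_sets, size_low = cfg$size_low,
        size_high = cfg$size_high,
        enriched_for = sim_net$truth$planted_biomarkers,
        enrichment_strength = cfg$enrichment_strength, seed = cfg$seed)
      inp <- file.path(out_dir, "inputs")
      dir.create(inp, showWarnings = FALSE)
      write_edge_list(net, file.path(inp, "network.tsv"),
                      file.path(inp, "tf_genes.txt"))
      write_expression_matrix(expr, file.path(inp, "expression.tsv"),
                              file.path(inp, "groups.tsv"))
      write_gene_sets(sets, file.path(inp, "gene_sets.gmt"))
      jsonlite::write_json(truth, file.path(inp, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  } else {
    stage("load", {
      if (is.null(cfg$matrix) || is.null(cfg$groups) || is.null(cfg$network)) {
        stop("need 'matrix', 'groups' and 'network' paths when simulate is FALSE")
      }
      expr <- read_expression_matrix(cfg$matrix, cfg$groups)
      net <- read_edge_list(cfg$network, cfg$tf)
      if (!is.null(cfg$gmt)) sets <- read_gene_sets(cfg$gmt)
      if (!is.null(cfg$reported)) reported <- read_reported_biomarkers(cfg$reported)
    })
  }

  de <- stage("de", de_analysis(expr, alpha = cfg$alpha_de))
  readr::write_tsv(tidy(de), file.path(out_dir, "de.tsv"), progress = FALSE)

  cond <- stage("network", build_condition_network(net, select_de(de, cfg$alpha_de),
                                                   label = cfg$label))
  stats <- stage("netstats", compute_stats(cond))
  readr::write_tsv(stats, file.path(out_dir, "netstats.tsv"), progress = FALSE)

  cand <- stage("select", select_candidates(stats, alpha = cfg$alpha_select,
                                            mode = cfg$selection_mode,
                                            cond = cond,
                                            perm_iters = cfg$perm_iters,
                                            seed = cfg$seed))
  readr::write_tsv(tidy(cand), file.path(out_dir, "candidates_all.tsv"),
                   progress = FALSE)

  enr <- NULL
  cov <- NULL
  if (!is.null(sets) && length(candidates(cand)) > 0) {
    enr <- stage("enrich", {
      query <- sort(unique(unlist(lapply(candidates(cand), unique_targets,
                                         cond = cond))))
      universe <- if (identical(cfg$universe, "gmt-union")) {
        sort(unique(unlist(sets$sets)))
      } else net$genes
      enrich(query, sets, universe)
    })
    readr::write_tsv(tidy(enr), file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
    cov <- stage("coverage",
                 suppressWarnings(pathway_coverage(cond, cand, enr, sets,
                                                   targets = cfg$coverage_targets)))
    readr::write_tsv(cov, file.path(out_dir, "coverage.tsv"), progress = FALSE)
  }

  report <- stage("report", build_report(de, cand, enr, cov,
                                         reported = reported, truth = truth,
                                         seed = cfg$seed, params = cfg))
  write_report(report, cand, out_dir, coverage = cov)
  invisible(report)
}
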