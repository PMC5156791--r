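test_that("miRNA ID normalisation strips prefixes, canonicalises stars, and is idempotent", {
  cases <- c("hsa-miR-155" = "mir-155",
             "miR-340*" = "mir-340*",
             "miR-340^*∗*^" = "mir-340*",
             "MIR-145" = "mir-145",
             "hsa-let-7g" = "let-7g",
             "miR-590-5p" = "mir-590-5p")
  expect_identical(normalize_mirna_id(names(cases)), unname(cases))
  # idempotence on a varied pool
  pool <- c(names(cases), unname(cases), "miR-22*", "hsa-miR-126 ")
  once <- normalize_mirna_id(pool)
  expect_identical(normalize_mirna_id(once), once)
  # star and non-star arms stay distinct
  expect_false(normalize_mirna_id("miR-340") == normalize_mirna_id("miR-340*"))
  expect_error(normalize_mirna_id(""), "non-empty")
})

test_that("expression matrix parsing validates, collapses duplicates, and maps groups", {
  d <- withr::local_tempdir()
  mat <- file.path(d, "m.tsv")
  grp <- file.path(d, "g.tsv")
  writeLines(c("mirna\ts1\ts2\ts3\ts4",
               "miR-1\t1\t2\t3\t4",
               "miR-2\t0\t0\t1\t1",
               "hsa-miR-3\t5\t5\t5\t5"), mat)
  writeLines(c("sample\tlabel", "s1\tcontrol", "s2\tcontrol",
               "s3\tdisease", "s4\tdisease"), grp)
  ex <- read_expression_matrix(mat, grp)
  expect_equal(dim(ex$values), c(3, 4))
  expect_setequal(rownames(ex$values), c("mir-1", "mir-2", "mir-3"))
  expect_equal(as.vector(table(ex$groups)[c("control", "disease")]), c(2L, 2L))

  # duplicated feature rows collapse by mean with a warning
  writeLines(c("mirna\ts1\ts2\ts3\ts4",
               "miR-1\t1\t2\t3\t4",
               "hsa-miR-1\t3\t4\t5\t6"), mat)
  expect_warning(ex2 <- read_expression_matrix(mat, grp), "collapsed")
  expect_equal(nrow(ex2$values), 1)
  expect_equal(unname(ex2$values["mir-1", ]), c(2, 3, 4, 5))

  # missing group label names the sample; non-numeric cell is located
  writeLines(c("sample\tlabel", "s1\tcontrol", "s2\tcontrol", "s3\tdisease"), grp)
  suppressWarnings(expect_error(read_expression_matrix(mat, grp), "s4"))
  writeLines(c("mirna\ts1", "miR-1\tabc"), mat)
  writeLines(c("s1\tcontrol"), grp)
  expect_error(read_expression_matrix(mat, grp), "non-numeric")
})

test_that("edge lists deduplicate, restrict TF genes, and reject malformed input", {
  d <- withr::local_tempdir()
  ef <- file.path(d, "edges.tsv")
  tf <- file.path(d, "tf.txt")
  writeLines(c("# comment", "miR-1\tG1", "miR-1\tG2", "hsa-miR-1\tg2",
               "miR-2\tG2", "miR-2\tG3"), ef)
  writeLines(c("G1", "G9"), tf)
  expect_warning(
    expect_message(net <- read_edge_list(ef, tf), "duplicate"),
    "absent")
  expect_equal(nrow(net$edges), 4)
  expect_identical(net$tf_genes, "G1")

  writeLines(c("miR-1\tG1\textra"), ef)
  expect_error(read_edge_list(ef), "line 1")
  writeLines(character(), ef)
  expect_error(read_edge_list(ef), "empty network")
})

test_that("GMT parsing enforces unique names, set semantics, and field counts", {
  d <- withr::local_tempdir()
  gmt <- file.path(d, "sets.gmt")
  writeLines(c("pwA\tdesc\tg1\tg2\tg3",
               "pwB\t\tg2\tg2\tg4",
               "pwC\tx\tg5"), gmt)
  gs <- read_gene_sets(gmt)
  expect_equal(lengths(gs$sets)[c("pwA", "pwB", "pwC")],
               c(pwA = 3L, pwB = 2L, pwC = 1L))
  expect_identical(gs$sets$pwB, c("G2", "G4"))

  writeLines(c("pwA\td\tg1", "pwA\td\tg2"), gmt)
  expect_error(read_gene_sets(gmt), "duplicate")
  writeLines(c("pwA\tg1"), gmt)
  expect_error(read_gene_sets(gmt), "line 1")
})

test_that("reported-biomarker lists normalise IDs and default missing fields", {
  d <- withr::local_tempdir()
  f <- file.path(d, "rep.tsv")
  writeLines(c("mirna\trole", "hsa-miR-155\tprognostic", "miR-126\tdiagnostic",
               "miR-208b\tboth", "miR-133a\tweird", "miR-16\t"), f)
  rb <- read_reported_biomarkers(f)
  expect_equal(nrow(rb), 5)
  expect_identical(rb$mirna[1], "mir-155")
  expect_identical(rb$role, c("prognostic", "diagnostic", "both", "unknown", "unknown"))
  expect_true(all(rb$direction == "unknown"))

  writeLines(c("mirna", "miR-1"), f)
  expect_identical(read_reported_biomarkers(f)$role, "unknown")
  writeLines("mirna", f)
  expect_error(read_reported_biomarkers(f), "empty")
})

test_that("network and gene-set round-trips reproduce identical objects, order-insensitively", {
  sim <- simulate_network(n_mirna = 15, n_gene = 60, n_planted = 2,
                          private_targets_per_planted = 5, seed = 42)
  d <- withr::local_tempdir()
  ef <- file.path(d, "e.tsv"); tf <- file.path(d, "t.txt")
  write_edge_list(sim$network, ef, tf)
  back <- read_edge_list(ef, tf)
  expect_identical(dplyr::arrange(back$edges, mirna, gene),
                   dplyr::arrange(sim$network$edges, mirna, gene))
  expect_identical(back$tf_genes, sim$network$tf_genes)

  # permuting input lines yields the identical object
  lines <- readLines(ef)
  shuffled <- c(lines[1], sample(lines[-1]))
  ef2 <- file.path(d, "e2.tsv")
  writeLines(shuffled, ef2)
  back2 <- read_edge_list(ef2, tf)
  expect_identical(dplyr::arrange(back2$edges, mirna, gene),
                   dplyr::arrange(back$edges, mirna, gene))

  gs <- simulate_gene_sets(sim$network, n_sets = 5, size_low = 3, size_high = 8,
                           seed = 9)
  gf <- file.path(d, "s.gmt")
  write_gene_sets(gs, gf)
  gs2 <- read_gene_sets(gf)
  expect_identical(gs2$sets, gs$sets)
})
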