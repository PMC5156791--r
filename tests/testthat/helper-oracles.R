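# Shared fixtures and independent brute-force oracles.

# tiny two-miRNA network used across modules
toy_network <- function() {
  mirna_network(
    tibble::tibble(
      mirna = c("mir-1", "mir-1", "mir-1", "mir-2", "mir-2", "mir-2"),
      gene = c("G1", "G2", "G3", "G2", "G3", "G4")
    ),
    tf_genes = c("G1", "G4")
  )
}

# brute-force NOD: scan every (gene, miRNA) pair
brute_nod <- function(net) {
  sapply(net$mirnas, function(m) {
    tg <- net$edges$gene[net$edges$mirna == m]
    sum(vapply(tg, function(g) {
      sum(net$edges$gene == g) == 1
    }, logical(1)))
  })
}

# brute-force upper-tail hypergeometric by enumerating every possible draw
brute_hypergeom_tail <- function(overlap, query_size, set_size, universe_size) {
  universe <- seq_len(universe_size)
  inset <- seq_len(set_size)
  draws <- utils::combn(universe, query_size)
  mean(apply(draws, 2, function(d) sum(d %in% inset) >= overlap))
}

# brute-force one-sample signed-rank p by enumerating all sign assignments
brute_signed_rank <- function(values, location, alternative) {
  d <- values - location
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

# expression object built directly from a matrix of control|case columns
make_expr <- function(mat, n_control) {
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  rownames(mat) <- sprintf("mir-%03d", seq_len(nrow(mat)))
  groups <- stats::setNames(
    rep(c("control", "disease"), c(n_control, ncol(mat) - n_control)),
    colnames(mat))
  mirna_expr(mat, groups)
}

# path to a curated ACS fixture
acs_file <- function(name) {
  system.file("extdata", "acs", name, package = "pomanet", mustWork = TRUE)
}
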