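test_that("two-group fit reproduces hand-computed OLS and is order-invariant", {
  # control (1,1), case (3,3): exact means, zero residual variance
  ex <- make_expr(matrix(c(1, 1, 3, 3), nrow = 1), n_control = 2)
  f <- fit_group_model(ex)
  expect_equal(f$log_fold_change, 2)
  expect_equal(f$sigma, 0)
  expect_true(f$zero_variance)

  # control (0,2), case (1,3): lfc 1, pooled sigma sqrt(2), df 2
  ex2 <- make_expr(matrix(c(0, 2, 1, 3), nrow = 1), n_control = 2)
  f2 <- fit_group_model(ex2)
  expect_equal(f2$log_fold_change, 1)
  expect_equal(f2$sigma, sqrt(2))
  expect_equal(f2$df_residual, 2)
  expect_equal(f2$unscaled_se, sqrt(1 / 2 + 1 / 2))

  # permuting samples leaves every output unchanged
  m <- matrix(rnorm(40), nrow = 4)
  ex3 <- make_expr(m, n_control = 5)
  perm <- sample(ncol(m))
  ex4 <- mirna_expr(ex3$values[, perm], ex3$groups[perm])
  expect_equal(fit_group_model(ex3), fit_group_model(ex4))

  expect_error(fit_group_model(make_expr(matrix(1:3, 1), n_control = 1)),
               "at least 2")
})

test_that("variance-prior estimation recovers simulated (d0, s0sq) and scales correctly", {
  # identical variances: infinite-d0 branch
  pr <- estimate_prior(rep(0.3, 10), 4)
  expect_true(is.infinite(pr$d0))
  expect_equal(pr$s0sq, exp(mean(log(0.09) - digamma(2) + log(2))))

  # parameter recovery on direct scaled inverse-chi-square draws
  dg <- 8
  rec <- sapply(1:50, function(s) {
    set.seed(s)
    sigma2 <- 0.05 * 4 / rchisq(2000, df = 4)
    s2 <- sigma2 * rchisq(2000, df = dg) / dg
    pr <- estimate_prior(sqrt(s2), dg)
    c(d0 = pr$d0, s0sq = pr$s0sq)
  })
  expect_gte(median(rec["d0", ]), 3)
  expect_lte(median(rec["d0", ]), 5.5)
  expect_lt(abs(median(rec["s0sq", ]) - 0.05) / 0.05, 0.15)

  # scale equivariance: doubling variances doubles s0sq, leaves d0 fixed
  set.seed(1)
  s <- sqrt(0.05 * 4 / rchisq(500, 4) * rchisq(500, dg) / dg)
  p1 <- estimate_prior(s, dg)
  p2 <- estimate_prior(s * sqrt(2), dg)
  expect_equal(p2$d0, p1$d0, tolerance = 1e-8)
  expect_equal(p2$s0sq, 2 * p1$s0sq, tolerance = 1e-8)

  expect_error(estimate_prior(c(0, 0, 0), 4), "no variance")
})

test_that("moderation interpolates between ordinary t and the prior", {
  ex <- make_expr(matrix(rnorm(200, sd = 0.5), nrow = 20), n_control = 5)
  fit <- fit_group_model(ex)
  prior <- estimate_prior(fit$sigma, fit$df_residual)
  mod <- moderate(fit, prior)

  # posterior variance lies between the sample variance and the prior
  lo <- pmin(fit$sigma^2, prior$s0sq)
  hi <- pmax(fit$sigma^2, prior$s0sq)
  expect_true(all(mod$s2_post >= lo - 1e-12 & mod$s2_post <= hi + 1e-12))

  # d0 -> 0 limit: moderated t equals the ordinary two-sample t
  mod0 <- moderate(fit, list(d0 = 1e-12, s0sq = prior$s0sq))
  t_ord <- fit$log_fold_change / (fit$sigma * fit$unscaled_se)
  expect_equal(mod0$t_moderated, t_ord, tolerance = 1e-5)

  # lfc = 0 gives t = 0, p = 1
  exz <- make_expr(rbind(c(1, 2, 1, 2)), n_control = 2)
  fz <- fit_group_model(exz)
  mz <- moderate(fz, list(d0 = 4, s0sq = 0.05))
  expect_equal(mz$t_moderated, 0)
  expect_equal(mz$p_raw, 1)
})

test_that("moderated p-value matches a Monte-Carlo null tail probability", {
  # one hand-built feature under the null of its own moderated model
  d0 <- 4; s0sq <- 0.05; dg <- 6; se <- sqrt(1 / 4 + 1 / 4)
  fit <- tibble::tibble(mirna = "m", log_fold_change = 0.35, sigma = 0.25,
                        df_residual = dg, unscaled_se = se,
                        zero_variance = FALSE)
  p_cdf <- moderate(fit, list(d0 = d0, s0sq = s0sq))$p_raw

  set.seed(99)
  n <- 1e6
  sigma2 <- s0sq * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  lfc <- rnorm(n, 0, sqrt(sigma2) * se)
  s2_post <- (d0 * s0sq + dg * s2) / (d0 + dg)
  t_obs <- fit$log_fold_change / (sqrt((d0 * s0sq + dg * fit$sigma^2) / (d0 + dg)) * se)
  t_null <- lfc / (sqrt(s2_post) * se)
  p_mc <- mean(abs(t_null) >= abs(t_obs))
  mc_se <- sqrt(p_mc * (1 - p_mc) / n)
  expect_lt(abs(p_cdf - p_mc), 3 * mc_se)
})

test_that("moderated statistics agree with the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(42)
  net <- simulate_network(n_mirna = 120, n_gene = 500, n_planted = 5,
                          private_targets_per_planted = 5, seed = 42)
  sim <- simulate_expression(net$network, n_control = 8, n_case = 8, seed = 42,
                             planted = net$truth$planted_biomarkers)
  de <- de_analysis(sim$expr)

  design <- cbind(1, as.numeric(sim$expr$groups == "disease"))
  lf <- limma::lmFit(sim$expr$values, design)
  eb <- limma::eBayes(lf)
  ord <- match(de$table$mirna, rownames(sim$expr$values))
  expect_equal(de$prior$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(de$prior$s0sq, eb$s2.prior, tolerance = 1e-6)
  expect_equal(de$table$t_moderated, unname(eb$t[ord, 2]), tolerance = 1e-8)
  expect_equal(de$table$p_raw, unname(eb$p.value[ord, 2]), tolerance = 1e-8)
})

test_that("BH adjustment matches the hand step-up computation and stays monotone", {
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")

  # permutation equivariance and monotonicity
  set.seed(3)
  p <- runif(30)
  q <- adjust_bh(p)
  perm <- sample(30)
  expect_equal(adjust_bh(p[perm]), q[perm])
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("DE selection is strict at the cutoff and controls the null", {
  tab <- tibble::tibble(mirna = c("a", "b", "c"),
                        p_adjusted = c(0.04, 0.05, 0.06))
  expect_identical(select_de(tab, 0.05), "a")
  expect_length(select_de(tab, 0), 0)

  # null calibration: selected count stays within the false-positive budget
  net <- simulate_network(n_mirna = 200, n_gene = 600, n_planted = 0, seed = 2)
  n_sel <- vapply(1:20, function(s) {
    sim <- simulate_expression(net$network, n_control = 10, n_case = 10,
                               lfc_magnitude = 0, seed = s)
    length(select_de(de_analysis(sim$expr)))
  }, numeric(1))
  expect_lte(mean(n_sel), 0.05 * 200)
})
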