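#' Fit the two-group linear model per miRNA
#'
#' Ordinary least squares for the design control vs disease: per feature the
#' log2 fold change is the difference of group means (disease minus
#' control), the residual SD is pooled across the two groups with
#' `n_total - 2` degrees of freedom, and the unscaled standard error is
#' `sqrt(1/n_case + 1/n_control)`. Constant (zero-variance) features keep
#' `sigma = 0` and are flagged; they are moderated entirely by the prior
#' downstream.
#'
#' @param expr A [mirna_expr] object with both groups of size at least 2.
#' @return A tibble with columns `mirna`, `log_fold_change`, `sigma`,
#'   `df_residual`, `unscaled_se`, `zero_variance`.
#' @export
fit_group_model <- function(expr) {
  stopifnot(inherits(expr, "mirna_expr"))
  ctrl <- expr$values[, expr$groups == "control", drop = FALSE]
  case <- expr$values[, expr$groups == "disease", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(case)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(expr$values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  mu1 <- rowMeans(ctrl)
  mu2 <- rowMeans(case)
  sse <- rowSums((ctrl - mu1)^2) + rowSums((case - mu2)^2)
  df <- n1 + n2 - 2
  sigma <- sqrt(sse / df)
  tibble::tibble(
    mirna = rownames(expr$values),
    log_fold_change = unname(mu2 - mu1),
    sigma = unname(sigma),
    df_residual = df,
    unscaled_se = sqrt(1 / n1 + 1 / n2),
    zero_variance = sigma == 0
  )
}

# invert the trigamma function by Newton's method (monotone decreasing, so
# convergence from the asymptotic start 0.5 + 1/x is global in practice)
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Estimate the variance prior (d0, s0sq) across features
#'
#' Method-of-moments on log sample variances under the scaled
#' inverse-chi-square model: with `e_g = log(s_g^2) - digamma(d_g/2) +
#' log(d_g/2)`, the prior degrees of freedom solve
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` by trigamma inversion,
#' and the prior variance follows from `mean(e) = log(s0sq) -
#' digamma(d0/2) + log(d0/2)` (the mean of the log F-distributed variance
#' ratio). If the observed dispersion of `e` does not
#' exceed its sampling expectation the prior degrees of freedom are
#' infinite (no evidence of variance heterogeneity) and `s0sq =
#' exp(mean(e))`. Zero-variance features are excluded from estimation.
#'
#' @param sigma Per-feature residual SDs.
#' @param df Per-feature residual degrees of freedom (scalar or vector).
#' @return A list with elements `d0` (possibly `Inf`) and `s0sq`.
#' @export
estimate_prior <- function(sigma, df) {
  df <- rep_len(df, length(sigma))
  keep <- is.finite(sigma) & sigma > 0 & df > 0
  if (sum(keep) < 2) stop("no variance information", call. = FALSE)
  s2 <- sigma[keep]^2
  dg <- df[keep]
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(dg / 2))
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s0sq = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Moderate per-feature t-statistics with the variance prior
#'
#' Shrinks each feature's variance toward the prior: `s2_post = (d0*s0sq +
#' df*s^2) / (d0 + df)` (`= s0sq` when d0 is infinite), forms `t =
#' lfc / (sqrt(s2_post) * unscaled_se)` and a two-sided p-value from the
#' t-distribution with `d0 + df` degrees of freedom.
#'
#' @param fit Output of [fit_group_model()].
#' @param prior Output of [estimate_prior()].
#' @return `fit` with columns `s2_post`, `t_moderated`, `p_raw` added.
#' @export
moderate <- function(fit, prior) {
  d0 <- prior$d0
  s0sq <- prior$s0sq
  s2 <- fit$sigma^2
  dg <- fit$df_residual
  s2_post <- if (is.infinite(d0)) rep(s0sq, nrow(fit)) else {
    (d0 * s0sq + dg * s2) / (d0 + dg)
  }
  t_mod <- fit$log_fold_change / (sqrt(s2_post) * fit$unscaled_se)
  df_tot <- d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_tot)
  p[fit$log_fold_change == 0] <- 1
  dplyr::mutate(fit, s2_post = s2_post, t_moderated = t_mod, p_raw = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values; a thin,
#' validating wrapper around `stats::p.adjust(method = "BH")` so every
#' stage corrects p-values through one surface.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression analysis of a case/control expression matrix
#'
#' Runs the full moderated-t pipeline: two-group fit, variance-prior
#' estimation, moderation, and BH adjustment, flagging features with
#' adjusted p below `alpha` as differentially expressed.
#'
#' @param expr A [mirna_expr] object.
#' @param alpha Adjusted-p cutoff (strict `<`), default 0.05.
#' @return An object of class `poma_de`: list with `table` (per-feature
#'   tibble), `prior` (`d0`, `s0sq`) and `alpha`.
#' @export
de_analysis <- function(expr, alpha = 0.05) {
  fit <- fit_group_model(expr)
  if (any(fit$zero_variance)) {
    message(sprintf("%d zero-variance feature(s) moderated by the prior alone",
                    sum(fit$zero_variance)))
  }
  prior <- estimate_prior(fit$sigma, fit$df_residual)
  tab <- moderate(fit, prior)
  tab$p_adjusted <- adjust_bh(tab$p_raw)
  tab$is_de <- tab$p_adjusted < alpha
  structure(list(table = tab, prior = prior, alpha = alpha),
            class = "poma_de")
}

#' Differentially expressed miRNA IDs
#'
#' @param de A `poma_de` object (or its per-feature tibble).
#' @param alpha Adjusted-p cutoff (strict `<`).
#' @return Character vector of DE miRNA IDs.
#' @export
select_de <- function(de, alpha = 0.05) {
  tab <- if (inherits(de, "poma_de")) de$table else tibble::as_tibble(de)
  tab$mirna[tab$p_adjusted < alpha]
}

#' @export
print.poma_de <- function(x, ...) {
  cat(sprintf("<poma_de> %d features, %d DE at adjusted p < %g (d0 = %.3g, s0sq = %.3g)\n",
              nrow(x$table), sum(x$table$is_de), x$alpha, x$prior$d0, x$prior$s0sq))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-feature differential-expression table
#'
#' @param x A `poma_de` object.
#' @param ... Unused.
#' @return The per-feature tibble.
#' @export
tidy.poma_de <- function(x, ...) x$table

#' One-row summary of a differential-expression fit
#'
#' @param x A `poma_de` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_features`, `n_de`, `d0`, `s0sq`, `alpha`.
#' @export
glance.poma_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$table),
    n_de = sum(x$table$is_de),
    d0 = x$prior$d0,
    s0sq = x$prior$s0sq,
    alpha = x$alpha
  )
}
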