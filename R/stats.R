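# Statistical primitives shared by every classification stage:
# empirical-Bayes moderated t, Benjamini-Yekutieli adjustment,
# two-proportion chi-square, and plain one/two-sample t-tests with
# defined zero-variance limits.

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR control valid under arbitrary dependence: sorted p-values
#' are scaled by `m * c(m) / rank` with `c(m) = sum(1/(1:m))`, then the
#' running minimum from the largest rank downward is taken and capped at
#' 1. Wraps [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
adjust_by <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BY")
}

#' Two-proportion chi-square test
#'
#' Compares x1/n1 against x2/n2 by the 1-df chi-square on the 2x2 table,
#' with Yates continuity correction by default. Wraps
#' [stats::prop.test()].
#'
#' @param x1,n1 Successes and trials in the first group.
#' @param x2,n2 Successes and trials in the second group.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List with `chi_sq` and `p_value`.
#' @export
prop_test <- function(x1, n1, x2, n2, correct = TRUE) {
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be at least 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("counts must satisfy 0 <= x <= n")
  }
  ht <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = correct))
  list(chi_sq = unname(ht$statistic), p_value = ht$p.value)
}

#' One-sample t-test with defined zero-variance limit
#'
#' @param values Numeric vector, length >= 2.
#' @param mu0 Null mean.
#' @return List with `t` and `p_value`. When the sample variance is zero
#'   the limit is taken: `t = 0, p = 1` if the mean equals `mu0`,
#'   otherwise `t = +/-Inf, p = 0`.
#' @export
one_sample_t <- function(values, mu0) {
  if (length(values) < 2L) stop("one_sample_t needs at least 2 values")
  stderr <- sqrt(stats::var(values) / length(values))
  scale <- max(abs(mean(values)), abs(mu0), 1)
  if (stderr < 10 * .Machine$double.eps * scale) {
    d <- mean(values) - mu0
    if (abs(d) < 1e-10 * scale) return(list(t = 0, p_value = 1))
    return(list(t = sign(d) * Inf, p_value = 0))
  }
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), p_value = ht$p.value)
}

#' Two-sample t-test with defined zero-variance limit
#'
#' @param a,b Numeric vectors, each length >= 2.
#' @param var_equal Use the pooled-variance test instead of Welch
#'   (default `FALSE`, i.e. Welch).
#' @return List with `t` and `p_value`; the statistic is positive when
#'   `mean(a) > mean(b)`. With zero variance in both groups the limit is
#'   `t = 0, p = 1` for equal means and `t = +/-Inf, p = 0` otherwise.
#' @export
two_sample_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("two_sample_t needs at least 2 values per group")
  }
  stderr <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  scale <- max(abs(mean(a)), abs(mean(b)), 1)
  if (stderr < 10 * .Machine$double.eps * scale) {
    d <- mean(a) - mean(b)
    if (abs(d) < 1e-10 * scale) return(list(t = 0, p_value = 1))
    return(list(t = sign(d) * Inf, p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p_value = ht$p.value)
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing target,
# well conditioned on the log scale).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) stop("trigamma_inverse needs x > 0")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Fit the variance-prior hyperparameters
#'
#' Moment-matching fit of the scaled inverse chi-square prior for
#' gene-wise variances, on the log scale: with `z = log(s2)`,
#' `e = z - digamma(df/2) + log(df/2)` is an unbiased estimate of
#' `log(sigma2)` plus a known-variance error term; matching the mean and
#' the excess variance of `e` over `trigamma(df/2)` gives the prior
#' degrees of freedom `d0` and prior variance `s0_sq`. A non-positive
#' excess variance yields `d0 = Inf` (all genes share `s0_sq`).
#'
#' @param s2 Gene-wise residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @return List with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("need at least 2 positive variances to fit the prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Core contrast on two replicate matrices (genes x reps). Returns the
# full ContrastResult data frame. d0/s0_sq may be forced: d0 = 0 gives
# the classical pooled t, d0 = Inf uses s0_sq for every gene.
moderated_t_mat <- function(m1, m2, gene_ids = rownames(m1),
                            d0 = NULL, s0_sq = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n1 <- ncol(m1); n2 <- ncol(m2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 replicates")
  if (nrow(m1) != nrow(m2)) stop("matrices must have the same genes")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(nrow(m1)))
  mean1 <- rowMeans(m1); mean2 <- rowMeans(m2)
  log_fc <- mean1 - mean2
  df <- n1 + n2 - 2
  ss <- rowSums((m1 - mean1)^2) + rowSums((m2 - mean2)^2)
  s2 <- ss / df

  if (is.null(d0)) {
    if (all(s2 == 0)) {
      warning("all gene-wise variances are zero; prior cannot be fitted, ",
              "falling back to the ordinary t-test")
      d0 <- 0
    } else {
      prior <- fit_variance_prior(s2, df)
      d0 <- prior$d0
      if (is.null(s0_sq)) s0_sq <- prior$s0_sq
    }
  }
  if (d0 > 0 && is.null(s0_sq)) {
    s0_sq <- fit_variance_prior(s2, df)$s0_sq
  }

  if (d0 == 0) {
    s2_post <- s2
    df_total <- df
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- d0 + df
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, log_fc / se,
                   ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df = df_total),
              0)
  p[se == 0 & log_fc == 0] <- 1
  data.frame(gene_id = gene_ids, log_fc = log_fc, t_stat = t_stat,
             p_value = p, p_adjusted = adjust_by(p),
             df_total = rep(df_total, length(p)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Empirical-Bayes moderated t-test between two sample groups
#'
#' Per gene, the pooled two-group residual variance `s2_g` (df =
#' n1 + n2 - 2) is shrunk toward a prior fitted across all genes by
#' moment matching on log variances ([fit_variance_prior()]): the
#' posterior variance is `(d0 * s0_sq + df * s2_g) / (d0 + df)` and the
#' moderated statistic `(mean1 - mean2) / (s_post * sqrt(1/n1 + 1/n2))`
#' is referred to a t distribution on `d0 + df` degrees of freedom.
#' P-values are Benjamini-Yekutieli adjusted across genes.
#'
#' @param dataset An `ExpressionDataset`.
#' @param group1_samples,group2_samples Disjoint character vectors of
#'   sample identifiers, each with >= 2 replicates.
#' @param method `"moderated"` (default) or `"ordinary"` for the
#'   classical pooled-variance t-test (equivalent to forcing `d0 = 0`).
#' @param d0,s0_sq Optional forced hyperparameters (mainly for testing
#'   limiting behaviour): `d0 = 0` recovers the ordinary t, `d0 = Inf`
#'   uses `s0_sq` as every gene's variance.
#' @return Data frame with columns `gene_id`, `log_fc` (group1 minus
#'   group2 on the log2 scale), `t_stat`, `p_value`, `p_adjusted`,
#'   `df_total`.
#' @export
moderated_t <- function(dataset, group1_samples, group2_samples,
                        method = c("moderated", "ordinary"),
                        d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  method <- match.arg(method)
  if (length(intersect(group1_samples, group2_samples))) {
    stop("sample groups must be disjoint")
  }
  missing_s <- setdiff(c(group1_samples, group2_samples),
                       dataset$samples$sample_id)
  if (length(missing_s)) {
    stop("unknown samples: ", paste(missing_s, collapse = ", "))
  }
  if (method == "ordinary" && is.null(d0)) d0 <- 0
  moderated_t_mat(dataset$values[, group1_samples, drop = FALSE],
                  dataset$values[, group2_samples, drop = FALSE],
                  gene_ids = dataset$gene_ids, d0 = d0, s0_sq = s0_sq)
}
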