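#' One-tailed Welch's t-test
#'
#' Tests whether `sample_a` has a larger mean than `sample_b` without
#' assuming equal variances, using the Welch statistic with Satterthwaite
#' degrees of freedom. This is the test comparing a feature set's fold
#' accuracies to the shuffled-label chance accuracies. When both samples
#' have zero variance and equal means the p-value is 0.5 by convention.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return A `stat_report` list: `test_name`, `statistic` (t), `df`
#'   (real-valued), `p_value` (one-tailed, for mean(a) > mean(b)).
#' @export
welch_one_tailed <- function(sample_a, sample_b) {
  na <- length(sample_a)
  nb <- length(sample_b)
  if (na < 2 || nb < 2) stopf("both samples need >= 2 values")
  va <- var(sample_a)
  vb <- var(sample_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    d <- mean(sample_a) - mean(sample_b)
    p <- if (d > 0) 0 else if (d < 0) 1 else 0.5
    return(stat_report("welch_one_tailed", statistic = 0,
                       df = NA_real_, p_value = p))
  }
  t_stat <- (mean(sample_a) - mean(sample_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  stat_report("welch_one_tailed", statistic = t_stat, df = df,
              p_value = stats::pt(t_stat, df, lower.tail = FALSE))
}

#' One-way ANOVA with Tukey-Kramer post hoc test
#'
#' Compares the fold accuracies of the feature sets: one-way ANOVA F with
#' degrees of freedom `(g - 1, N - g)`, Tukey-Kramer pairwise p-values from
#' the studentized-range distribution (valid for unequal group sizes), and
#' a Bonferroni correction of the ANOVA p-value for the number of
#' classification tasks (3 in the emulated study). The Bonferroni product
#' is capped at 1; the uncapped product is retained as
#' `adjusted_p_uncapped`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#'   Names, if present, label the pairwise comparisons.
#' @param bonferroni_m Number of tests the ANOVA p is corrected for
#'   (default 3).
#' @return A `stat_report` with `statistic` (F), `df` (length-2),
#'   `p_value`, `adjusted_p`, `adjusted_p_uncapped` and `pairwise` (data
#'   frame: pair, diff, p).
#' @export
anova_tukey <- function(groups, bonferroni_m = 3L) {
  if (length(groups) < 2L) stopf("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stopf("each group needs >= 2 values")
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  g <- length(groups)
  ns <- vapply(groups, length, 0L)
  n <- sum(ns)
  means <- vapply(groups, mean, 0)
  grand <- sum(ns * means) / n
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- g - 1L
  df2 <- n - g
  if (ssw == 0 && ssb == 0) {
    f <- 0
    p <- 1
  } else if (ssw == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  mse <- if (df2 > 0) ssw / df2 else NA_real_
  pairs <- utils::combn(g, 2)
  pairwise <- data.frame(
    pair = apply(pairs, 2, function(ij) {
      paste(names(groups)[ij], collapse = " vs ")
    }),
    diff = apply(pairs, 2, function(ij) means[ij[1]] - means[ij[2]]),
    p = apply(pairs, 2, function(ij) {
      if (!is.finite(mse) || mse == 0) {
        return(as.numeric(means[ij[1]] == means[ij[2]]))
      }
      q <- abs(means[ij[1]] - means[ij[2]]) /
        sqrt(mse / 2 * (1 / ns[ij[1]] + 1 / ns[ij[2]]))
      ptukey(q, nmeans = g, df = df2, lower.tail = FALSE)
    }),
    stringsAsFactors = FALSE
  )
  raw_adj <- p * bonferroni_m
  stat_report("anova_tukey", statistic = f, df = c(df1, df2), p_value = p,
              adjusted_p = min(1, raw_adj), adjusted_p_uncapped = raw_adj,
              pairwise = pairwise)
}

#' Pearson chi-squared test of homogeneity
#'
#' Tests independence of the rows and columns of a contingency table (e.g.
#' molecular subtype x scanner field strength) with the Pearson statistic
#' `sum((O - E)^2 / E)`, `E = row * col / total`, `df = (r-1)(c-1)`. No
#' continuity correction is applied.
#'
#' @param counts Non-negative integer matrix.
#' @return A `stat_report` with `statistic`, `df`, `p_value` and the
#'   expected counts as `expected`.
#' @export
chi_squared <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0) {
    stopf("`counts` must be non-negative with a positive total")
  }
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) stopf("zero marginal in table")
  expected <- outer(rs, cs) / sum(counts)
  x2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  stat_report("chi_squared", statistic = x2, df = df,
              p_value = pchisq(x2, df, lower.tail = FALSE),
              expected = expected)
}

#' 95% confidence-interval half-width
#'
#' t-based half-width `t[0.975, n-1] * sd / sqrt(n)` with the sample SD,
#' as used for the error bars on fold accuracies (small n, so the t
#' distribution rather than the normal).
#'
#' @param values Numeric vector, length >= 2.
#' @return The half-width (scalar).
#' @export
ci95 <- function(values) {
  n <- length(values)
  if (n < 2) stopf("need >= 2 values")
  qt(0.975, n - 1) * sd(values) / sqrt(n)
}

stat_report <- function(test_name, statistic, df, p_value,
                        adjusted_p = NULL, ...) {
  rep <- list(test_name = test_name, statistic = unname(statistic),
              df = unname(df), p_value = unname(p_value))
  if (!is.null(adjusted_p)) rep$adjusted_p <- adjusted_p
  extra <- list(...)
  rep[names(extra)] <- extra
  structure(rep, class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  dfs <- paste(format(round(x$df, 2)), collapse = ", ")
  cat(sprintf("<%s: statistic = %.4f, df = %s, p = %.4g%s>\n",
              x$test_name, x$statistic, dfs, x$p_value,
              if (!is.null(x$adjusted_p)) {
                sprintf(", adjusted p = %.4g", x$adjusted_p)
              } else ""))
  invisible(x)
}
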