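#' Descriptive statistics of a proportion series
#'
#' Sample mean, sample standard deviation (n - 1 denominator), a t-based
#' 95% confidence interval for the mean, and the range — the layout used
#' for method-agreement reporting.
#'
#' @param x numeric vector, `n >= 2` for a confidence interval.
#' @param conf confidence level (default 0.95).
#' @return List of class `stat_summary`: `n`, `mean`, `sd`, `ci_lower`,
#'   `ci_upper`, `min`, `max`. With `n < 2` the CI is `NA` and the result
#'   carries `flag = "ci_undefined"`.
#' @export
describe_series <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("empty series")
  m <- mean(x)
  if (n < 2L) {
    return(structure(list(n = n, mean = m, sd = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          min = min(x), max = max(x),
                          flag = "ci_undefined"),
                     class = "stat_summary"))
  }
  s <- stats::sd(x)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  structure(list(n = n, mean = m, sd = s,
                 ci_lower = m - half, ci_upper = m + half,
                 min = min(x), max = max(x), flag = NA_character_),
            class = "stat_summary")
}

#' One-way ANOVA between two groups
#'
#' Classical between-/within-group sums-of-squares decomposition computed
#' directly; the p-value comes from the F distribution. Two identical
#' groups (zero within-group variance and equal means) give `F = 0`,
#' `p = 1`.
#'
#' @param group_a,group_b numeric vectors, each with `n >= 2`.
#' @return List with `f`, `p`, and `table` (a data frame with rows
#'   between/within/total and columns sum_sq, df, mean_sq).
#' @export
one_way_anova <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2")
  grand <- mean(c(group_a, group_b))
  ssb <- na * (mean(group_a) - grand)^2 + nb * (mean(group_b) - grand)^2
  ssw <- sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)
  df_b <- 1L
  df_w <- na + nb - 2L
  msb <- ssb / df_b
  msw <- ssw / df_w
  if (msw == 0) {
    f <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f <- msb / msw
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(f = f, p = p,
       table = data.frame(
         source = c("between", "within", "total"),
         sum_sq = c(ssb, ssw, ssb + ssw),
         df = c(df_b, df_w, df_b + df_w),
         mean_sq = c(msb, msw, NA_real_)))
}

#' Method-agreement report: Monte Carlo vs. traversal proportions
#'
#' Compares the per-slice Monte Carlo proportions against the exact
#' traversal proportions for the medullary and cortical regions:
#' descriptive statistics per series, a one-way ANOVA per region pair, the
#' per-slice absolute differences, and a pass/fail agreement verdict at
#' the chosen significance level (agreement = no significant difference in
#' either pair).
#'
#' @param alpha_mm,alpha_mt medullary proportions, Monte Carlo and
#'   traversal (equal length).
#' @param alpha_cm,alpha_ct cortical proportions, Monte Carlo and
#'   traversal.
#' @param level significance level (default 0.05).
#' @return List of class `agreement_report`: `summaries` (named
#'   `stat_summary` list), `anova_medullary`, `anova_cortical`,
#'   `max_abs_diff_medullary`, `max_abs_diff_cortical`,
#'   `mean_abs_diff_medullary`, `mean_abs_diff_cortical`, `agreement`
#'   (logical), `verdict`.
#' @export
agreement_report <- function(alpha_mm, alpha_mt, alpha_cm, alpha_ct,
                             level = 0.05) {
  lens <- c(length(alpha_mm), length(alpha_mt),
            length(alpha_cm), length(alpha_ct))
  if (length(unique(lens)) != 1L) {
    stop("series length mismatch: ", paste(lens, collapse = ", "))
  }
  rng <- range(c(alpha_mm, alpha_mt, alpha_cm, alpha_ct), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("proportions must lie in [0, 1]")

  an_m <- one_way_anova(alpha_mm, alpha_mt)
  an_c <- one_way_anova(alpha_cm, alpha_ct)
  agree <- an_m$p > level && an_c$p > level
  structure(list(
    summaries = list(alpha_mm = describe_series(alpha_mm),
                     alpha_mt = describe_series(alpha_mt),
                     alpha_cm = describe_series(alpha_cm),
                     alpha_ct = describe_series(alpha_ct)),
    anova_medullary = an_m,
    anova_cortical = an_c,
    max_abs_diff_medullary = max(abs(alpha_mm - alpha_mt)),
    max_abs_diff_cortical = max(abs(alpha_cm - alpha_ct)),
    mean_abs_diff_medullary = mean(abs(alpha_mm - alpha_mt)),
    mean_abs_diff_cortical = mean(abs(alpha_cm - alpha_ct)),
    level = level,
    agreement = agree,
    verdict = if (agree) "no significant difference"
              else "significant difference"
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Monte Carlo vs. traversal agreement\n")
  cat(sprintf("  medullary: F = %.4g, p = %.4g (max |diff| = %.3g)\n",
              x$anova_medullary$f, x$anova_medullary$p,
              x$max_abs_diff_medullary))
  cat(sprintf("  cortical:  F = %.4g, p = %.4g (max |diff| = %.3g)\n",
              x$anova_cortical$f, x$anova_cortical$p,
              x$max_abs_diff_cortical))
  cat(sprintf("  verdict at level %.2g: %s\n", x$level, x$verdict))
  invisible(x)
}
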