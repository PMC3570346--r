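#' Two-group comparison: Student's t with automatic Welch correction
#'
#' Follows the convention of deciding the t-test variant from the data: a
#' two-sided F test of variance equality at `variance_alpha` selects the
#' pooled-variance Student test when variances look equal and the Welch
#' (Satterthwaite) test otherwise. Both p values are reported alongside the
#' choice.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param variance_alpha Significance level of the variance-equality F test.
#' @param alpha,trend_alpha Thresholds for the significance and trend flags.
#'
#' @return One-row tibble: `statistic`, `df`, `p_value`, `variant`
#'   (`"student"` or `"welch"`), `p_student`, `p_welch`, `var_test_p`,
#'   `mean_a`, `mean_b`, `significant`, `trend`.
#' @export
t_test_auto <- function(a, b, variance_alpha = 0.05, alpha = 0.05,
                        trend_alpha = 0.1) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)

  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    p <- if (equal) 1 else 0
    return(tibble(
      statistic = if (equal) 0 else Inf, df = length(a) + length(b) - 2,
      p_value = p, variant = "student", p_student = p, p_welch = p,
      var_test_p = 1, mean_a = mean(a), mean_b = mean(b),
      significant = p < alpha, trend = p < trend_alpha & p >= alpha
    ))
  }

  vt <- var.test(a, b)
  welch_chosen <- vt$p.value < variance_alpha
  student <- t.test(a, b, var.equal = TRUE)
  welch <- t.test(a, b, var.equal = FALSE)
  chosen <- if (welch_chosen) welch else student
  p <- chosen$p.value
  tibble(
    statistic = unname(chosen$statistic), df = unname(chosen$parameter),
    p_value = p, variant = if (welch_chosen) "welch" else "student",
    p_student = student$p.value, p_welch = welch$p.value,
    var_test_p = vt$p.value, mean_a = mean(a), mean_b = mean(b),
    significant = p < alpha, trend = p < trend_alpha & p >= alpha
  )
}

#' One-way ANOVA with Tukey HSD post hoc tests
#'
#' Omnibus one-way ANOVA across three or more groups (e.g. control / minor
#' SE / medium SE) followed by all pairwise Tukey honestly-significant-
#' difference comparisons (Tukey–Kramer for unbalanced groups).
#'
#' @param data Tibble with the response and grouping columns.
#' @param value,group Column names (strings) of the response and the group.
#' @param alpha,trend_alpha Flag thresholds.
#'
#' @return List of class `anova_tukey`: `omnibus` (one-row tibble with
#'   `f_statistic`, `df1`, `df2`, `p_value`, flags) and `pairwise` (tibble of
#'   Tukey-adjusted comparisons: `comparison`, `diff`, `conf_low`,
#'   `conf_high`, `p_adj`, flags).
#' @export
anova_tukey <- function(data, value = "value", group = "group", alpha = 0.05,
                        trend_alpha = 0.1) {
  y <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 3) abort("need at least 3 groups for the ANOVA design")
  if (any(table(g) < 2)) abort("every group needs n >= 2")
  fit <- aov(y ~ g)
  an <- summary(fit)[[1]]
  p <- an[["Pr(>F)"]][1]
  omnibus <- tibble(
    f_statistic = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
    p_value = p, significant = p < alpha, trend = p < trend_alpha & p >= alpha
  )
  tk <- TukeyHSD(fit)$g
  padj <- unname(tk[, "p adj"])
  pairwise <- tibble(
    comparison = rownames(tk), diff = unname(tk[, "diff"]),
    conf_low = unname(tk[, "lwr"]), conf_high = unname(tk[, "upr"]),
    p_adj = padj,
    significant = padj < alpha,
    trend = padj < trend_alpha & padj >= alpha
  )
  structure(list(omnibus = omnibus, pairwise = pairwise),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("<anova_tukey>\nOmnibus one-way ANOVA:\n")
  print(x$omnibus)
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise)
  invisible(x)
}

#' Pearson correlation with two-sided p value
#'
#' `r` with the usual t transform `t = r sqrt((n-2)/(1-r^2))` on n - 2
#' degrees of freedom.
#'
#' @param x,y Paired numeric samples, n >= 3, finite, non-constant.
#' @param alpha,trend_alpha Flag thresholds.
#' @return One-row tibble: `r`, `n`, `df`, `statistic`, `p_value`,
#'   `significant`, `trend`.
#' @export
pearson_r <- function(x, y, alpha = 0.05, trend_alpha = 0.1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance in x or y; correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson")
  p <- ct$p.value
  tibble(
    r = unname(ct$estimate), n = length(x), df = unname(ct$parameter),
    statistic = unname(ct$statistic), p_value = p,
    significant = p < alpha, trend = p < trend_alpha & p >= alpha
  )
}

#' Percent difference of a treated group relative to control
#'
#' `(treated - control) / control * 100`, computed from unrounded means.
#'
#' @param control_mean Control group mean, > 0.
#' @param treated_mean Treated (e.g. KA) group mean.
#' @return Percent difference (vectorised).
#' @examples
#' percent_difference(5.3, 20.6) # 288.7
#' @export
percent_difference <- function(control_mean, treated_mean) {
  if (any(control_mean <= 0)) abort("`control_mean` must be positive")
  (treated_mean - control_mean) / control_mean * 100
}

# asterisk/section-sign notation used in the report tables
significance_flag <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ "§",
    TRUE ~ ""
  )
}
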