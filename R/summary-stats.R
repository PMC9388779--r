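#' Pooled two-sample t statistic from printed summaries
#'
#' Computes the equal-variance two-sample t statistic from group means, SDs
#' and sizes, as used when checking a demographic table against its printed
#' statistics: `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))` with pooled
#' variance `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1 (`s1 >= 0`, `n1 >= 2`).
#' @param m2,s2,n2 Likewise for group 2.
#' @return A list with `t`, `df` and `p_value` (two-tailed). A zero pooled
#'   variance with unequal means yields a signed infinite t.
#' @export
two_sample_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 < 0 || s2 < 0) stopf("SDs must be non-negative")
  if (n1 < 2 || n2 < 2) stopf("group sizes must be >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    t_stat <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  }
  list(t = t_stat, df = df, p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Yates continuity-corrected chi-squared statistic for a 2 x 2 table
#'
#' `chi^2 = sum (|O - E| - 0.5)^2 / E` over the four cells, with the
#' correction floored at zero when `|O - E| < 0.5`.
#'
#' @param table 2 x 2 matrix of non-negative counts with positive margins.
#' @return A list with `chi2`, `df = 1` and `p_value`.
#' @export
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stopf("a 2 x 2 table is required")
  if (any(table < 0)) stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("all margins must be positive")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  adj <- pmax(abs(table - E) - 0.5, 0)
  chi2 <- sum(adj^2 / E)
  list(chi2 = chi2, df = 1, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
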