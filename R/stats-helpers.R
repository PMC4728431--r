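#' Two-by-two contingency result with exact test and odds ratio
#'
#' Runs Fisher's exact test (two-sided: sum of probabilities of tables at
#' most as probable as the observed one, the standard convention implemented
#' by [stats::fisher.test()]) and reports the sample odds ratio (a*d)/(b*c),
#' with 0.5 added to every cell when any cell is zero (Haldane-Anscombe
#' correction, reporting only; the p-value uses the uncorrected table).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative "two.sided", "greater" or "less".
#' @return List with table, odds_ratio, p_value and sidedness.
#' @export
contingency_result <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  ctab <- tab
  if (any(tab == 0)) ctab <- tab + 0.5
  or <- (ctab[1, 1] * ctab[2, 2]) / (ctab[1, 2] * ctab[2, 1])
  sided <- switch(alternative, two.sided = "two_sided",
                  greater = "one_sided_greater", less = "one_sided_less")
  list(table = tab, odds_ratio = or, p_value = min(p, 1), sidedness = sided)
}
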