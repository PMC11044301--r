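#' Mann-Whitney U test for two groups
#'
#' Rank-sum comparison with tie-corrected normal approximation (exact
#' enumeration for small tie-free samples). The U statistic reported is for
#' the first group. Thin wrapper over [stats::wilcox.test()].
#'
#' @param group_a,group_b Numeric samples.
#' @param exact Use the exact distribution when both groups have <= 8
#'   observations and there are no ties.
#' @return List with `U` and two-sided `p`.
#' @export
mann_whitney <- function(group_a, group_b, exact = NULL) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  if (is.null(exact))
    exact <- length(group_a) <= 8 && length(group_b) <= 8 &&
      !anyDuplicated(c(group_a, group_b))
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise post hoc
#'
#' Tie-corrected H statistic with a chi-square p-value (df = 2) across three
#' groups, followed by pairwise Mann-Whitney comparisons flagged significant
#' at `alpha / 3` (Bonferroni). Wraps [stats::kruskal.test()].
#'
#' @param groups List of exactly 3 non-empty numeric samples (names are kept
#'   for the pairwise labels).
#' @param alpha Family-wise significance level (default 0.05; the pairwise
#'   threshold is then 0.0167).
#' @return List with `H`, `p`, `pairwise` (data.frame: comparison, p,
#'   significant) and `threshold`.
#' @export
kruskal_wallis_with_posthoc <- function(groups, alpha = 0.05) {
  if (length(groups) != 3 || any(!lengths(groups)))
    stop("exactly 3 non-empty groups required")
  if (is.null(names(groups))) names(groups) <- paste0("group", 1:3)
  kw <- kruskal.test(groups)
  thr <- alpha / 3
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    p <- mann_whitney(groups[[pr[1]]], groups[[pr[2]]])$p
    data.frame(comparison = paste(pr, collapse = " vs "), p = p,
               significant = p < thr)
  }))
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pw,
       threshold = thr)
}

#' Chi-square or Fisher's exact test for a 2 x k contingency table
#'
#' For 2 x 2 tables with any expected cell count below 5, Fisher's exact test
#' (hypergeometric enumeration); otherwise the chi-square test, with Yates
#' continuity correction for 2 x 2 tables. Wraps [stats::chisq.test()] /
#' [stats::fisher.test()].
#'
#' @param table Matrix of non-negative integer counts with 2 rows.
#' @return List with `method` (`"fisher"` or `"chisq"`), `p`, and
#'   `statistic` (chi-square only).
#' @export
#' @examples
#' categorical_tests(matrix(c(5, 0, 0, 5), 2))  # Fisher, p = 0.0079
categorical_tests <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margins: zero row or column total")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(dim(table) == 2) && any(expected < 5)) {
    ft <- fisher.test(table)
    list(method = "fisher", p = ft$p.value, statistic = NA_real_)
  } else {
    ct <- suppressWarnings(
      chisq.test(table, correct = all(dim(table) == 2)))
    list(method = "chisq", p = ct$p.value,
         statistic = unname(ct$statistic))
  }
}
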