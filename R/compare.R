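#' Non-parametric comparison of a measure between groups
#'
#' With two groups a Mann-Whitney U test (normal approximation with tie
#' correction) is used; with three or more, a Kruskal-Wallis rank test with
#' tie correction against a chi-squared reference with `k - 1` degrees of
#' freedom, optionally followed by Dunn's pairwise post hoc test with
#' Benjamini-Hochberg adjusted two-sided p-values.
#'
#' When every value is identical there is no rank variance; the statistic is
#' defined as 0 with p = 1 rather than erroring.
#'
#' @param values Numeric vector (e.g. a detection index or network density).
#' @param groups Group labels, same length as `values`; each group needs at
#'   least two observations.
#' @param posthoc Run Dunn's test after a Kruskal-Wallis test?
#' @return A `group_comparison` object: a list with `test`
#'   (`"kruskal_wallis"` or `"mann_whitney"`), `statistic`, `df` (KW only),
#'   `p_value`, and a `posthoc` tibble with columns `pair`, `z`, `p`,
#'   `p_adjusted` (empty unless applicable). Has [tidy()] and [glance()]
#'   methods.
#' @export
compare_groups <- function(values, groups, posthoc = TRUE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least two groups")
  if (any(tab < 2)) abort("every group needs at least two observations")

  empty_posthoc <- tibble(pair = character(), z = double(),
                          p = double(), p_adjusted = double())
  if (length(unique(values)) == 1) {
    res <- list(test = if (length(tab) == 2) "mann_whitney" else "kruskal_wallis",
                statistic = 0, df = length(tab) - 1L, p_value = 1,
                posthoc = empty_posthoc)
    class(res) <- "group_comparison"
    return(res)
  }

  if (length(tab) == 2) {
    lv <- names(tab)
    wt <- suppressWarnings(
      wilcox.test(values[groups == lv[1]], values[groups == lv[2]],
                  exact = FALSE, correct = FALSE)
    )
    res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                df = NA_integer_, p_value = wt$p.value,
                posthoc = empty_posthoc)
  } else {
    kw <- kruskal.test(values, factor(groups))
    ph <- if (posthoc) dunn_test(values, groups) else empty_posthoc
    res <- list(test = "kruskal_wallis", statistic = unname(kw$statistic),
                df = unname(kw$parameter), p_value = kw$p.value,
                posthoc = ph)
  }
  class(res) <- "group_comparison"
  res
}

#' Dunn's post hoc test on ranks
#'
#' Pairwise z statistics on mean ranks with tie-corrected variance,
#' two-sided p-values, and Benjamini-Hochberg adjustment across all pairs.
#' The z for pair "A - B" is positive when A has the larger mean rank.
#'
#' @inheritParams compare_groups
#' @return Tibble with columns `pair`, `z`, `p`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.character(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- sort(unique(groups))
  mean_rank <- tapply(r, groups, mean)[lv]
  n_g <- tapply(r, groups, length)[lv]
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[p[1]] + 1 / n_g[p[2]]))
    (mean_rank[p[1]] - mean_rank[p[2]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  tibble(
    pair = apply(pairs, 2, paste, collapse = " - "),
    z = unname(z),
    p = unname(p),
    p_adjusted = p.adjust(p, method = "BH")
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$test == "kruskal_wallis") {
    cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
    if (nrow(x$posthoc) > 0) {
      cat("Dunn post hoc (BH-adjusted):\n")
      print(as.data.frame(x$posthoc), row.names = FALSE)
    }
  } else {
    cat(sprintf("Mann-Whitney U = %.4g, p = %.4g\n", x$statistic, x$p_value))
  }
  invisible(x)
}
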