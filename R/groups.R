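# Group comparisons: nucleocyclic (Group 1) versus the rest.

#' Compare a parameter between Group 1 and Groups 2/3
#'
#' One-tailed Wilcoxon rank-sum test of the null hypothesis that the
#' parameter distribution is the same in the nucleocyclic group and in the
#' remaining TSSs.  The direction of the alternative is always supplied by
#' the caller (e.g. `"greater"` for expression and breadth, `"less"` for
#' cross-strain distance).  Exact when both sides are small, normal
#' approximation with tie correction otherwise (see [rank_sum_test()]).
#'
#' @param values numeric parameter per TSS.
#' @param groups integer labels (1 = nucleocyclic); `NA`s excluded.
#' @param direction `"greater"` or `"less"`: the alternative for Group 1
#'   relative to the rest.
#' @param group the focal group label (default 1).
#' @return object of class `group_comparison`: the rank-sum result plus
#'   group sizes and medians.
#' @export
compare_groups <- function(values, groups,
                           direction = c("greater", "less"), group = 1L) {
  direction <- match.arg(direction)
  ok <- !is.na(values) & !is.na(groups)
  v <- values[ok]
  g <- groups[ok]
  x <- v[g == group]
  y <- v[g != group]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 members on each side")
  }
  res <- rank_sum_test(x, y, alternative = direction)
  structure(list(p.value = res$p.value, statistic = res$statistic,
                 method = res$method, degenerate = res$degenerate,
                 direction = direction,
                 n_group = length(x), n_rest = length(y),
                 median_group = stats::median(x),
                 median_rest = stats::median(y)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group comparison (%s): n = %d vs %d, medians %.4g vs %.4g, p = %.4g (%s)\n",
    x$direction, x$n_group, x$n_rest, x$median_group, x$median_rest,
    x$p.value, x$method))
  invisible(x)
}
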