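# Per-parameter descriptive summaries and EOP-vs-LOP Mann-Whitney
# comparisons, mirroring the reference table layout (median [mean +/- SD]).

#' Per-parameter summary statistics for one group
#'
#' @param cohort A \code{\link{cohort_table}}.
#' @param group Group label to summarize.
#' @return Data frame with columns \code{parameter}, \code{median} (midpoint
#'   convention for even n), \code{mean} and \code{sd} (sample, n-1).
#' @export
group_summary <- function(cohort, group) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!group %in% cohort$group) stop("group '", group, "' not in cohort")
  v <- cohort$values[cohort$group == group, , drop = FALSE]
  data.frame(parameter = colnames(v),
             median = apply(v, 2, stats::median),
             mean = colMeans(v),
             sd = apply(v, 2, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mann-Whitney U test for two samples
#'
#' U is computed with midranks for ties.  The two-sided p-value follows
#' standard statistical-software behaviour: exact enumeration for small
#' tie-free samples, and otherwise the normal approximation with
#' tie-corrected variance and continuity correction (the regime that
#' applies at the study's sample sizes of 43 and 68).  When the pooled
#' data are constant the test is degenerate and p = 1 by convention.
#'
#' @param x,y Numeric samples, each of size >= 1.
#' @return List with elements \code{U} (the statistic for \code{x} over
#'   \code{y}; \code{U(x,y) + U(y,x) = n1*n2}) and \code{p} (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = U, p = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(U = unname(wt$statistic), p = p)
}

#' Compare two groups parameter by parameter
#'
#' One Mann-Whitney comparison per parameter; a parameter is flagged
#' significant when p < alpha, with no multiplicity adjustment (optionally
#' Benjamini-Hochberg adjusted significance via \code{fdr = TRUE}).
#'
#' @param cohort A \code{\link{cohort_table}}.
#' @param group_a,group_b Group labels to compare.
#' @param alpha Significance level (default 0.05).
#' @param fdr If \code{TRUE}, flag significance on Benjamini-Hochberg
#'   adjusted p-values instead (default off).
#' @return Data frame with per-parameter medians/means/SDs of both groups,
#'   \code{U}, \code{p} and \code{significant}.
#' @export
compare_groups <- function(cohort, group_a = "EOP", group_b = "LOP",
                           alpha = 0.05, fdr = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  for (g in c(group_a, group_b)) {
    if (!g %in% cohort$group) stop("group '", g, "' not in cohort")
  }
  va <- cohort$values[cohort$group == group_a, , drop = FALSE]
  vb <- cohort$values[cohort$group == group_b, , drop = FALSE]
  res <- lapply(colnames(va), function(cn) {
    mw <- mann_whitney_u(va[, cn], vb[, cn])
    data.frame(parameter = cn,
               median_a = stats::median(va[, cn]), mean_a = mean(va[, cn]),
               sd_a = stats::sd(va[, cn]),
               median_b = stats::median(vb[, cn]), mean_b = mean(vb[, cn]),
               sd_b = stats::sd(vb[, cn]),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p_use <- if (fdr) stats::p.adjust(out$p, "BH") else out$p
  out$significant <- p_use < alpha
  attr(out, "groups") <- c(group_a, group_b)
  attr(out, "alpha") <- alpha
  out
}
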