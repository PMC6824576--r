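# Two-step clustering: seeded k-means pre-clustering followed by
# agglomerative merging of pre-clusters under the log-likelihood distance
# d(j,s) = xi_j + xi_s - xi_<j,s>, with xi_v = -N_v * sum_k 0.5 *
# log(sigma2_k + sigma2_vk) (continuous-variable form; population,
# divide-by-N variances inside xi; the global variance term sigma2_k
# guards log(0) so no extra smoothing is needed).  Per-parameter
# predictor-importance scores of the final two clusters corroborate
# entropy-flagged anomaly candidates: parameters carrying anomalies
# separate the clusters weakly and score low.

# Sufficient statistics of one cluster: n, per-column sum and sum of
# squares; population variance derived on demand.
cluster_stats <- function(x, idx) {
  xm <- x[idx, , drop = FALSE]
  list(n = length(idx), sum = colSums(xm), sumsq = colSums(xm^2))
}

pooled_stats <- function(a, b) {
  list(n = a$n + b$n, sum = a$sum + b$sum, sumsq = a$sumsq + b$sumsq)
}

pop_var <- function(st) {
  v <- st$sumsq / st$n - (st$sum / st$n)^2
  pmax(v, 0)
}

xi_term <- function(st, global_var) {
  -st$n * sum(0.5 * log(global_var + pop_var(st)))
}

#' Log-likelihood distance between two clusters
#'
#' @param stats_j,stats_s Cluster sufficient statistics as produced
#'   internally (lists with \code{n}, \code{sum}, \code{sumsq}), or numeric
#'   matrices/vectors of the member rows themselves.
#' @param global_var Per-column global population variance (> 0).
#' @return The merge cost d(j,s) = xi_j + xi_s - xi_<j,s> (>= 0,
#'   symmetric).
#' @export
log_likelihood_distance <- function(stats_j, stats_s, global_var) {
  as_stats <- function(obj) {
    if (is.list(obj) && all(c("n", "sum", "sumsq") %in% names(obj))) return(obj)
    m <- as.matrix(obj)
    if (nrow(m) == 0) stop("empty cluster")
    list(n = nrow(m), sum = colSums(m), sumsq = colSums(m^2))
  }
  a <- as_stats(stats_j); b <- as_stats(stats_s)
  if (a$n == 0 || b$n == 0) stop("empty cluster")
  if (any(global_var <= 0)) stop("global variances must be positive")
  xi_term(a, global_var) + xi_term(b, global_var) -
    xi_term(pooled_stats(a, b), global_var)
}

#' Two-step clustering of patients
#'
#' Step 1 partitions the rows into \code{n_preclusters} seeded k-means
#' pre-clusters; step 2 agglomeratively merges the pre-cluster pair with
#' minimal log-likelihood distance until \code{k} clusters remain.
#' Cluster ids are ordered by size (1 = largest).
#'
#' @param x Numeric matrix (typically the z-scored residual-subspace
#'   columns), complete.
#' @param n_preclusters Number of k-means pre-clusters (default 20; capped
#'   at the number of distinct rows).
#' @param k Final number of clusters (default 2).
#' @param seed Integer seed for the k-means step.
#' @return Integer vector of cluster assignments (attribute
#'   \code{degenerate = TRUE} when the input had fewer distinct rows than
#'   \code{k}, in which case all rows share cluster 1).
#' @export
two_step_cluster <- function(x, n_preclusters = 20, k = 2, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k) stop("need at least k = ", k, " patients")
  if (n_preclusters < k) stop("n_preclusters must be >= k")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    assign_all <- rep(1L, n)
    attr(assign_all, "degenerate") <- TRUE
    return(assign_all)
  }
  n_preclusters <- min(n_preclusters, n_distinct)
  pre <- with_seed(seed, {
    stats::kmeans(x, centers = n_preclusters, nstart = 5,
                  iter.max = 100)$cluster
  })
  global_var <- pop_var(cluster_stats(x, seq_len(n)))
  global_var[global_var == 0] <- 1e-12   # constant columns carry no cost
  members <- split(seq_len(n), pre)
  stats_list <- lapply(members, function(idx) cluster_stats(x, idx))
  while (length(stats_list) > k) {
    m <- length(stats_list)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- xi_term(stats_list[[i]], global_var) +
          xi_term(stats_list[[j]], global_var) -
          xi_term(pooled_stats(stats_list[[i]], stats_list[[j]]), global_var)
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    stats_list[[i]] <- pooled_stats(stats_list[[i]], stats_list[[j]])
    members[[i]] <- c(members[[i]], members[[j]])
    stats_list[[j]] <- NULL
    members[[j]] <- NULL
  }
  sizes <- vapply(members, length, 0L)
  ord <- order(sizes, decreasing = TRUE)
  assignment <- integer(n)
  for (r in seq_along(ord)) assignment[members[[ord[r]]]] <- r
  attr(assignment, "degenerate") <- FALSE
  assignment
}

#' Predictor importance of a two-cluster assignment
#'
#' Per parameter, a Welch t-test between the two clusters; importance is
#' -log10(p) normalized by its maximum over parameters and clipped to
#' [0, 1].  Parameters identical across clusters get importance 0.  Low
#' importance marks parameters that contribute little to the unsupervised
#' separation -- the corroborating signature of an anomaly-carrying
#' parameter.
#'
#' @param x Numeric matrix (columns = parameters).
#' @param assignment Integer vector with exactly two non-empty clusters,
#'   each of size >= 2.
#' @return A \code{cluster_importance} data frame with columns
#'   \code{parameter}, \code{p}, \code{importance}, \code{rank} (1 =
#'   most important).
#' @export
predictor_importance <- function(x, assignment) {
  x <- as.matrix(x)
  ids <- sort(unique(assignment))
  if (length(ids) != 2) stop("assignment must have exactly 2 clusters")
  i1 <- assignment == ids[1]; i2 <- assignment == ids[2]
  if (sum(i1) < 2 || sum(i2) < 2) {
    stop("a cluster has fewer than 2 members; increase n_preclusters or ",
         "check for degenerate input")
  }
  pvals <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[i1, j]; b <- x[i2, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }, 0)
  score <- -log10(pmax(pvals, .Machine$double.xmin))
  mx <- max(score)
  importance <- if (mx > 0) pmin(pmax(score / mx, 0), 1) else rep(0, length(score))
  out <- data.frame(parameter = colnames(x), p = pvals,
                    importance = importance,
                    rank = rank(-importance, ties.method = "min"),
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_importance", "data.frame")
  out
}

#' Corroborate entropy flags with clustering importance
#'
#' The corroborated anomaly set is the intersection of the entropy-flagged
#' parameters and those with clustering importance at or below
#' \code{importance_cutoff}: two unrelated detectors agreeing on the same
#' parameter.
#'
#' @param entropy_report An \code{\link{entropy_screen}} result.
#' @param importance_report A \code{\link{predictor_importance}} result
#'   over the same parameter set.
#' @param importance_cutoff Importance at or below which a parameter
#'   counts as weakly separating (default 0.05).
#' @return Character vector of corroborated parameter names.
#' @export
anomaly_corroboration <- function(entropy_report, importance_report,
                                  importance_cutoff = 0.05) {
  ep <- entropy_report$parameter
  ip <- importance_report$parameter
  if (!length(intersect(ep, ip))) {
    stop("entropy and importance reports cover disjoint parameter sets")
  }
  flagged <- entropy_report$parameter[entropy_report$flagged]
  weak <- importance_report$parameter[
    importance_report$importance <= importance_cutoff]
  intersect(flagged, weak)
}
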