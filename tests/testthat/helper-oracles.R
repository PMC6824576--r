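# Independent oracles used across the suite.  Each is a deliberately
# plain, loop-based implementation kept separate from the package's code
# paths.

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled (tie-free) values to the first sample.
exact_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- abs(u_of(seq_len(n1)) - n1 * n2 / 2)
  splits <- utils::combn(n1 + n2, n1)
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    if (abs(u_of(splits[, j]) - n1 * n2 / 2) >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(splits)
}

# Brute-force LOF reference: nested loops over the Breunig et al.
# definitions, no shared code with immunonoise::lof().
lof_bruteforce <- function(pts, k) {
  n <- nrow(pts)
  d <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- sapply(setdiff(seq_len(n), i), function(j) d(i, j))
    names(di) <- setdiff(seq_len(n), i)
    kd <- sort(di)[k]
    kdist[i] <- kd
    nbrs[[i]] <- as.integer(names(di)[di <= kd + 0e-12])
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    total <- 0
    for (o in nbrs[[i]]) total <- total + max(kdist[o], d(i, o))
    lrd[i] <- if (total == 0) Inf else length(nbrs[[i]]) / total
  }
  sapply(seq_len(n), function(i) {
    if (!is.finite(lrd[i])) return(1)
    mean(sapply(nbrs[[i]], function(o) lrd[o] / lrd[i]))
  })
}

# Direct-formula log-likelihood merge cost from raw member rows.
ll_distance_direct <- function(a, b, global_var) {
  a <- as.matrix(a); b <- as.matrix(b)
  popv <- function(m) apply(m, 2, function(v) mean((v - mean(v))^2))
  xi <- function(m) -nrow(m) * sum(0.5 * log(global_var + popv(m)))
  xi(a) + xi(b) - xi(rbind(a, b))
}

# Small hand-built cohort for IO tests.
tiny_cohort <- function() {
  cohort_table(
    matrix(c(1.5, -0.17, 2.25, 0.4, 3.75, 1.1), nrow = 3, byrow = TRUE,
           dimnames = list(NULL, c("a", "b"))),
    c("EOP", "EOP", "LOP"), c("p1", "p2", "p3"))
}

# The canonical five anomaly parameters used in recovery experiments.
canonical_targets <- c("chemotaxis", "CD4_pct", "CD8_pct", "CD20_pct",
                       "IgG_Aa_ATCC29523")
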