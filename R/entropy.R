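# Plug-in (Shannon) sample entropy of a parameter's distinct recorded
# values, in base-10 digits: H = -sum (n_i/S) log10(n_i/S) over the
# frequency counts n_i of the S observations.  H is 0 when all
# observations coincide and attains log10(S) when all are distinct; the
# squared statistic H^2 is what anomaly screening thresholds.  This is the
# frequency-based Shannon estimator, not the Richman-Moorman time-series
# SampEn that shares the name.

#' Frequency counts of recorded values
#'
#' Rounds values half-to-even to \code{decimals} places and tabulates the
#' resulting distinct values.  Rounding to the recorded measurement
#' precision is what creates the tie structure the entropy statistic
#' measures; scale normalization cannot change distinct-value counts and
#' is therefore irrelevant here.
#'
#' @param values Non-empty numeric vector.
#' @param decimals Decimal places to round to.
#' @return Named integer vector of counts \code{n_i}; \code{sum} equals the
#'   number of observations S.
#' @export
discretize <- function(values, decimals = 2) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  r <- round(values, decimals)
  tab <- table(format(r, trim = TRUE, scientific = FALSE))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Sample entropy of frequency counts
#'
#' @param counts Non-empty vector of positive counts \code{n_i}.
#' @return H = -sum (n_i/S) log10(n_i/S); 0 for a single bin.
#' @export
sample_entropy <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 1, all(counts >= 1))
  p <- counts / sum(counts)
  -sum(p * log10(p))
}

#' Maximum attainable sample entropy for S observations
#'
#' The plug-in entropy of S observations is bounded by log10(S), attained
#' when every value is distinct; reports print both the bound and its
#' square (the "possible range" of the squared statistic).
#'
#' @param S Number of observations (>= 1).
#' @return List with \code{H_max = log10(S)} and
#'   \code{H_max_squared = log10(S)^2}, unrounded.
#' @export
max_entropy <- function(S) {
  if (!is.numeric(S) || length(S) != 1 || S < 1) stop("S must be >= 1")
  H <- log10(S)
  list(H_max = H, H_max_squared = H^2)
}

#' Entropy anomaly screen over a parameter set
#'
#' Computes per-parameter sample entropy on the pooled rows of
#' \code{cohort} (pass the discovery subset for a discovery screen, the
#' validation subset for a validation screen) and flags parameters whose
#' squared entropy meets \code{threshold}.
#'
#' @param cohort A \code{\link{cohort_table}} already subset to the rows
#'   to pool.
#' @param parameters Non-empty subset of cohort parameters to screen
#'   (typically the residual subspace).
#' @param decimals Rounding applied before counting distinct values; at or
#'   above the recorded precision this is a no-op and ties reflect the
#'   measurement grid.
#' @param threshold Flag threshold on squared entropy (default 3).
#' @return An \code{entropy_report}: data frame with columns
#'   \code{parameter}, \code{n_distinct}, \code{s}, \code{h},
#'   \code{h_squared}, \code{flagged}; attributes \code{h_max},
#'   \code{h_max_squared}, \code{threshold}.
#' @export
entropy_screen <- function(cohort, parameters, decimals = 2, threshold = 3) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!length(parameters)) stop("parameter set must be non-empty")
  miss <- setdiff(parameters, cohort$parameters)
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  S <- nrow(cohort$values)
  rows <- lapply(parameters, function(pn) {
    counts <- discretize(cohort$values[, pn], decimals)
    H <- sample_entropy(counts)
    data.frame(parameter = pn, n_distinct = length(counts), s = S,
               h = H, h_squared = H^2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$h_squared >= threshold
  me <- max_entropy(S)
  attr(out, "h_max") <- me$H_max
  attr(out, "h_max_squared") <- me$H_max_squared
  attr(out, "threshold") <- threshold
  class(out) <- c("entropy_report", "data.frame")
  out
}
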