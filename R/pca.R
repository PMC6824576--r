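# Correlation-matrix PCA of the standardized discovery matrix and the
# partition of parameters into the normal subspace (variance carriers) and
# the residual subspace searched for anomalies.  Correlation (not
# covariance) PCA is forced by the heterogeneous units of the panel
# (counts, percentages, pg/ml, ELISA units).

#' Column-standardize a matrix
#'
#' @param x Numeric matrix.
#' @return Matrix with each column centered to mean 0 and scaled to sample
#'   SD 1.  A constant column is an error naming the parameter: it carries
#'   no variance information and must be dropped by the caller.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[which(sds == 0)]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant column(s): ", paste(nm, collapse = ", "),
         "; drop before standardizing")
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Eigendecompose the parameter correlation structure
#'
#' Principal component analysis of the sample correlation matrix of
#' \code{x}.  Deterministic up to eigenvector sign, which is fixed by
#' making the largest-magnitude loading of each component positive so
#' reports are reproducible across linear-algebra backends.
#'
#' @param x Numeric matrix (rows = patients), at least 2 rows.  It is
#'   standardized internally; pre-standardized input is accepted
#'   (standardization is idempotent up to scale).
#' @return An object of class \code{subspace_decomposition}: eigenvalues
#'   (non-increasing), loadings (p x p, column j = unit eigenvector j),
#'   per-component and cumulative variance fractions.
#' @export
pca_subspace <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows for PCA")
  z <- standardize(x)
  C <- crossprod(z) / (nrow(z) - 1)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)          # clip tiny negative rounding noise
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(x)
  colnames(V) <- sprintf("PC%d", seq_len(ncol(V)))
  p <- ncol(x)
  structure(list(eigenvalues = lam, loadings = V,
                 variance_fraction = lam / p,
                 cumulative_fraction = cumsum(lam) / p,
                 parameters = colnames(x)),
            class = "subspace_decomposition")
}

#' @export
print.subspace_decomposition <- function(x, ...) {
  cat("<subspace_decomposition> ", length(x$eigenvalues), " components\n",
      sep = "")
  cat("  top eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Split parameters into normal and residual subspaces
#'
#' Components with eigenvalue above \code{eps} are retained ("eigenvalue
#' zero" on a scree plot means lambda <= eps).  Each retained component, in
#' decreasing-eigenvalue order, is assigned its dominant parameter: the
#' largest-|loading| parameter not already assigned.  The assigned
#' dominants form the normal subspace; all other parameters form the
#' residual subspace where anomalies are sought.
#'
#' @param decomp A \code{\link{pca_subspace}} result.
#' @param eps Eigenvalue threshold (>= 0), default 0.01.
#' @return List with \code{normal_parameters} (in component order),
#'   \code{residual_parameters} (in original column order),
#'   \code{n_retained} and \code{eps}.
#' @export
split_subspaces <- function(decomp, eps = 0.01) {
  stopifnot(inherits(decomp, "subspace_decomposition"), eps >= 0)
  retained <- which(decomp$eigenvalues > eps)
  if (!length(retained)) stop("all components at or below eps = ", eps)
  params <- decomp$parameters
  assigned <- character(0)
  for (j in retained) {
    load <- abs(decomp$loadings[, j])
    load[params %in% assigned] <- -Inf
    assigned <- c(assigned, params[which.max(load)])
  }
  list(normal_parameters = assigned,
       residual_parameters = params[!params %in% assigned],
       n_retained = length(retained), eps = eps)
}

#' Cumulative variance explained by the first k components
#'
#' @param decomp A \code{\link{pca_subspace}} result.
#' @param k Number of leading components, 1 <= k <= p.
#' @return Cumulative fraction sum(lambda[1:k]) / p.
#' @export
variance_explained <- function(decomp, k) {
  stopifnot(inherits(decomp, "subspace_decomposition"))
  p <- length(decomp$eigenvalues)
  if (k < 1 || k > p) stop("k must be in 1..", p)
  sum(decomp$eigenvalues[seq_len(k)]) / p
}
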