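# Local Outlier Factor scoring (Breunig et al. definitions: k-distance
# with ties included, reachability distance, local reachability density,
# LOF as the mean lrd ratio over the neighborhood) and supervised EOP/LOP
# classification by a 1-D k-nearest-neighbour vote on the aggregate LOF
# score, with stratified cross-validation.

#' Local Outlier Factor scores
#'
#' For each point: k-distance is the distance to its k-th nearest
#' neighbour; the neighbourhood contains every point within that distance
#' (ties included).  reach-dist_k(p,o) = max(k-distance(o), d(p,o));
#' lrd_k(p) is the reciprocal mean reach-dist from p to its
#' neighbourhood; LOF_k(p) is the mean of lrd(o)/lrd(p) over the
#' neighbourhood.  Euclidean distance throughout.  Scores are ~1 in
#' homogeneous regions and > 1 for local outliers.  Coincident duplicate
#' points (zero k-distance) take lrd = Inf and LOF = 1 by the standard
#' duplicates convention.
#'
#' @param points Numeric matrix, n rows (points) by d columns; n > k_lof.
#' @param k_lof Neighbourhood size (>= 1).
#' @return Numeric vector of n LOF scores.
#' @export
lof <- function(points, k_lof = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k_lof < 1) stop("k_lof must be >= 1")
  if (n <= k_lof) stop("need more points than k_lof (n = ", n,
                       ", k_lof = ", k_lof, ")")
  D <- as.matrix(stats::dist(points))
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    ks <- sort(d, partial = k_lof)[k_lof]
    kdist[i] <- ks
    nbrs[[i]] <- setdiff(which(D[i, ] <= ks), i)
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    reach <- pmax(kdist[nb], D[i, nb])
    s <- sum(reach)
    lrd[i] <- if (s == 0) Inf else length(nb) / s
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.finite(lrd[i])) { scores[i] <- 1; next }
    nb <- nbrs[[i]]
    ratio <- lrd[nb] / lrd[i]
    scores[i] <- mean(ratio)
  }
  scores
}

#' Aggregate LOF scores over a flagged parameter set
#'
#' Restricts the cohort to the discovery groups (EOP and LOP), z-scores
#' the selected columns over those rows and computes one LOF score per
#' patient in that joint feature space.
#'
#' @param cohort A \code{\link{cohort_table}}.
#' @param parameters Non-empty set of parameters (the flagged /
#'   corroborated anomaly candidates).
#' @param k_lof Neighbourhood size (default 10, a standard MinPts choice).
#' @return Data frame with \code{patient_id}, \code{group}, \code{lof};
#'   attributes \code{k_lof} and \code{feature_parameters}.
#' @export
aggregate_lof <- function(cohort, parameters, k_lof = 10) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!length(parameters)) stop("parameter set must be non-empty")
  miss <- setdiff(parameters, cohort$parameters)
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  disc <- subset_by_group(cohort, c("EOP", "LOP"))
  z <- standardize(disc$values[, parameters, drop = FALSE])
  scores <- lof(z, k_lof)
  out <- data.frame(patient_id = rownames(disc$values),
                    group = as.character(disc$group),
                    lof = scores, stringsAsFactors = FALSE)
  attr(out, "k_lof") <- k_lof
  attr(out, "feature_parameters") <- parameters
  out
}

# Majority vote among the k nearest training scores (1-D Euclidean);
# distance ties resolved by training order, label ties by the single
# nearest neighbour.
knn_predict_1d <- function(train_x, train_y, test_x, k) {
  k <- min(k, length(train_x))
  vapply(test_x, function(x0) {
    ord <- order(abs(train_x - x0), seq_along(train_x))
    top <- train_y[ord[seq_len(k)]]
    tab <- table(top)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) winners else as.character(train_y[ord[1]])
  }, "")
}

stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold_of <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_of
  })
}

confusion_metrics <- function(truth, pred, positive, negative) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth == negative & pred == negative)
  fp <- sum(truth == negative & pred != negative)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' k-NN classification of LOF scores with stratified cross-validation
#'
#' Classifies patients from their scalar aggregate-LOF score by majority
#' vote among the \code{k_nn} nearest training scores.  Apparent metrics
#' come from predicting the training data with itself (self included, the
#' usual resubstitution convention); cross-validated metrics from seeded
#' stratified k-fold CV where neighbours come only from the training part.
#' EOP is the positive class: sensitivity is the EOP true-positive rate,
#' specificity the LOP true-negative rate.
#'
#' @param scores Numeric vector of per-patient scores.
#' @param labels Group label per patient; exactly two classes.
#' @param k_nn Odd neighbourhood size (default 5).
#' @param folds Number of CV folds (default 10); must not exceed the
#'   smaller class size.
#' @param seed Integer seed for fold construction.
#' @param positive Positive class (default \code{"EOP"}).
#' @return A \code{classification_report} list: \code{apparent} and
#'   \code{cv} confusion counts + sensitivity/specificity, \code{k_nn},
#'   \code{folds}, \code{seed}.
#' @export
knn_classify_cv <- function(scores, labels, k_nn = 5, folds = 10, seed = 1L,
                            positive = "EOP") {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  classes <- unique(labels)
  if (length(classes) != 2) stop("labels must contain exactly two classes")
  if (!positive %in% classes) stop("positive class '", positive, "' absent")
  negative <- setdiff(classes, positive)
  if (k_nn %% 2 == 0) stop("k_nn must be odd")
  min_class <- min(table(labels))
  if (folds > min_class) {
    stop("folds (", folds, ") exceeds the smallest class size (", min_class,
         "); use folds <= ", min_class)
  }
  apparent_pred <- knn_predict_1d(scores, labels, scores, k_nn)
  fold_of <- stratified_folds(labels, folds, seed)
  cv_pred <- character(length(scores))
  for (fd in seq_len(folds)) {
    test <- fold_of == fd
    if (length(unique(labels[!test])) < 2) {
      stop("a training fold lost a class; use fewer folds")
    }
    cv_pred[test] <- knn_predict_1d(scores[!test], labels[!test],
                                    scores[test], k_nn)
  }
  structure(list(apparent = confusion_metrics(labels, apparent_pred,
                                              positive, negative),
                 cv = confusion_metrics(labels, cv_pred, positive, negative),
                 k_nn = k_nn, folds = folds, seed = seed,
                 positive = positive),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> k_nn =", x$k_nn, ", folds =", x$folds, "\n")
  cat(sprintf("  apparent: sens %.3f spec %.3f\n",
              x$apparent$sensitivity, x$apparent$specificity))
  cat(sprintf("  cv:       sens %.3f spec %.3f\n",
              x$cv$sensitivity, x$cv$specificity))
  invisible(x)
}

#' Choose the k-NN neighbourhood size by cross-validation
#'
#' Evaluates each candidate k by stratified CV balanced accuracy
#' ((sensitivity + specificity) / 2) on the same seeded folds and returns
#' the maximizer; ties go to the smallest k.
#'
#' @inheritParams knn_classify_cv
#' @param candidate_ks Odd candidate values (default 1, 3, ..., 15).
#' @return The selected k.
#' @export
select_k <- function(scores, labels, candidate_ks = seq(1, 15, by = 2),
                     folds = 10, seed = 1L, positive = "EOP") {
  acc <- vapply(candidate_ks, function(k) {
    rep <- knn_classify_cv(scores, labels, k_nn = k, folds = folds,
                           seed = seed, positive = positive)
    (rep$cv$sensitivity + rep$cv$specificity) / 2
  }, 0)
  candidate_ks[which.max(acc)]   # which.max takes the first (smallest) tie
}
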