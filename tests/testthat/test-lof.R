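test_that("LOF is ~1 on a homogeneous grid and maximal for a displaced point", {
  grid <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  scores <- lof(grid, k_lof = 8)
  interior <- grid[, 1] %in% 4:7 & grid[, 2] %in% 4:7
  expect_true(all(scores[interior] >= 0.9 & scores[interior] <= 1.1))
  set.seed(111)
  pts <- rbind(matrix(rnorm(60, sd = 0.5), 30, 2), c(10, 10))
  s <- lof(pts, k_lof = 5)
  expect_equal(which.max(s), 31)
  expect_gt(s[31], 1)
})

test_that("LOF equals the brute-force reference on random instances", {
  set.seed(112)
  for (i in 1:12) {
    n <- sample(20:60, 1); d <- sample(1:6, 1)
    k <- sample(c(3, 5, 10), 1)
    pts <- matrix(rnorm(n * d), n, d)
    expect_equal(lof(pts, k), lof_bruteforce(pts, k), tolerance = 1e-9)
  }
})

test_that("LOF is invariant to rotation and translation", {
  set.seed(113)
  pts <- matrix(rnorm(80), 40, 2)
  base <- lof(pts, 5)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(lof(pts %*% R, 5), base, tolerance = 1e-9)
  expect_equal(lof(pts + 3.5, 5), base, tolerance = 1e-9)
})

test_that("coincident duplicates score 1 by convention", {
  pts <- rbind(matrix(0, 6, 2), matrix(rnorm(20, 4), 10, 2))
  s <- lof(pts, k_lof = 4)
  expect_equal(s[1:6], rep(1, 6))
})

test_that("lof guards its neighbourhood-size preconditions", {
  pts <- matrix(rnorm(20), 10, 2)
  expect_error(lof(pts, 10), "more points than")
  expect_error(lof(pts, 0), "k_lof")
})

test_that("aggregate_lof scores discovery patients in the flagged space", {
  coh <- generate_cohort(default_table2_config(structure = "collinear",
                                               seed = 8))
  sc <- aggregate_lof(coh, canonical_targets, k_lof = 10)
  expect_equal(nrow(sc), 111)
  expect_setequal(unique(sc$group), c("EOP", "LOP"))
  expect_true(all(is.finite(sc$lof)))
  expect_error(aggregate_lof(coh, character(0)), "non-empty")
  flat <- coh
  flat$values[, "CD8_pct"] <- 1
  expect_error(aggregate_lof(flat, "CD8_pct"), "constant")
})

test_that("knn classification is perfect on separated scores", {
  scores <- c(rnorm(30, 5, 0.1), rnorm(20, 0, 0.1))
  labels <- rep(c("EOP", "LOP"), c(30, 20))
  rep_ <- knn_classify_cv(scores, labels, k_nn = 5, folds = 10, seed = 1)
  expect_equal(rep_$apparent$sensitivity, 1)
  expect_equal(rep_$apparent$specificity, 1)
  expect_equal(rep_$cv$sensitivity, 1)
  expect_equal(rep_$cv$specificity, 1)
  # metrics always recompute from the stored confusion counts
  for (m in list(rep_$apparent, rep_$cv)) {
    expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
    expect_equal(m$specificity, m$tn / (m$tn + m$fp))
    expect_equal(m$tp + m$fp + m$tn + m$fn, 50)
  }
})

test_that("classifier preconditions are enforced", {
  scores <- rnorm(20)
  labels <- rep(c("EOP", "LOP"), 10)
  expect_error(knn_classify_cv(scores, labels, k_nn = 4), "odd")
  expect_error(knn_classify_cv(scores, labels, folds = 11), "smallest class")
  expect_error(knn_classify_cv(scores, rep("EOP", 20)), "two classes")
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  set.seed(115)
  accs <- vapply(1:20, function(s) {
    scores <- rnorm(111)
    labels <- sample(rep(c("EOP", "LOP"), c(68, 43)))
    rep_ <- knn_classify_cv(scores, labels, k_nn = 5, folds = 10, seed = s)
    (rep_$cv$sensitivity + rep_$cv$specificity) / 2
  }, 0)
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("select_k is deterministic and ties resolve to the smallest k", {
  scores <- c(rnorm(30, 5, 0.1), rnorm(20, 0, 0.1))
  labels <- rep(c("EOP", "LOP"), c(30, 20))
  expect_equal(select_k(scores, labels, folds = 10, seed = 2), 1)
  noisy <- c(rnorm(60, 1), rnorm(51, 0))
  lab2 <- rep(c("EOP", "LOP"), c(60, 51))
  expect_identical(select_k(noisy, lab2, folds = 10, seed = 3),
                   select_k(noisy, lab2, folds = 10, seed = 3))
})
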