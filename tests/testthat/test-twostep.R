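test_that("log-likelihood distance matches the worked 1-D example", {
  A <- matrix(c(0, 1)); B <- matrix(c(10, 11))
  gv <- mean((c(0, 1, 10, 11) - 5.5)^2)
  expect_equal(gv, 25.25)
  # 2 * log(50.5 / 25.5) by direct evaluation
  expect_equal(log_likelihood_distance(A, B, gv), 1.36659, tolerance = 1e-4)
  expect_equal(log_likelihood_distance(A, B, gv),
               ll_distance_direct(A, B, gv), tolerance = 1e-12)
})

test_that("merge cost is symmetric, non-negative and oracle-consistent", {
  set.seed(101)
  for (i in 1:30) {
    d <- sample(1:3, 1)
    x <- matrix(rnorm(30 * d, sd = runif(1, 0.5, 3)), 30, d)
    gv <- apply(x, 2, function(v) mean((v - mean(v))^2))
    idx <- sample(30)
    a <- x[idx[1:sample(2:10, 1)], , drop = FALSE]
    b <- x[idx[11:(10 + sample(2:10, 1))], , drop = FALSE]
    dj <- log_likelihood_distance(a, b, gv)
    expect_equal(dj, log_likelihood_distance(b, a, gv))
    expect_gte(dj, -1e-9)
    expect_equal(dj, ll_distance_direct(a, b, gv), tolerance = 1e-9)
  }
  # merging two identical singletons costs nothing
  s <- matrix(2.5)
  expect_equal(log_likelihood_distance(s, s, 4), 0, tolerance = 1e-12)
  expect_error(log_likelihood_distance(matrix(numeric(0), 0, 1), s, 4),
               "empty cluster")
})

test_that("two-step clustering recovers well-separated blobs and is seeded", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 10), 50, 2))
    a <- two_step_cluster(x, n_preclusters = 20, k = 2, seed = s)
    truth <- rep(1:2, each = 50)
    max(mean(a == truth), mean(a == 3 - truth)) == 1
  }, NA)
  expect_equal(sum(hits), 20)
  set.seed(2000)
  x <- matrix(rnorm(200), 100, 2)
  expect_identical(two_step_cluster(x, seed = 9), two_step_cluster(x, seed = 9))
})

test_that("identical points yield a flagged degenerate single cluster", {
  x <- matrix(1, 40, 3)
  a <- two_step_cluster(x, k = 2, seed = 1)
  expect_true(attr(a, "degenerate"))
  expect_equal(unique(as.integer(a)), 1L)
})

test_that("clustering is invariant to parameter order", {
  disc <- subset_by_group(
    generate_cohort(default_table2_config(structure = "collinear", seed = 6)),
    c("EOP", "LOP"))
  z <- standardize(disc$values)
  a1 <- two_step_cluster(z, seed = 3)
  a2 <- two_step_cluster(z[, rev(seq_len(ncol(z)))], seed = 3)
  expect_gte(max(mean(a1 == a2), mean(a1 == 3 - a2)), 0.95)
})

test_that("predictor importance normalizes to [0,1] with sensible extremes", {
  set.seed(103)
  sep <- c(rnorm(30, -3), rnorm(30, 3))
  x <- cbind(signal = sep, noise = rnorm(60), const = 0)
  asg <- rep(1:2, each = 30)
  imp <- predictor_importance(x, asg)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
  expect_equal(imp$importance[imp$parameter == "signal"], 1)
  expect_equal(imp$importance[imp$parameter == "const"], 0)
  expect_lt(imp$importance[imp$parameter == "noise"], 0.2)
  expect_error(predictor_importance(x, rep(1, 60)), "exactly 2")
  expect_error(predictor_importance(x, c(2, rep(1, 59))), "fewer than 2")
})

test_that("contaminated parameters sink to the bottom of the importance ranks", {
  wins <- vapply(1:20, function(s) {
    clean <- generate_cohort(default_table2_config(structure = "collinear",
                                                   seed = s))
    disc_clean <- subset_by_group(clean, c("EOP", "LOP"))
    sp <- split_subspaces(pca_subspace(disc_clean$values), 0.01)
    resid <- sp$residual_parameters
    targets <- utils::head(c(intersect(canonical_targets, resid),
                             setdiff(resid, canonical_targets)), 5)
    coh <- inject_contamination(
      clean, contamination_spec(targets, prop = 0.3, displacement = 3,
                                target_groups = "EOP"), seed = s + 1000)
    disc <- subset_by_group(coh, c("EOP", "LOP"))
    z <- standardize(disc$values[, resid, drop = FALSE])
    imp <- predictor_importance(z, two_step_cluster(z, 20, 2, seed = s))
    bottom6 <- imp$parameter[order(imp$importance)][1:6]
    sum(targets %in% bottom6) >= 4
  }, NA)
  expect_gte(sum(wins), 15)
})

test_that("corroboration intersects entropy flags with weak separators", {
  er <- data.frame(parameter = c("a", "b", "c"),
                   flagged = c(TRUE, TRUE, FALSE))
  ir <- data.frame(parameter = c("a", "b", "c"),
                   importance = c(0.02, 0.80, 0.01))
  expect_identical(anomaly_corroboration(er, ir, 0.05), "a")
  er$flagged <- FALSE
  expect_length(anomaly_corroboration(er, ir, 0.05), 0)
  ir2 <- data.frame(parameter = c("x", "y"), importance = c(0, 0))
  expect_error(anomaly_corroboration(er, ir2), "disjoint")
})
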