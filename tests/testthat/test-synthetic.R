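test_that("identical configuration produces bitwise-identical cohorts", {
  cfg <- default_table2_config(seed = 11)
  expect_identical(generate_cohort(cfg)$values, generate_cohort(cfg)$values)
  cc <- default_table2_config(structure = "collinear", seed = 11)
  expect_identical(generate_cohort(cc)$values, generate_cohort(cc)$values)
  expect_false(identical(generate_cohort(cfg)$values,
                         generate_cohort(default_table2_config(seed = 12))$values))
})

test_that("the packaged configuration encodes the full reference panel", {
  cfg <- default_table2_config()
  expect_length(cfg$specs, 28)
  expect_equal(unname(cfg$group_sizes[c("EOP", "LOP", "VALIDATION")]),
               c(68, 43, 51))
  # spot-check a handful of hand-frozen reference cells
  expect_equal(cfg$specs$IL1$groups$EOP, c(436.72, 897.76))
  expect_equal(cfg$specs$IL2$groups$LOP, c(118.40, 104.59))
  expect_equal(cfg$specs$chemotaxis$groups$VALIDATION, c(40.17, 15.65))
  expect_equal(cfg$specs$IgG_Pi_ATCC25611$groups$LOP, c(-0.27, 0.18))
  # strongly dispersed cytokines are right-skewed, tight percentages normal
  expect_identical(cfg$specs$IL1$family, "lognormal_shifted")
  expect_identical(cfg$specs$IL6$family, "lognormal_shifted")
  expect_identical(cfg$specs$CD8_pct$family, "normal")
  expect_identical(cfg$specs$chemotaxis$family, "normal")
  # negative-support titers get a shift below every group mean
  expect_lt(cfg$specs$IgG_Pi_ATCC25611$shift, -0.27)
})

test_that("parameter and contamination specs validate their invariants", {
  expect_error(parameter_spec("x", "normal", list(EOP = c(1, 0))), "SD")
  expect_error(parameter_spec("x", "lognormal_shifted",
                              list(EOP = c(1, 1)), shift = 2), "shift")
  expect_error(parameter_spec("x", "normal", list(EOP = c(1, 1)),
                              decimals = 9), "decimals")
  expect_error(contamination_spec("a", prop = 0), "prop")
  expect_error(contamination_spec("a", prop = 1.2), "prop")
  expect_error(generator_config(list(parameter_spec(
    "a", "normal", list(EOP = c(0, 1)))), group_sizes = c(EOP = 0)),
    "positive")
})

test_that("a degenerate scale collapses to a constant column with zero entropy", {
  sp <- list(parameter_spec("flat", "normal", list(EOP = c(5, 1e-9)),
                            decimals = 2))
  cfg <- generator_config(sp, group_sizes = c(EOP = 50), seed = 4)
  coh <- generate_cohort(cfg)
  expect_equal(unique(coh$values[, "flat"]), 5)
  expect_equal(sample_entropy(discretize(coh$values[, "flat"], 2)), 0)
})

test_that("contamination perturbs only targeted cells and inflates variance", {
  coh <- generate_cohort(default_table2_config(seed = 21))
  spec <- contamination_spec("CD8_pct", prop = 0.3, displacement = 3,
                             mode = "bimodal", target_groups = "EOP")
  out <- inject_contamination(coh, spec, seed = 22)
  untouched <- setdiff(coh$parameters, "CD8_pct")
  expect_identical(out$values[, untouched], coh$values[, untouched])
  lop <- coh$group == "LOP"
  expect_identical(out$values[lop, "CD8_pct"], coh$values[lop, "CD8_pct"])
  eop <- coh$group == "EOP"
  expect_gt(var(out$values[eop, "CD8_pct"]), var(coh$values[eop, "CD8_pct"]))
  # near-zero mixture weight: output equals input with high probability
  tiny <- contamination_spec("CD8_pct", prop = 1e-9, displacement = 3)
  expect_identical(inject_contamination(coh, tiny, seed = 1)$values,
                   coh$values)
  expect_error(inject_contamination(coh, contamination_spec("nope"), 1),
               "not in cohort")
})

test_that("contaminated squared entropy exceeds the clean value across seeds", {
  # coarse integer-recorded column; 20 seeded replicates
  wins <- vapply(1:20, function(s) {
    disc <- subset_by_group(generate_cohort(default_table2_config(seed = s)),
                            c("EOP", "LOP"))
    cont <- inject_contamination(
      disc, contamination_spec("chemotaxis", prop = 0.3, displacement = 3,
                               target_groups = "EOP"), seed = s + 500)
    entropy_screen(cont, "chemotaxis")$h_squared >
      entropy_screen(disc, "chemotaxis")$h_squared
  }, NA)
  expect_gte(sum(wins), 18)
})

test_that("heavy-tail contamination inflates variance too", {
  coh <- generate_cohort(default_table2_config(seed = 31))
  spec <- contamination_spec("CD4_pct", prop = 0.3, displacement = 3,
                             mode = "heavy_tail", target_groups = "EOP")
  out <- inject_contamination(coh, spec, seed = 32)
  eop <- coh$group == "EOP"
  expect_gt(var(out$values[eop, "CD4_pct"]), var(coh$values[eop, "CD4_pct"]))
})
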