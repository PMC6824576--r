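test_that("cohort_table validates ids, labels and completeness", {
  m <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_s3_class(cohort_table(m, c("EOP", "EOP", "LOP")), "cohort_table")
  expect_error(cohort_table(m, c("EOP", "EOP", "LOP"), c("p", "p", "q")),
               "duplicate patient ids")
  expect_error(cohort_table(m, c("EOP", "EOP", "XXX")), "unknown group")
  expect_error(cohort_table(m, c("EOP", "EOP")), "labels")
  m[2, 1] <- NA
  expect_error(cohort_table(m, c("EOP", "EOP", "LOP")), "missing value")
})

test_that("csv and tsv round-trips preserve values, ids, labels and order", {
  coh <- tiny_cohort()
  for (fmt in c("csv", "tsv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(coh, path)
    back <- read_cohort(path)
    expect_equal(back$values, coh$values, tolerance = 1e-12)
    expect_identical(rownames(back$values), rownames(coh$values))
    expect_identical(as.character(back$group), as.character(coh$group))
    expect_identical(colnames(back$values), colnames(coh$values))
    unlink(path)
  }
})

test_that("negative titers and many-digit values survive a round-trip", {
  vals <- matrix(c(-0.17, 1.23456789012, -5e-4, 897.76), 2, 2,
                 dimnames = list(NULL, c("IgG_Pi_ATCC25611", "IL1")))
  coh <- cohort_table(vals, c("LOP", "EOP"))
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$values, coh$values, tolerance = 1e-12)
  expect_true(back$values[1, 1] < 0)
  unlink(path)
})

test_that("read_cohort rejects malformed files with named locations", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,a,b,group", "p1,1,2,EOP", "p2,x,4,LOP"), path)
  expect_error(read_cohort(path), "non-numeric value 'x' in column 'a'")
  writeLines(c("patient_id,a,b,group", "p1,1,2,EOP", "p2,,4,LOP"), path)
  expect_error(read_cohort(path), "missing value in column 'a'")
  writeLines(c("patient_id,a,b,group", "p1,1,2,EOP", "p1,3,4,LOP"), path)
  expect_error(read_cohort(path), "duplicate patient ids")
  writeLines(c("patient_id,a,b,group", "p1,1,2,CONTROL"), path)
  expect_error(read_cohort(path), "unknown group")
  writeLines(c("patient_id,a,b,grp", "p1,1,2,EOP"), path)
  expect_error(read_cohort(path), "label column")
  unlink(path)
  expect_error(read_cohort(tempfile(fileext = ".csv")), "not found")
})

test_that("rename maps display names onto canonical parameter names", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,Neutrophil chemotaxis,group",
               "p1,52.6,LOP", "p2,42.1,EOP"), path)
  coh <- read_cohort(path, rename = display_name_map())
  expect_identical(coh$parameters, "chemotaxis")
  unlink(path)
})

test_that("subset_by_group filters rows, keeps parameters, guards emptiness", {
  coh <- generate_cohort(default_table2_config(seed = 3))
  disc <- subset_by_group(coh, c("EOP", "LOP"))
  expect_equal(n_patients(disc), 111)
  expect_identical(disc$parameters, coh$parameters)
  val <- subset_by_group(coh, "VALIDATION")
  expect_equal(n_patients(val), 51)
  all3 <- subset_by_group(coh, c("EOP", "LOP", "VALIDATION"))
  expect_identical(all3$values, coh$values)
  expect_error(subset_by_group(coh, character(0)), "non-empty")
  eop_only <- subset_by_group(coh, "EOP")
  expect_error(subset_by_group(eop_only, "LOP"), "no patients")
})
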