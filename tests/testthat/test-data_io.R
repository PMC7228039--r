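test_that("reading a delimited battery parses ids, labels and parameters", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,model,burrowing",
               "R01,naive,kindling,120.5",
               "R02,sham,kindling,NA",
               "R03,treated,kindling,80"), f)
  tab <- read_parameter_table(f)
  expect_s3_class(tab, "parameter_table")
  expect_equal(dim(tab), c(3L, 1L))
  expect_equal(tab$animal_id, c("R01", "R02", "R03"))
  # "NA" token becomes a missing value, the row is retained
  expect_true(is.na(tab$values["R02", "burrowing"]))
  expect_equal(tab$values["R03", "burrowing"], 80)
  expect_equal(tab$parse_report$n_coerced, 0L)
})

test_that("non-numeric cells become missing and are counted in the parse report", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,model,p1,p2",
               "R01,naive,m1,not_a_number,1",
               "R02,naive,m1,2,3"), f)
  tab <- read_parameter_table(f)
  expect_true(is.na(tab$values["R01", "p1"]))
  expect_equal(tab$parse_report$n_coerced, 1L)
  expect_equal(tab$parse_report$cells$p1, 1L)
})

test_that("validation rejects duplicate ids and missing mandatory columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,model,p1",
               "R01,naive,m1,1",
               "R01,sham,m1,2"), f)
  expect_error(read_parameter_table(f), "duplicate animal_id.*R01")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,p1", "R01,naive,1", "R02,naive,2"), g)
  expect_error(read_parameter_table(g), "mandatory column 'model'")

  expect_error(parameter_table(matrix(1:4, 2, dimnames = list(NULL, c("a", "b"))),
                               c("x", "y"), c("naive", NA), c("m", "m")),
               "non-missing group")
})

test_that("missingness filter removes strictly above the threshold only", {
  vals <- cbind(p_removed = c(rep(NA, 3), rnorm(7)),   # 30% missing
                p_boundary = c(rep(NA, 2), rnorm(8)),  # exactly 20%
                p_full = rnorm(10))
  tab <- make_table(vals)
  res <- filter_by_missingness(tab, 0.20)
  expect_equal(res$report$removed_by_missingness, "p_removed")
  expect_equal(colnames(res$table$values), c("p_boundary", "p_full"))
  expect_equal(res$report$retained, c("p_boundary", "p_full"))
  # animals are never removed at this stage
  expect_equal(nrow(res$table$values), 10L)
})

test_that("filter matches hand enumeration on a 10-parameter fixture", {
  # 10 animals; parameters 2, 5, 7, 10 are given 3-5 missing cells (> 20%),
  # the rest at most 2 (<= 20%)
  n_missing <- c(0, 3, 1, 2, 4, 0, 5, 2, 1, 3)
  set.seed(42)
  vals <- sapply(n_missing, function(m) {
    v <- rnorm(10)
    if (m > 0) v[sample.int(10, m)] <- NA
    v
  })
  colnames(vals) <- sprintf("p%02d", 1:10)
  tab <- make_table(vals)
  res <- filter_by_missingness(tab, 0.20)
  expect_equal(res$report$removed_by_missingness,
               sprintf("p%02d", which(n_missing > 2)))
  expect_equal(res$report$retained, sprintf("p%02d", which(n_missing <= 2)))
  expect_length(res$report$retained, 6L)
  expect_error(filter_by_missingness(tab, -0.1), "must be in")
})

test_that("manual exclusions drop declared columns and warn on absent ones", {
  vals <- matrix(rnorm(30), 10, dimnames = list(NULL, c("a", "b", "c")))
  tab <- make_table(vals)
  specs <- parameter_spec(c("a", "b", "c"), excluded = c(FALSE, TRUE, FALSE))
  res <- apply_exclusions(tab, specs)
  expect_equal(colnames(res$table$values), c("a", "c"))
  expect_equal(res$report$removed_by_exclusion, "b")

  # empty exclusion list leaves the table unchanged
  none <- parameter_spec(c("a", "b", "c"), excluded = FALSE)
  res2 <- apply_exclusions(tab, none)
  expect_identical(res2$table$values, tab$values)

  # exclusion of an absent (already-removed) column: warning, not error
  ghost <- parameter_spec(c("a", "b", "c", "gone"),
                          excluded = c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(res3 <- apply_exclusions(tab, ghost), "not present")
  expect_identical(res3$table$values, tab$values)
})

test_that("two-stage funnel: 15 retained parameters minus 2 exclusions leaves 13", {
  set.seed(7)
  vals <- matrix(rnorm(20 * 16), 20)
  colnames(vals) <- c(sprintf("p%02d", 1:13), "body_weight_change",
                      "seizure_frequency", "sparse")
  vals[1:10, "sparse"] <- NA   # 50% missing -> removed by the filter
  tab <- make_table(vals)
  specs <- parameter_spec(colnames(vals),
                          excluded = colnames(vals) %in%
                            c("body_weight_change", "seizure_frequency"))
  res <- filter_parameters(tab, specs)
  expect_length(res$report$retained, 13L)
  expect_equal(res$report$removed_by_missingness, "sparse")
  expect_setequal(res$report$removed_by_exclusion,
                  c("body_weight_change", "seizure_frequency"))
  expect_equal(res$report$n_input_parameters, 16L)
})

test_that("filtering is idempotent and the report partitions the input", {
  set.seed(99)
  for (rep in 1:20) {
    vals <- matrix(rnorm(12 * 8), 12)
    colnames(vals) <- sprintf("p%d", 1:8)
    mask <- matrix(runif(12 * 8) < runif(1, 0, 0.4), 12)
    vals[mask] <- NA
    # keep at least one fully observed column so the filter cannot empty
    vals[, 1] <- rnorm(12)
    tab <- make_table(vals)
    res <- filter_by_missingness(tab, 0.20)
    # partition property: disjoint sets covering the input
    parts <- c(res$report$retained, res$report$removed_by_missingness,
               res$report$removed_by_exclusion)
    expect_setequal(parts, colnames(vals))
    expect_equal(anyDuplicated(parts), 0L)
    # idempotence
    res2 <- filter_by_missingness(res$table, 0.20)
    expect_identical(res2$table$values, res$table$values)
    # input column order preserved among retained parameters
    expect_equal(res$report$retained,
                 intersect(colnames(vals), res$report$retained))
  }
})

test_that("parameter specs round-trip through YAML", {
  spec <- parameter_spec(c("burrowing", "of_immobility"),
                         direction = c(1, -1), excluded = c(FALSE, TRUE),
                         note = c("g displaced", "phenotype measure"))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_spec(spec, f)
  back <- read_parameter_spec(f)
  expect_equal(as.data.frame(back), as.data.frame(spec))
  expect_error(parameter_spec("x", direction = 0), "exactly \\+1 or -1")
})

test_that("table and report writers round-trip", {
  set.seed(3)
  vals <- matrix(rnorm(20), 10, dimnames = list(NULL, c("a", "b")))
  vals[2, 1] <- NA
  tab <- make_table(vals)
  f <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(tab, f)
  back <- read_parameter_table(f)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_equal(back$group, tab$group)

  rep_path <- withr::local_tempfile(fileext = ".json")
  res <- filter_by_missingness(tab, 0.2)
  write_filter_report(res$report, rep_path)
  parsed <- jsonlite::read_json(rep_path, simplifyVector = TRUE)
  expect_equal(parsed$retained, res$report$retained)
})
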