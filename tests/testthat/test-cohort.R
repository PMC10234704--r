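test_that("cohort CSV round-trip is field-identical, including missing cells", {
  cohort <- random_records(20, seed = 101)
  cohort$hypotension[3] <- NA
  cohort$impression[5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  for (field in names(patient_fields())) {
    expect_equal(as.vector(back[[field]]), as.vector(cohort[[field]]),
                 info = field, tolerance = 1e-12)
  }
  expect_true(is.na(back$hypotension[3]))
  expect_true(is.na(back$impression[5]))
})

test_that("read_cohort enforces the schema and parses flexible boolean tokens", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age", "a,50"), path)
  expect_error(read_cohort(path), "required column 'arm'")

  cohort <- random_records(3, seed = 7)
  cohort$arm <- factor(c("case", "control", "control"), levels = c("case", "control"))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, p2)
  txt <- readLines(p2)
  txt[2] <- sub("^x00001,case", "x00001,CASE", txt[2])
  txt[2] <- sub("true", "YES", txt[2])
  txt[3] <- sub("false", "No", txt[3])
  writeLines(txt, p2)
  expect_s3_class(read_cohort(p2), "aas_cohort")

  txt[2] <- sub("^x00001,CASE", "x00001,banana", txt[2])
  writeLines(txt, p2)
  expect_error(read_cohort(p2), "unparseable arm.*banana")

  # unknown columns are dropped with a warning, not an error
  cohort2 <- random_records(2, seed = 8)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cbind(cohort2, scratch_note = c("a", "b")), p3)
  expect_warning(read_cohort(p3), "unknown column")
})

test_that("missing-data policy defaults booleans to negative and impression to unsure", {
  cohort <- bind_records(record(), record(arm = "control"))
  cohort$hypotension[1] <- NA
  cohort$impression[2] <- NA
  out <- apply_missing_policy(cohort, quiet = TRUE)
  expect_false(out$hypotension[1])
  expect_equal(as.character(out$impression[2]), "unsure")
  expect_equal(attr(out, "imputation_log"), c(hypotension = 1L, impression = 1L))

  # the unsure default leaves the total unchanged vs leaving the category unscored
  scored <- score_ripp(out)
  no_imp <- scored$total[2] -
    c(alternative_likely = -1L, unsure = 0L, aas_most_likely = 2L)[["unsure"]]
  expect_equal(scored$total[2], no_imp)

  # idempotent, and identity on complete records (imputation log aside)
  strip <- function(x) {
    attr(x, "imputation_log") <- NULL
    tibble::as_tibble(x)
  }
  expect_equal(strip(apply_missing_policy(out, quiet = TRUE)), strip(out))
})

test_that("exclusion rules follow the printed boundaries and first-match tallying", {
  cohort <- bind_records(
    record(id = "minor", age = 17),
    record(id = "dur14", pain_duration_days = 14),   # strictly >14 excludes
    record(id = "dur15", pain_duration_days = 15),
    record(id = "trauma", recent_trauma_24h = TRUE),
    record(id = "both", age = 16, recent_trauma_24h = TRUE),  # counted once, first rule
    record(id = "ok", age = 70, pain_duration_days = 2)
  )
  res <- apply_exclusions(cohort)
  expect_setequal(res$cohort$id, c("dur14", "ok"))
  expect_equal(unname(res$tally),
               c(2L, 1L, 1L, 0L))
  expect_equal(names(res$tally),
               c("under_18", "pain_duration_gt_14d", "trauma_within_24h", "chart_ineligible"))

  # optional pre-computed chart-eligibility column is honoured last
  cohort$eligible <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  res2 <- apply_exclusions(cohort)
  expect_equal(unname(res2$tally[["chart_ineligible"]]), 1L)
  expect_equal(nrow(res2$cohort), 1L)
})

test_that("no eligible record is ever excluded (property over random records)", {
  recs <- random_records(200, seed = 42)
  recs$age <- runif(200, 18, 95)
  recs$pain_duration_days <- runif(200, 0, 14)
  recs$recent_trauma_24h <- FALSE
  res <- apply_exclusions(recs)
  expect_equal(nrow(res$cohort), 200L)
  expect_true(all(res$tally == 0L))
})

test_that("1:1 control selection is uniform-without-replacement, seeded, and guarded", {
  recs <- random_records(900, seed = 9)
  recs$arm <- factor(rep(c("case", "control"), c(140, 760)),
                     levels = c("case", "control"))
  s1 <- select_controls(recs, 379, seed = 11)
  s2 <- select_controls(recs, 379, seed = 11)
  expect_identical(s1$id, s2$id)
  expect_equal(unname(arm_sizes(s1)), c(140L, 379L))
  expect_true(all(recs$id[recs$arm == "case"] %in% s1$id))

  s3 <- select_controls(recs, 379, seed = 12)
  expect_false(identical(s1$id, s3$id))

  all_ctl <- select_controls(recs, 760, seed = 99)
  expect_equal(sort(all_ctl$id), sort(recs$id))

  expect_error(select_controls(recs, 761, seed = 1), "761.*760")
})
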