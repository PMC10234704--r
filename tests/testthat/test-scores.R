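test_that("RIPP component mapping matches the scorecard on canonical presentations", {
  cohort <- bind_records(
    record(id = "classic", known_aortic_aneurysm = TRUE, impression = "aas_most_likely",
           hypotension = TRUE, abrupt_onset_pain = TRUE, migrating_radiating = TRUE),
    record(id = "benign", impression = "alternative_likely"),
    record(id = "neutral"),
    record(id = "pain3", abrupt_onset_pain = TRUE, tearing_ripping = TRUE,
           migrating_radiating = TRUE)
  )
  res <- score_ripp(cohort)
  expect_equal(res$total, c(7L, -1L, 0L, 2L))
  expect_equal(res$high_risk, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$pain_points, c(1L, 0L, 0L, 2L))
  expect_equal(res$risk_factor_points[1], 2L)
  expect_equal(res$impression_points[2], -1L)
  # components always sum to the total
  expect_equal(res$risk_factor_points + res$impression_points +
                 res$exam_points + res$pain_points, res$total)
})

test_that("pain banding is exact over all 16 feature subsets", {
  grid <- expand.grid(abrupt_onset_pain = c(FALSE, TRUE),
                      tearing_ripping = c(FALSE, TRUE),
                      migrating_radiating = c(FALSE, TRUE),
                      severe_pain = c(FALSE, TRUE))
  cohort <- do.call(bind_records, lapply(seq_len(nrow(grid)), function(i) {
    do.call(record, as.list(grid[i, ]))
  }))
  res <- score_ripp(cohort)
  n_feat <- rowSums(grid)
  expect_equal(res$pain_points,
               ifelse(n_feat == 0, 0L, ifelse(n_feat <= 2, 1L, 2L)))
  expect_equal(res$total, res$pain_points)  # nothing else set
})

test_that("RIPP total stays in [-1, 8] and is monotone in every feature", {
  recs <- random_records(300, seed = 13)
  base <- score_ripp(recs)$total
  expect_true(all(base >= -1 & base <= 8))
  flip_fields <- setdiff(boolean_fields(), c("cxr_abnormal", "recent_trauma_24h"))
  for (f in flip_fields) {
    up <- recs
    up[[f]] <- TRUE
    expect_true(all(score_ripp(up)$total >= base), info = f)
  }
  # impression moves along its printed ordering
  for (lv in c("alternative_likely", "unsure", "aas_most_likely")) {
    recs2 <- recs
    recs2$impression <- factor(lv, levels = levels(recs$impression))
    assign(paste0("t_", lv), score_ripp(recs2)$total)
  }
  expect_true(all(t_alternative_likely <= t_unsure))
  expect_true(all(t_unsure <= t_aas_most_likely))
})

test_that("scoring refuses unresolved missing values", {
  cohort <- bind_records(record())
  cohort$hypotension <- NA
  expect_error(score_ripp(cohort), "apply_missing_policy")
  defs <- builtin_definitions()
  expect_error(evaluate_definition(defs$addrs, cohort), "apply_missing_policy")
})

test_that("engine-encoded RIPP agrees with the native scorer on 10,000 random records", {
  recs <- random_records(10000, seed = 99)
  native <- score_ripp(recs)
  engine <- evaluate_definition(builtin_definitions()$ripp_engine, recs)
  expect_equal(engine$raw, native$total)
  expect_equal(engine$high_risk, native$high_risk)
})

test_that("the declarative engine evaluates definitions as specified", {
  defs <- builtin_definitions()
  tearing_only <- bind_records(record(tearing_ripping = TRUE))
  res <- evaluate_definition(defs$addrs, tearing_only)
  expect_equal(res$raw, 1L)
  expect_true(res$high_risk)

  empty <- score_definition("empty", items = list(), aggregation = "sum_points",
                            high_risk_threshold = 1L)
  res0 <- evaluate_definition(empty, random_records(5, seed = 1))
  expect_equal(res0$raw, rep(0L, 5))
  expect_false(any(res0$high_risk))

  # saturation: a record satisfying every item scores the full points sum
  everything <- bind_records(record(
    known_aortic_aneurysm = TRUE, hypotension = TRUE, tearing_ripping = TRUE,
    abrupt_onset_pain = TRUE, severe_pain = TRUE, focal_neuro_deficit = TRUE,
    pulse_deficit = TRUE))
  aortas <- evaluate_definition(defs$aortas, everything)
  pts <- vapply(defs$aortas$items, `[[`, 0, "points")
  expect_equal(aortas$raw, as.integer(sum(pts)))

  # contributions sum (or count) to the raw score
  recs <- random_records(50, seed = 3)
  for (d in defs) {
    r <- evaluate_definition(d, recs)
    expect_equal(unname(rowSums(attr(r, "contributions"))), as.numeric(r$raw),
                 info = d$name)
  }
})

test_that("definition validation rejects unknown fields and disallowed operators at load time", {
  bad_field <- list(list(name = "x", points = 1, predicate = "not_a_field"))
  expect_error(score_definition("bad", bad_field), "unknown field 'not_a_field'")
  bad_op <- list(list(name = "x", points = 1, predicate = "age > 50"))
  expect_error(score_definition("bad", bad_op), "operator '>' not allowed")
})

test_that("dichotomisation applies the threshold comparator and is monotone", {
  defn <- score_definition("t", list(), high_risk_threshold = 1L, comparator = ">=")
  expect_false(dichotomize(0L, defn))
  expect_true(dichotomize(1L, defn))
  raws <- -1:8
  expect_true(all(diff(dichotomize(raws, defn)) >= 0))
})

test_that("the RIPP score==1 convention switch shifts the dichotomy as documented", {
  # a record whose total is exactly 1 (single non-aneurysmal risk factor)
  boundary <- bind_records(record(family_history = TRUE))
  expect_true(score_ripp(boundary, threshold = "ge1")$high_risk)
  expect_false(score_ripp(boundary, threshold = "ge2")$high_risk)

  # downstream accuracy shifts accordingly: ge2 can only lower sensitivity
  cohort <- generate_cohort(generator_config(n_cases = 300L, n_controls = 300L, seed = 8L))
  s1 <- score_cohort(cohort, "ripp", ripp_threshold = "ge1")
  s2 <- score_cohort(cohort, "ripp", ripp_threshold = "ge2")
  cm1 <- confusion(s1$high_risk, s1$arm)
  cm2 <- confusion(s2$high_risk, s2$arm)
  expect_lte(cm2$tp, cm1$tp)
  expect_gte(cm2$tn, cm1$tn)
})

test_that("score_cohort is order-stable, complete, and rejects unknown tools", {
  cohort <- bind_records(record(), record(arm = "control"))
  all_tools <- c("ripp", "addrs", "lovy", "aortas", "von_kodolitsch")
  res <- score_cohort(cohort, all_tools)
  expect_equal(nrow(res), 10L)
  expect_equal(unique(res$tool), all_tools)
  # the all-negative unsure record is low risk under every tool
  neg <- res[res$id == res$id[1], ]
  expect_false(any(neg$high_risk))
  expect_error(score_cohort(cohort, "apgar"), "unknown tool.*registered tools")
})

test_that("hand-scored golden records match across tools", {
  cohort <- bind_records(
    record(id = "g1"),
    record(id = "g2", known_aortic_aneurysm = TRUE, impression = "aas_most_likely",
           hypotension = TRUE, abrupt_onset_pain = TRUE, migrating_radiating = TRUE),
    record(id = "g3", impression = "alternative_likely"),
    record(id = "g4", abrupt_onset_pain = TRUE, tearing_ripping = TRUE,
           migrating_radiating = TRUE),
    record(id = "g5", family_history = TRUE),
    record(id = "g6", severe_pain = TRUE),
    record(id = "g7", impression = "alternative_likely", severe_pain = TRUE),
    record(id = "g8", aortic_valve_disease = TRUE, impression = "aas_most_likely",
           hypotension = TRUE, new_murmur = TRUE, pulse_deficit = TRUE,
           focal_neuro_deficit = TRUE, bp_differential_gt20 = TRUE,
           abrupt_onset_pain = TRUE, tearing_ripping = TRUE,
           migrating_radiating = TRUE, severe_pain = TRUE)
  )
  ripp <- score_ripp(cohort)
  expect_equal(ripp$total, c(0L, 7L, -1L, 2L, 1L, 1L, 0L, 7L))
  expect_equal(ripp$high_risk, c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))

  addrs <- evaluate_definition(builtin_definitions()$addrs, cohort)
  # hand count of satisfied categories: predisposing / pain / exam
  expect_equal(addrs$raw, c(0L, 2L, 0L, 1L, 1L, 1L, 1L, 3L))
  expect_equal(addrs$high_risk, addrs$raw >= 1L)

  vonk <- evaluate_definition(builtin_definitions()$von_kodolitsch, cohort)
  expect_equal(vonk$raw, c(0L, 1L, 0L, 1L, 0L, 0L, 0L, 2L))
})
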