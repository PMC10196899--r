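test_that("stream lengths equal rate times duration for every channel", {
  s <- tiny_session(length_s = 300)
  for (nm in names(E4_RATES)) {
    expect_length(s$channels[[nm]]$samples, 300 * E4_RATES[[nm]])
  }
})

test_that("generation is deterministic under a fixed seed", {
  a <- tiny_session(seed = 11)
  b <- tiny_session(seed = 11)
  expect_identical(a, b)
  c2 <- tiny_session(seed = 12)
  expect_false(identical(a$channels$EDA$samples, c2$channels$EDA$samples))
})

test_that("planted events violate their intended rule in the raw stream", {
  plan <- artifact_plan(rule_id = 3, start_second = 50, duration_seconds = 10)
  s <- generate_session(length_s = 120, label = "T2", plan = plan, seed = 3)
  temp <- s$channels$TEMP$samples
  idx <- (50 * 4 + 1):(60 * 4)
  expect_true(all(temp[idx] < 30))
  expect_true(all(temp[-idx] >= 30))
})

test_that("invalid plans and parameters are rejected", {
  bad <- artifact_plan(rule_id = 1, start_second = 115, duration_seconds = 10)
  expect_error(generate_session(length_s = 120, label = "T0", plan = bad),
               "outside the session")
  expect_error(artifact_plan(rule_id = 5, start_second = 1, duration_seconds = 1),
               "rule_id")
  expect_error(generate_session(length_s = 32, label = "T0"), ">= 64")
  expect_error(generate_session(length_s = 120, label = "T0", delta = -1),
               "delta")
  expect_error(cohort_config(subjects = 0), "at least one subject")
})

test_that("artifact completeness: the rule oracle flags inside every planted event, and only there", {
  plan <- full_plan()
  s <- generate_session(length_s = 200, label = "T1", plan = plan, seed = 9)
  orc <- oracle_qc(s)
  t0 <- s$channels$EDA$start_time  # grid is in absolute epoch seconds
  for (k in seq_len(nrow(plan))) {
    span <- t0 + seq(plan$start_second[k],
                     plan$start_second[k] + plan$duration_seconds[k])
    flagged_in_span <- orc$rules[orc$seconds %in% span, plan$rule_id[k]]
    expect_true(any(flagged_in_span),
                label = sprintf("rule %d event flagged by its rule", plan$rule_id[k]))
  }
  clean <- generate_session(length_s = 200, label = "T1", seed = 9)
  expect_equal(sum(!oracle_qc(clean)$valid), 0)
})

test_that("severity cohorts have one session per subject and time point", {
  co <- generate_cohort(cohort_config("severity", subjects = 2,
                                      session_length = 64, seed = 1))
  expect_length(co$sessions, 6)
  expect_equal(as.vector(table(co$metadata$label)), rep(2L, 3))
  co2 <- generate_cohort(cohort_config("severity", subjects = 2,
                                       session_length = 64, seed = 1))
  expect_identical(co$metadata, co2$metadata)
})

test_that("psychometric items respect instrument ranges and label conditioning", {
  co <- generate_cohort(cohort_config("severity", subjects = 3,
                                      session_length = 64, seed = 4))
  md <- co$metadata
  ym <- as.matrix(md[, paste0("YMRS", 1:11)])
  hd <- as.matrix(md[, paste0("HDRS", 1:17)])
  expect_true(all(ym >= 0) && all(t(ym) <= c(4, 4, 4, 4, 8, 8, 4, 8, 8, 4, 4)))
  expect_true(all(hd >= 0))
  # remission: both totals at 7 or below; acute mania: YMRS total near 20+
  t2 <- md$label == "T2"
  expect_true(all(rowSums(ym[t2, ]) <= 7) && all(rowSums(hd[t2, ]) <= 7))
  expect_true(all(rowSums(ym[md$label == "T0", ]) >= 15))
})

test_that("zero separation removes all class structure from the signal", {
  specs <- default_channel_specs("severity")
  a <- generate_session(specs, 64, "T0", seed = 5, delta = 0)
  b <- generate_session(specs, 64, "T2", seed = 5, delta = 0)
  expect_identical(a$channels$EDA$samples, b$channels$EDA$samples)
  expect_identical(a$channels$HR$samples, b$channels$HR$samples)
})
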