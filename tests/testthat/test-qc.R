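test_that("EDA slope is the forward difference scaled by rate", {
  expect_equal(eda_slope(rep(2, 10), 4), rep(0, 10))
  # 1.0 -> 4.0 uS between consecutive 4 Hz samples: 12 uS/s, beyond +10
  expect_equal(eda_slope(c(1, 4), 4)[2], 12)
  expect_equal(eda_slope(numeric(1), 4), 0)
  set.seed(1)
  x <- cumsum(rnorm(50))
  manual <- c(0, (x[-1] - x[-50]) * 4)
  expect_equal(eda_slope(x, 4), manual)
})

test_that("out-of-range samples flag their containing second", {
  s <- tiny_session(length_s = 100, seed = 6)
  s$channels$EDA$samples[4 * 40 + 2] <- 0.04  # inside second 40
  m <- apply_filter(s)
  sec40 <- which(m$seconds == s$channels$EDA$start_time + 40)
  expect_true(m$rules[sec40, 1])
  expect_false(m$valid[sec40])
})

test_that("range endpoints are inclusive", {
  # channels pinned exactly at the limits stay valid throughout
  mk <- function(val, rate, n = 80) list(start_time = 0, rate = rate,
                                         samples = rep(val, rate * n))
  s <- e4_session("edge", "p", "T0", channels = list(
    ACC_X = mk(0, 32), ACC_Y = mk(0, 32), ACC_Z = mk(1, 32),
    BVP = mk(0, 64), EDA = mk(0.05, 4), TEMP = mk(30, 4), HR = mk(250, 1)))
  m <- apply_filter(s)
  expect_true(all(m$valid))
  # one step past the limit flags
  s$channels$TEMP$samples[] <- 29.999
  expect_false(all(apply_filter(s)$valid))
})

test_that("a clean session yields an empty mask (idempotence on filtered data)", {
  s <- tiny_session(length_s = 300, seed = 10)
  m <- apply_filter(s)
  expect_true(all(m$valid))
  expect_equal(sum(m$rules), 0)
})

test_that("flagged seconds match the brute-force per-sample oracle exactly", {
  for (seed in 1:10) {
    plan <- artifact_plan(
      rule_id = sample(1:4, 3, replace = TRUE),
      start_second = sample(10:160, 3),
      duration_seconds = sample(2:8, 3)
    )
    s <- generate_session(length_s = 200, label = "T0", plan = plan,
                          seed = seed)
    m <- apply_filter(s)
    orc <- oracle_qc(s)
    expect_identical(m$valid, orc$valid)
    expect_identical(unname(m$rules), unname(orc$rules))
  }
})

test_that("widening a valid range never increases the flagged set", {
  plan <- full_plan()
  s <- generate_session(length_s = 200, label = "T0", plan = plan, seed = 2)
  narrow <- apply_filter(s, filter_config())
  wide <- apply_filter(s, filter_config(eda_range = c(0.001, 100),
                                        temp_range = c(20, 45),
                                        hr_range = c(10, 350),
                                        eda_slope_range = c(-20, 20)))
  expect_true(all(narrow$valid | !wide$valid | wide$valid))
  expect_true(all(which(!wide$valid) %in% which(!narrow$valid)))
})

test_that("every transition-padded second sits within 5 s of a hard rule", {
  plan <- full_plan()
  s <- generate_session(length_s = 200, label = "T0", plan = plan, seed = 2)
  m <- apply_filter(s)
  hard <- m$seconds[m$rules[, 1] | m$rules[, 2] | m$rules[, 3] | m$rules[, 4]]
  pad <- m$seconds[m$rules[, 5]]
  expect_gt(length(pad), 0)
  for (p in pad) expect_lte(min(abs(hard - p)), 5)
  # rule 5 never marks a second already caught by rules 1-4
  expect_false(any(m$rules[, 5] & rowSums(m$rules[, 1:4]) > 0))
})

test_that("drop report arithmetic and degenerate cases", {
  s <- tiny_session(length_s = 100)
  m <- apply_filter(s)
  r <- drop_report(m)
  expect_equal(r$dropped_pct, 0)
  # 398 flagged of 3600 seconds is 11.06%, the scale of a typical session
  fake <- structure(list(
    seconds = 1:3600,
    valid = c(rep(FALSE, 398), rep(TRUE, 3202)),
    rules = cbind(rule1 = c(rep(TRUE, 398), rep(FALSE, 3202)),
                  rule2 = FALSE, rule3 = FALSE, rule4 = FALSE, rule5 = FALSE)
  ), class = "validity_mask")
  expect_equal(drop_report(fake)$dropped_pct, 100 * 398 / 3600)
  expect_equal(round(drop_report(fake)$dropped_pct, 2), 11.06)
  expect_error(drop_report(structure(list(seconds = integer(), valid = logical(),
                                          rules = matrix(FALSE, 0, 5)),
                                     class = "validity_mask")), "empty")
  s$channels$HR <- NULL
  expect_error(apply_filter(s), "HR")
})

test_that("planted drop percentage matches the oracle", {
  plan <- artifact_plan(rule_id = 2, start_second = 50, duration_seconds = 10)
  s <- generate_session(length_s = 400, label = "T1", plan = plan, seed = 3)
  m <- apply_filter(s)
  orc <- oracle_qc(s)
  expect_equal(drop_report(m)$dropped_pct, 100 * sum(!orc$valid) / 400)
})
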