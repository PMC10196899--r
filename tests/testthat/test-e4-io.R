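test_that("write/read round-trips a session to declared precision", {
  s <- tiny_session(length_s = 128, seed = 2)
  d <- withr::local_tempdir()
  write_session(s, d)
  s2 <- read_session(d)
  # ACC is integer counts: exact
  expect_identical(s2$channels$ACC_X$samples, s$channels$ACC_X$samples)
  # other channels: 6 significant digits
  for (nm in c("EDA", "TEMP", "BVP", "HR")) {
    expect_equal(s2$channels[[nm]]$samples, s$channels[[nm]]$samples,
                 tolerance = 1e-5)
    expect_identical(s2$channels[[nm]]$rate, as.numeric(E4_RATES[[nm]]))
  }
  expect_identical(s2$ymrs, s$ymrs)
  expect_identical(s2$hdrs, s$hdrs)
  expect_identical(s2$label, s$label)
  expect_equal(s2$ibi$interval, s$ibi$interval, tolerance = 1e-5)
  # byte determinism
  d2 <- withr::local_tempdir()
  write_session(s, d2)
  for (f in list.files(d)) {
    expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)))
  }
})

test_that("acceleration counts convert at 1/64 g per count", {
  d <- withr::local_tempdir()
  writeLines(c("1600000000", "32", "64,0,-32"), file.path(d, "ACC.csv"))
  for (nm in c("EDA", "TEMP", "BVP", "HR")) {
    rate <- c(EDA = 4, TEMP = 4, BVP = 64, HR = 1)[[nm]]
    base <- c(EDA = 2, TEMP = 34, BVP = 0, HR = 70)[[nm]]
    writeLines(c("1600000000", as.character(rate), rep(as.character(base), rate)),
               file.path(d, paste0(nm, ".csv")))
  }
  s <- read_session(d)
  expect_identical(s$channels$ACC_X$samples, 1.0)
  expect_identical(s$channels$ACC_Y$samples, 0.0)
  expect_identical(s$channels$ACC_Z$samples, -0.5)
})

test_that("missing and malformed archives fail with informative errors", {
  s <- tiny_session(length_s = 70)
  d <- withr::local_tempdir()
  write_session(s, d)
  file.remove(file.path(d, "EDA.csv"))
  expect_error(read_session(d), "EDA")

  d2 <- withr::local_tempdir()
  write_session(s, d2)
  lines <- readLines(file.path(d2, "TEMP.csv"))
  lines[2] <- "not-a-rate"
  writeLines(lines, file.path(d2, "TEMP.csv"))
  expect_error(read_session(d2), "line 2")

  d3 <- withr::local_tempdir()
  write_session(s, d3)
  lines <- readLines(file.path(d3, "HR.csv"))
  lines[10] <- "oops"
  writeLines(lines, file.path(d3, "HR.csv"))
  expect_error(read_session(d3), "line 10")

  bad <- s
  bad$channels$EDA$rate <- 0
  expect_error(e4_session("x", "x", "T0", channels = bad$channels), "rate")
})

test_that("an empty IBI list writes a header-only file", {
  s <- tiny_session(length_s = 70)
  s$ibi <- data.frame(offset = numeric(), interval = numeric())
  d <- withr::local_tempdir()
  write_session(s, d)
  expect_length(readLines(file.path(d, "IBI.csv")), 1L)
  expect_equal(nrow(read_session(d)$ibi), 0L)
})

test_that("validate_session reports consistent rate x duration", {
  s <- tiny_session(length_s = 90)
  d <- withr::local_tempdir()
  write_session(s, d)
  v <- validate_session(d)
  expect_setequal(v$channel, names(E4_RATES))
  expect_true(all(abs(v$samples - v$rate * 90) <= v$rate))
  expect_true(all(v$seconds == 90))
})

test_that("cohorts round-trip through archives and a metadata table", {
  co <- generate_cohort(cohort_config("severity", subjects = 1,
                                      session_length = 64, seed = 8))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_setequal(names(co2$sessions), names(co$sessions))
  expect_equal(co2$metadata$label, co$metadata$label)
  expect_equal(co2$metadata$YMRS1, co$metadata$YMRS1)
  expect_equal(co2$sessions[[1]]$channels$EDA$samples,
               co$sessions[[1]]$channels$EDA$samples, tolerance = 1e-5)
})
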