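test_that("downsampling takes per-unit means and drops partial units", {
  expect_equal(downsample(rep(5, 32), 32), 5)
  expect_equal(downsample(1:64, 64), 32.5)
  expect_equal(downsample(1:10, 4), c(2.5, 6.5))  # trailing 2 samples dropped
  set.seed(3)
  x <- rnorm(1000)
  expect_equal(downsample(x, 4, 1), oracle_unit_means(x, 4, 1))
  expect_equal(downsample(x, 4, 8), oracle_unit_means(x, 4, 8))
  expect_error(downsample(1:4, 0.5, 1), ">= 1")
})

test_that("alignment joins channels on their common seconds", {
  s <- tiny_session(length_s = 120, seed = 1)
  rec <- align(s)
  expect_equal(ncol(rec$matrix), 120)
  expect_equal(rownames(rec$matrix), E4_CHANNELS)
  # HR passes through unaveraged
  expect_equal(rec$matrix["HR", ], unname(s$channels$HR$samples[1:120]))
  # EDA row equals per-second means
  expect_equal(rec$matrix["EDA", ],
               oracle_unit_means(s$channels$EDA$samples, 4, 1))
})

test_that("a late-starting HR stream shifts the common grid", {
  s <- tiny_session(length_s = 130, seed = 2, hr_offset_s = 10)
  rec <- align(s)
  expect_equal(rec$seconds[1], s$channels$HR$start_time)
  expect_equal(length(rec$seconds), 120)
})

test_that("flagged seconds are removed from all channels", {
  plan <- artifact_plan(rule_id = 4, start_second = 30, duration_seconds = 5)
  s <- generate_session(length_s = 150, label = "T0", plan = plan, seed = 4)
  m <- apply_filter(s)
  rec <- align(s, m)
  expect_setequal(rec$seconds, m$seconds[m$valid])
  orc <- oracle_qc(s)
  expect_setequal(rec$seconds, orc$seconds[orc$valid])
})

test_that("windowing arithmetic matches the contiguous-run oracle", {
  s <- tiny_session(length_s = 3600, seed = 5)
  rec <- align(s)
  expect_equal(dim(segment_windows(rec, 32))[1], 112)
  expect_equal(dim(segment_windows(rec, 1))[1], 3600)
  # gapped grids: windows never straddle a gap
  for (seed in 1:5) {
    set.seed(seed)
    rec2 <- rec
    drop <- sort(sample(3600, 150))
    rec2$seconds <- rec$seconds[-drop]
    rec2$matrix <- rec$matrix[, -drop]
    for (w in c(8, 32)) {
      expect_equal(dim(segment_windows(rec2, w))[1],
                   oracle_segment_count(rec2$seconds, w))
    }
  }
  expect_error(segment_windows(rec, 48), "power of 2")
  rec3 <- rec
  rec3$seconds <- rec$seconds[1:20]
  rec3$matrix <- rec$matrix[, 1:20]
  expect_warning(out <- segment_windows(rec3, 32), "zero segments")
  expect_equal(dim(out)[1], 0)
})

test_that("windowing conserves data: segments x w never exceeds valid seconds", {
  s <- tiny_session(length_s = 500, seed = 6)
  rec <- align(s)
  for (w in c(4, 16, 64)) {
    expect_lte(dim(segment_windows(rec, w))[1] * w, length(rec$seconds))
  }
})

test_that("min-max normalization uses train statistics only", {
  set.seed(7)
  train <- array(rnorm(40 * 7 * 8, mean = 6, sd = 2), dim = c(40, 7, 8))
  params <- fit_normalizer(train)
  scaled <- apply_normalizer(train, params)
  expect_gte(min(scaled), 0)
  expect_lte(max(scaled), 1)
  # (x - min) / (max - min): spot value
  expect_equal(apply_normalizer(array(6, dim = c(1, 7, 1)),
                                list(min = rep(2, 7), max = rep(10, 7)))[1, 1, 1],
               0.5)
  # oracle recomputation
  ch_min <- apply(train, 2, min); ch_max <- apply(train, 2, max)
  manual <- sweep(sweep(train, 2, ch_min), 2, ch_max - ch_min, "/")
  expect_equal(scaled, manual)
  # test data outside the train range is not clipped
  test <- array(100, dim = c(1, 7, 8))
  expect_true(all(apply_normalizer(test, params) > 1))
  # constant channel maps to zero
  train[, 3, ] <- 1
  expect_message(p2 <- fit_normalizer(train), "constant")
  expect_true(all(apply_normalizer(train, p2)[, 3, ] == 0))
})

test_that("partitions follow the 20-test / 80-20 contract and stay disjoint", {
  arr <- make_arrays(150, w = 8)
  seg <- list(structure(arr$x, label = NA, session_id = "s", subject_id = "p"))
  pool <- list(segments = arr$x, labels = arr$y,
               sessions = rep("s", 450), subjects = rep("p", 450))
  ds <- make_partitions(pool, seed = 1)
  tab <- table(ds$labels, ds$partition)
  expect_true(all(tab[, "test"] == 20))
  expect_true(all(tab[, "train"] == 104))
  expect_true(all(tab[, "validation"] == 26))
  # disjoint by construction: partition is a single assignment vector
  expect_true(all(table(ds$partition)[c("train", "validation", "test")] ==
                    c(312, 78, 60)))
  ds2 <- make_partitions(pool, seed = 2)
  expect_false(identical(which(ds$partition == "test"),
                         which(ds2$partition == "test")))
  expect_identical(unname(table(ds2$partition)), unname(table(ds$partition)))
  # reproducible under the same seed
  expect_identical(make_partitions(pool, seed = 1)$partition, ds$partition)
})

test_that("undersized classes are rejected by name", {
  arr <- make_arrays(15, w = 4)
  pool <- list(segments = arr$x, labels = arr$y,
               sessions = rep("s", 45), subjects = rep("p", 45))
  expect_error(make_partitions(pool, test_per_class = 20), "C1")
})

test_that("unbalanced pools are balanced by down-sampling to the smallest class", {
  arr <- make_arrays(60, w = 4)
  keep <- c(which(arr$y == "C1"), which(arr$y == "C2")[1:45],
            which(arr$y == "C3")[1:30])
  pool <- list(segments = arr$x[keep, , , drop = FALSE], labels = arr$y[keep],
               sessions = rep("s", length(keep)), subjects = rep("p", length(keep)))
  ds <- make_partitions(pool, seed = 3)
  tab <- table(ds$labels, ds$partition)
  expect_true(all(tab[, "test"] == 20))
  expect_equal(length(unique(tab[, "train"])), 1L)
  expect_equal(length(unique(tab[, "validation"])), 1L)
})

test_that("generalization sets exclude training subjects and unseen labels", {
  arr <- make_arrays(30, w = 4)
  pool <- list(segments = arr$x, labels = arr$y,
               sessions = rep("s1", 90), subjects = rep("p1", 90))
  ds <- make_partitions(pool, test_per_class = 5, seed = 1)
  overlap <- list(segments = arr$x, labels = arr$y,
                  sessions = rep("s1", 90), subjects = rep("p1", 90))
  expect_error(make_generalization_set(overlap, ds), "overlap")
  arr2 <- make_arrays(10, w = 4, K = 3, seed = 2)
  alien <- list(segments = arr2$x, labels = rep("Z", 30),
                sessions = rep("s9", 30), subjects = rep("p9", 30))
  expect_error(make_generalization_set(alien, ds), "absent")
  ok <- list(segments = arr2$x, labels = arr2$y,
             sessions = rep("s9", 30), subjects = rep("p9", 30))
  g <- make_generalization_set(ok, ds, seed = 1)
  expect_equal(length(unique(table(g$y))), 1L)
})
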