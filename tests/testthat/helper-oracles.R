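# Independent brute-force oracles. These deliberately re-derive everything
# sample by sample with plain loops, sharing no code with the package paths
# they check.

# Per-sample, per-rule QC oracle: flags every grid second containing a
# violating native-rate sample, then pads rule 5 around rules 1-4.
oracle_qc <- function(session, config = filter_config()) {
  chs <- session$channels
  starts <- sapply(chs, function(c) ceiling(c$start_time))
  ends <- sapply(chs, function(c) floor(c$start_time + length(c$samples) / c$rate))
  grid <- seq.int(max(starts), min(ends) - 1)
  rules <- matrix(FALSE, length(grid), 5)
  second_of <- function(ch, i) floor(ch$start_time + (i - 1) / ch$rate)
  mark <- function(rules, col, ch, bad_idx) {
    for (i in bad_idx) {
      s <- second_of(ch, i)
      j <- which(grid == s)
      if (length(j)) rules[j, col] <- TRUE
    }
    rules
  }
  eda <- chs$EDA
  rules <- mark(rules, 1, eda,
                which(eda$samples < config$eda_range[1] |
                      eda$samples > config$eda_range[2]))
  sl <- rep(0, length(eda$samples))
  for (i in 2:length(eda$samples)) {
    sl[i] <- (eda$samples[i] - eda$samples[i - 1]) * eda$rate
  }
  rules <- mark(rules, 2, eda,
                which(sl < config$eda_slope_range[1] |
                      sl > config$eda_slope_range[2]))
  temp <- chs$TEMP
  rules <- mark(rules, 3, temp,
                which(temp$samples < config$temp_range[1] |
                      temp$samples > config$temp_range[2]))
  hr <- chs$HR
  rules <- mark(rules, 4, hr,
                which(hr$samples < config$hr_range[1] |
                      hr$samples > config$hr_range[2]))
  hard <- rules[, 1] | rules[, 2] | rules[, 3] | rules[, 4]
  for (j in seq_along(grid)) {
    if (!hard[j] && any(hard & abs(grid - grid[j]) <= config$transition_pad)) {
      rules[j, 5] <- TRUE
    }
  }
  list(seconds = grid, valid = rowSums(rules) == 0, rules = rules)
}

# per-unit mean oracle for downsampling
oracle_unit_means <- function(samples, rate, mu = 1) {
  per <- rate * mu
  out <- c()
  i <- 1
  while (i + per - 1 <= length(samples)) {
    out <- c(out, mean(samples[i:(i + per - 1)]))
    i <- i + per
  }
  out
}

# number of non-overlapping w-windows over contiguous runs of seconds
oracle_segment_count <- function(seconds, w) {
  if (!length(seconds)) return(0L)
  runs <- split(seconds, cumsum(c(1, diff(seconds) != 1)))
  sum(vapply(runs, function(r) floor(length(r) / w), 0))
}

# tie-corrected Kendall W through base R's Friedman statistic:
# chi^2_F = m (n - 1) W
oracle_kendall_w <- function(scores) {
  m <- nrow(scores); n <- ncol(scores)
  fr <- stats::friedman.test(scores)
  unname(fr$statistic / (m * (n - 1)))
}

# closed-form MI (nats) from a joint count table
oracle_mi_from_counts <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) total <- total + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  total
}
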