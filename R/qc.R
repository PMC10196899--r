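#' Quality-control filter configuration
#'
#' Valid ranges for the rules-based filter of invalid physiological data:
#' rule 1, EDA outside 0.05-60 uS (floor/ceiling artifacts); rule 2, EDA
#' slope outside -10 to +10 uS/s; rule 3, skin temperature outside
#' 30-40 degC (sensor not worn); rule 4, heart rate outside 25-250 bpm;
#' rule 5 flags transitional data within 5 s of any second caught by rules
#' 1-4. Range endpoints are inclusive: a value exactly on the limit is valid.
#'
#' @param eda_range,eda_slope_range,temp_range,hr_range Length-2 ordered
#'   numeric ranges.
#' @param transition_pad Seconds of padding around invalid seconds (rule 5).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(eda_range = c(0.05, 60),
                          eda_slope_range = c(-10, 10),
                          temp_range = c(30, 40),
                          hr_range = c(25, 250),
                          transition_pad = 5) {
  for (r in list(eda_range, eda_slope_range, temp_range, hr_range)) {
    if (length(r) != 2 || r[1] > r[2]) stop_mw("ranges must be ordered length-2")
  }
  if (transition_pad < 0) stop_mw("transition_pad must be >= 0")
  structure(list(eda_range = eda_range, eda_slope_range = eda_slope_range,
                 temp_range = temp_range, hr_range = hr_range,
                 transition_pad = transition_pad),
            class = "filter_config")
}

#' Per-sample EDA slope
#'
#' Forward difference scaled by the sampling rate, in uS per second. The
#' first sample's slope is defined as 0.
#'
#' @param eda Numeric samples at the native rate.
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of slopes, same length as `eda`.
#' @export
eda_slope <- function(eda, rate) {
  if (length(eda) < 2) return(rep(0, length(eda)))
  c(0, diff(eda) * rate)
}

# Integer-second grid shared by all modeled channels of a session:
# from the latest channel start to the earliest channel end.
session_grid <- function(session) {
  chs <- session$channels[intersect(E4_CHANNELS, names(session$channels))]
  starts <- vapply(chs, function(ch) ceiling(ch$start_time), 0)
  ends <- vapply(chs, function(ch) floor(ch$start_time + length(ch$samples) / ch$rate), 0)
  lo <- max(starts); hi <- min(ends)
  if (hi <= lo) stop_mw("channels share no common seconds")
  seq.int(lo, hi - 1L)
}

# second containing sample i of a channel (samples timestamped at their onset)
sample_seconds <- function(ch) {
  floor(ch$start_time + (seq_along(ch$samples) - 1) / ch$rate)
}

#' Apply the rules-based filter to a session
#'
#' Rules are evaluated on native-rate samples; any violating sample
#' invalidates the whole second that contains it, on the integer-second grid
#' common to all channels. Rule 5 then flags every otherwise-valid second
#' within `transition_pad` seconds (both directions) of a second caught by
#' rules 1-4. Invalidity is global: a flagged second is excluded from all
#' seven channels downstream.
#'
#' @param session An `e4_session` containing at least EDA, TEMP and HR.
#' @param config A [filter_config()].
#' @return An object of class `validity_mask`: grid `seconds`, logical
#'   `valid`, and an n x 5 logical matrix `rules` recording which rule(s)
#'   flagged each second.
#' @export
apply_filter <- function(session, config = filter_config()) {
  for (nm in c("EDA", "TEMP", "HR")) {
    if (!nm %in% names(session$channels)) {
      stop_mw("governing channel '%s' missing; cannot apply filter", nm)
    }
  }
  grid <- session_grid(session)
  rules <- matrix(FALSE, length(grid), 5,
                  dimnames = list(NULL, paste0("rule", 1:5)))
  flag <- function(ch, violating) {
    secs <- unique(sample_seconds(ch)[violating])
    grid %in% secs
  }
  eda <- session$channels$EDA
  rules[, 1] <- flag(eda, eda$samples < config$eda_range[1] |
                          eda$samples > config$eda_range[2])
  sl <- eda_slope(eda$samples, eda$rate)
  rules[, 2] <- flag(eda, sl < config$eda_slope_range[1] |
                          sl > config$eda_slope_range[2])
  temp <- session$channels$TEMP
  rules[, 3] <- flag(temp, temp$samples < config$temp_range[1] |
                           temp$samples > config$temp_range[2])
  hr <- session$channels$HR
  rules[, 4] <- flag(hr, hr$samples < config$hr_range[1] |
                         hr$samples > config$hr_range[2])
  hard <- rules[, 1] | rules[, 2] | rules[, 3] | rules[, 4]
  if (any(hard) && config$transition_pad > 0) {
    # grid is consecutive, so padding is index arithmetic
    n <- length(grid); pad <- config$transition_pad
    near <- rep(FALSE, n)
    for (h in which(hard)) {
      near[max(1, h - pad):min(n, h + pad)] <- TRUE
    }
    rules[, 5] <- near & !hard
  }
  structure(list(seconds = grid, valid = rowSums(rules) == 0, rules = rules,
                 session_id = session$session_id),
            class = "validity_mask")
}

#' @export
print.validity_mask <- function(x, ...) {
  cat(sprintf("Validity mask for %s: %d seconds, %d flagged (%.2f%%)\n",
              x$session_id %||% "?", length(x$seconds), sum(!x$valid),
              100 * mean(!x$valid)))
  cat("  per-rule seconds:", paste(colnames(x$rules), colSums(x$rules),
                                   sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Summarize data dropped by the quality-control filter
#'
#' @param mask A `validity_mask`.
#' @return A list of class `drop_report`: total seconds, flagged seconds,
#'   percentage dropped, and per-rule second counts (a second may trigger
#'   several rules, so rule counts can sum to more than the flagged total).
#' @export
drop_report <- function(mask) {
  stopifnot(inherits(mask, "validity_mask"))
  if (length(mask$seconds) == 0) stop_mw("empty validity mask")
  flagged <- sum(!mask$valid)
  structure(list(
    total_seconds = length(mask$seconds),
    flagged_seconds = flagged,
    dropped_pct = 100 * flagged / length(mask$seconds),
    per_rule = colSums(mask$rules)
  ), class = "drop_report")
}

#' @export
print.drop_report <- function(x, ...) {
  cat(sprintf("QC drop report: %d/%d seconds flagged (%.2f%%)\n",
              x$flagged_seconds, x$total_seconds, x$dropped_pct))
  cat("  ", paste(names(x$per_rule), x$per_rule, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Export a validity mask as a per-second table
#'
#' @param mask A `validity_mask`.
#' @return Data frame: second, valid, comma-separated triggering rules.
#' @export
mask_table <- function(mask) {
  rules <- apply(mask$rules, 1, function(r) {
    paste(which(r), collapse = ",")
  })
  data.frame(second = mask$seconds, valid = mask$valid, rules = rules)
}
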