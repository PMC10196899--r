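#' Channel inventory of an E4-style recording
#'
#' The device streams seven modeled channels: triaxial acceleration at 32 Hz,
#' electrodermal activity (EDA) and skin temperature at 4 Hz, blood volume
#' pulse (BVP) at 64 Hz, and heart rate (HR) at 1 Hz. Interbeat intervals
#' (IBI) are carried through input/output as metadata but never modeled.
#'
#' @format A named integer vector of sampling rates (Hz) keyed by channel.
#' @export
E4_RATES <- c(
  ACC_X = 32L, ACC_Y = 32L, ACC_Z = 32L,
  EDA = 4L, TEMP = 4L, BVP = 64L, HR = 1L
)

#' Canonical channel order used by the aligned 7-channel matrix
#' @export
E4_CHANNELS <- c("ACC_X", "ACC_Y", "ACC_Z", "BVP", "EDA", "HR", "TEMP")

# Acceleration is stored on-device as signed integer counts at 1/64 g per
# count; I/O converts to g on read and back to counts on write.
ACC_COUNTS_PER_G <- 64

# Instrument item maxima: Young Mania Rating Scale (11 items; items 5, 6, 8
# and 9 are double-weighted 0-8) and 17-item Hamilton Depression Rating Scale.
YMRS_ITEM_MAX <- c(4L, 4L, 4L, 4L, 8L, 8L, 4L, 8L, 8L, 4L, 4L)
HDRS_ITEM_MAX <- c(4L, 4L, 4L, 2L, 2L, 2L, 4L, 4L, 4L, 4L, 4L, 2L, 2L, 2L, 4L, 3L, 2L)

#' Class labels for the two supervised tasks
#'
#' `severity_labels()` gives the three intra-individual episode states
#' (acute, response, remission); `polarity_labels()` the seven
#' inter-individual diagnosis/state classes.
#'
#' @return Character vector of class labels.
#' @export
severity_labels <- function() c("T0", "T1", "T2")

#' @rdname severity_labels
#' @export
polarity_labels <- function() {
  c("manic_BD", "depressed_BD", "mixed_BD", "depressed_MDD",
    "euthymic_BD", "euthymic_MDD", "HC")
}

#' Per-channel signal specification for the synthetic generator
#'
#' Describes one channel's sampling rate, resting baseline, white-noise
#' standard deviation, slow baseline drift, and the class-conditional
#' structure: an additive mean shift and a multiplicative variance factor per
#' class label. Class shifts are scaled by the cohort separation `delta`, so
#' `delta = 0` makes all classes identically distributed.
#'
#' @param name Channel name, one of `names(E4_RATES)`.
#' @param baseline Resting level in channel units (g, uS, degC, a.u., bpm).
#' @param noise_sd White-noise SD at the native rate, channel units.
#' @param drift_sd Stationary SD of the mean-reverting baseline drift
#'   (correlation time about 30 s).
#' @param bounds Length-2 reflecting bounds keeping the drifting baseline
#'   inside the physiologically valid range.
#' @param class_shift Named numeric vector: additive offset per class label.
#' @param class_scale Named numeric vector: variance scale factor per label.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, baseline, noise_sd, drift_sd = 0,
                         bounds = c(-Inf, Inf),
                         class_shift = numeric(), class_scale = numeric()) {
  if (!name %in% names(E4_RATES)) {
    stop_mw("unknown channel name '%s'", name)
  }
  if (noise_sd < 0) stop_mw("noise_sd must be >= 0 for channel '%s'", name)
  structure(list(
    name = name, rate = E4_RATES[[name]], baseline = baseline,
    noise_sd = noise_sd, drift_sd = drift_sd, bounds = bounds,
    class_shift = class_shift, class_scale = class_scale
  ), class = "channel_spec")
}

#' Default channel specifications for a synthetic mood-disorder cohort
#'
#' Baselines sit well inside the quality-control filter's valid ranges.
#' Class-conditional structure reflects the clinical picture in kind: acute
#' states raise motor activity (ACC), electrodermal activity and heart rate
#' and depress peripheral skin temperature; BVP carries no class information
#' (raw pulse waveform, uninformative for these tasks). Severity classes
#' order T0 > T1 > T2; the seven polarity classes get distinct shift
#' patterns across channels.
#'
#' @param task `"severity"` or `"polarity"`.
#' @return Named list of [channel_spec()] objects, one per modeled channel.
#' @export
default_channel_specs <- function(task = c("severity", "polarity")) {
  task <- match.arg(task)
  if (task == "severity") {
    lab <- severity_labels()
    shifts <- list(
      ACC_X = c(0.20, 0.08, 0), ACC_Y = c(0.16, 0.06, 0), ACC_Z = c(0.12, 0.05, 0),
      BVP   = c(0, 0, 0),
      EDA   = c(1.50, 0.60, 0),
      HR    = c(12, 5, 0),
      TEMP  = c(-0.8, -0.3, 0)
    )
    scales <- list(
      ACC_X = c(1.4, 1.15, 1), ACC_Y = c(1.4, 1.15, 1), ACC_Z = c(1.4, 1.15, 1),
      BVP = c(1, 1, 1), EDA = c(1.3, 1.1, 1), HR = c(1.2, 1.1, 1),
      TEMP = c(1, 1, 1)
    )
  } else {
    lab <- polarity_labels()
    # rows: manic, depBD, mixed, depMDD, euthBD, euthMDD, HC
    shifts <- list(
      ACC_X = c(0.25, -0.08, 0.18, -0.12, 0.05, -0.03, 0),
      ACC_Y = c(0.20, -0.06, 0.14, -0.10, 0.04, -0.02, 0),
      ACC_Z = c(0.15, -0.05, 0.10, -0.08, 0.03, -0.02, 0),
      BVP   = rep(0, 7),
      EDA   = c(0.6, 1.2, 0.9, 1.5, 0.25, 0.15, 0),
      HR    = c(10, 8, 9, 6, 2, 1, 0),
      TEMP  = c(-0.3, -0.6, -0.45, -0.8, -0.1, -0.05, 0)
    )
    scales <- lapply(stats::setNames(names(shifts), names(shifts)),
                     function(ch) rep(1, 7))
    scales$EDA <- c(1.3, 1.2, 1.25, 1.2, 1.05, 1.05, 1)
    scales$ACC_X <- c(1.4, 0.9, 1.25, 0.85, 1.05, 1, 1)
  }
  base <- list(
    ACC_X = list(baseline = 0.00, noise_sd = 0.12, drift_sd = 0.02, bounds = c(-1.5, 1.5)),
    ACC_Y = list(baseline = 0.00, noise_sd = 0.12, drift_sd = 0.02, bounds = c(-1.5, 1.5)),
    ACC_Z = list(baseline = 0.70, noise_sd = 0.12, drift_sd = 0.02, bounds = c(-1.5, 1.5)),
    BVP   = list(baseline = 0.00, noise_sd = 15.0, drift_sd = 2.00, bounds = c(-150, 150)),
    EDA   = list(baseline = 2.00, noise_sd = 0.25, drift_sd = 0.15, bounds = c(0.5, 20)),
    HR    = list(baseline = 72.0, noise_sd = 3.00, drift_sd = 2.00, bounds = c(45, 160)),
    TEMP  = list(baseline = 34.0, noise_sd = 0.15, drift_sd = 0.08, bounds = c(31.5, 38))
  )
  out <- lapply(names(base), function(ch) {
    channel_spec(
      name = ch,
      baseline = base[[ch]]$baseline,
      noise_sd = base[[ch]]$noise_sd,
      drift_sd = base[[ch]]$drift_sd,
      bounds = base[[ch]]$bounds,
      class_shift = stats::setNames(shifts[[ch]], lab),
      class_scale = stats::setNames(scales[[ch]], lab)
    )
  })
  stats::setNames(out, names(base))
}
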