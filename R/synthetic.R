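#' Plan rule-violating artifacts for a synthetic session
#'
#' Each event makes the governing channel violate one quality-control rule
#' for a span of seconds: rule 1 pins EDA to an out-of-range value
#' (default 0.01 uS, a "floor" artifact), rule 2 superimposes an alternating
#' per-sample jump on EDA so the slope exceeds +/-10 uS/s, rule 3 pins skin
#' temperature out of range (default 25 degC, sensor off wrist), rule 4 pins
#' heart rate out of range (default 300 bpm).
#'
#' @param rule_id Integer vector in 1..4, one per event.
#' @param start_second Event onset, seconds from session start (0-based).
#' @param duration_seconds Event length in seconds.
#' @param magnitude Value the channel is pinned to (rules 1, 3, 4) or the
#'   per-sample alternating jump in uS (rule 2). `NA` picks the default.
#' @return An object of class `artifact_plan` (a data frame).
#' @export
artifact_plan <- function(rule_id = integer(), start_second = integer(),
                          duration_seconds = integer(), magnitude = NA_real_) {
  n <- length(rule_id)
  if (n > 0 && (length(start_second) != n || length(duration_seconds) != n)) {
    stop_mw("rule_id, start_second and duration_seconds must have equal length")
  }
  if (n > 0 && !all(rule_id %in% 1:4)) {
    stop_mw("rule_id must lie in 1..4 (rule 5 is derived padding, not plantable)")
  }
  defaults <- c(0.01, 3.5, 25, 300)
  magnitude <- rep_len(magnitude, max(n, 0L))
  if (n > 0) {
    magnitude[is.na(magnitude)] <- defaults[rule_id[is.na(magnitude)]]
  }
  structure(
    data.frame(rule_id = as.integer(rule_id),
               start_second = as.numeric(start_second),
               duration_seconds = as.numeric(duration_seconds),
               magnitude = as.numeric(magnitude)),
    class = c("artifact_plan", "data.frame")
  )
}

# Mean-reverting (Ornstein-Uhlenbeck) baseline drift, one value per second,
# reflected into [lo, hi]. Mean reversion (correlation time ~tau s) keeps the
# session-average level at `center`, so sessions carry no long-run level
# fingerprint and classes with zero shift stay indistinguishable.
reflect_walk <- function(n, center, stat_sd, lo, hi, tau = 30) {
  center <- min(max(center, lo), hi)
  if (stat_sd <= 0) return(rep(center, n))
  phi <- exp(-1 / tau)
  eps <- stats::rnorm(n, 0, stat_sd * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- center + eps[1]
  for (t in 2:n) x[t] <- center + phi * (x[t - 1] - center) + eps[t]
  span <- hi - lo
  if (is.finite(span)) {
    y <- (x - lo) %% (2 * span)
    y <- ifelse(y > span, 2 * span - y, y)
    x <- y + lo
  }
  x
}

generate_channel <- function(spec, length_s, label, delta = 1,
                             subject_offset = 0) {
  n <- spec$rate * length_s
  shift <- if (length(spec$class_shift) && label %in% names(spec$class_shift)) {
    delta * spec$class_shift[[label]]
  } else 0
  vscale <- if (length(spec$class_scale) && label %in% names(spec$class_scale)) {
    1 + delta * (spec$class_scale[[label]] - 1)
  } else 1
  level <- reflect_walk(length_s, spec$baseline + shift + subject_offset,
                        spec$drift_sd, spec$bounds[1], spec$bounds[2])
  samples <- rep(level, each = spec$rate) +
    stats::rnorm(n, 0, spec$noise_sd * sqrt(max(vscale, 0)))
  samples
}

inject_artifacts <- function(channels, plan, length_s) {
  if (is.null(plan) || nrow(plan) == 0L) return(channels)
  governing <- c("EDA", "EDA", "TEMP", "HR")
  for (k in seq_len(nrow(plan))) {
    ev <- plan[k, ]
    if (ev$start_second < 0 || ev$start_second + ev$duration_seconds > length_s) {
      stop_mw("artifact event %d lies outside the session (start %s, duration %s, session %s s)",
              k, ev$start_second, ev$duration_seconds, length_s)
    }
    ch <- governing[ev$rule_id]
    rate <- E4_RATES[[ch]]
    idx <- seq.int(floor(ev$start_second * rate) + 1L,
                   floor((ev$start_second + ev$duration_seconds) * rate))
    idx <- idx[idx >= 1 & idx <= length(channels[[ch]]$samples)]
    if (ev$rule_id == 2L) {
      # alternating +magnitude on every other sample: slope = magnitude * rate
      bump <- rep_len(c(0, ev$magnitude), length(idx))
      channels[[ch]]$samples[idx] <- channels[[ch]]$samples[idx] + bump
    } else {
      channels[[ch]]$samples[idx] <- ev$magnitude
    }
  }
  channels
}

# Draw item scores summing near target_total, each within its instrument
# maximum; if cap is finite the total is reduced below it (remission).
generate_item_scores <- function(target_total, item_max, cap = Inf) {
  lambda <- target_total * item_max / sum(item_max)
  scores <- pmin(stats::rpois(length(item_max), lambda), item_max)
  while (sum(scores) > cap) {
    pos <- which(scores > 0)
    pick <- pos[sample.int(length(pos), 1L)]
    scores[pick] <- scores[pick] - 1L
  }
  as.integer(scores)
}

score_targets <- function(label, episode_type = "manic_BD") {
  # (YMRS target total, HDRS target total, cap on each total or Inf)
  sev <- switch(episode_type,
    manic_BD      = list(T0 = c(24, 5), T1 = c(12, 4), T2 = c(3, 3)),
    mixed_BD      = list(T0 = c(26, 10), T1 = c(14, 6), T2 = c(4, 3)),
    depressed_BD  = list(T0 = c(2, 22), T1 = c(2, 12), T2 = c(2, 3)),
    depressed_MDD = list(T0 = c(3, 28), T1 = c(2, 13), T2 = c(1, 4)),
    stop_mw("unknown episode_type '%s'", episode_type)
  )
  pol <- list(
    manic_BD = c(24, 5), depressed_BD = c(2, 22), mixed_BD = c(26, 10),
    depressed_MDD = c(3, 28), euthymic_BD = c(2, 3), euthymic_MDD = c(1, 3),
    HC = c(1, 1)
  )
  if (label %in% names(sev)) {
    list(targets = sev[[label]], cap = if (label == "T2") 7 else Inf)
  } else if (label %in% names(pol)) {
    cap <- if (label %in% c("euthymic_BD", "euthymic_MDD", "HC")) 7 else Inf
    list(targets = pol[[label]], cap = cap)
  } else {
    list(targets = c(2, 2), cap = 7)
  }
}

#' Generate one synthetic E4-style recording session
#'
#' Produces all seven modeled channels at their native rates around a slowly
#' drifting baseline (reflecting random walk inside the physiologically valid
#' range) with Gaussian noise, a class-conditional mean shift scaled by
#' `delta`, and a class-conditional variance factor. Artifact-plan events are
#' injected afterwards so each one violates its intended quality-control
#' rule. Acceleration is quantized to 1/64 g, the on-device count resolution.
#'
#' @param specs Named list of [channel_spec()]; default
#'   [default_channel_specs()] for the severity task.
#' @param length_s Session length in seconds (>= 64).
#' @param label Class label used to look up class-conditional structure.
#' @param plan An [artifact_plan()]; default empty.
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param delta Class-separation multiplier applied to all class shifts
#'   (and, symmetrically, to variance factors); 0 removes all class structure.
#' @param subject_offset Named per-channel additive offset (subject random
#'   effect), channel units.
#' @param subject_id,session_id,time_point Metadata carried on the session.
#' @param episode_type Episode profile used for the psychometric items when
#'   `label` is a severity time point.
#' @param hr_offset_s HR stream start delay in seconds (device behavior;
#'   default 0).
#' @param start_time Session start, epoch seconds.
#' @return An `e4_session` object.
#' @export
generate_session <- function(specs = default_channel_specs("severity"),
                             length_s, label, plan = artifact_plan(),
                             seed = 1L, delta = 1,
                             subject_offset = numeric(),
                             subject_id = "S01", session_id = NULL,
                             time_point = if (label %in% severity_labels()) label else "single",
                             episode_type = "manic_BD",
                             hr_offset_s = 0, start_time = 1600000000) {
  if (length_s < 64) stop_mw("length_s must be >= 64 seconds")
  bad <- setdiff(names(specs), names(E4_RATES))
  if (length(bad)) stop_mw("unknown channel name '%s'", bad[1])
  if (delta < 0) stop_mw("class separation delta must be >= 0")
  with_seed(seed, {
    channels <- lapply(specs, function(sp) {
      off <- if (sp$name %in% names(subject_offset)) subject_offset[[sp$name]] else 0
      list(start_time = start_time, rate = sp$rate,
           samples = generate_channel(sp, length_s, label, delta, off))
    })
    names(channels) <- vapply(specs, `[[`, "", "name")
    channels <- inject_artifacts(channels, plan, length_s)
    for (a in intersect(c("ACC_X", "ACC_Y", "ACC_Z"), names(channels))) {
      channels[[a]]$samples <-
        round(channels[[a]]$samples * ACC_COUNTS_PER_G) / ACC_COUNTS_PER_G
    }
    if (hr_offset_s > 0 && "HR" %in% names(channels)) {
      hr <- channels$HR
      keep <- seq.int(hr$rate * hr_offset_s + 1L, length(hr$samples))
      channels$HR <- list(start_time = start_time + hr_offset_s,
                          rate = hr$rate, samples = hr$samples[keep])
    }
    # sparse IBI record: carried through I/O, excluded from modeling
    n_ibi <- min(75L, length_s)
    intervals <- stats::rnorm(n_ibi, 0.8, 0.05)
    ibi <- data.frame(offset = cumsum(intervals), interval = intervals)
    st <- score_targets(label, episode_type)
    ymrs <- generate_item_scores(st$targets[1], YMRS_ITEM_MAX, st$cap)
    hdrs <- generate_item_scores(st$targets[2], HDRS_ITEM_MAX, st$cap)
    e4_session(
      session_id = session_id %||% paste0(subject_id, "_", label),
      subject_id = subject_id, label = label, time_point = time_point,
      channels = channels, ibi = ibi, ymrs = ymrs, hdrs = hdrs
    )
  })
}

#' Configuration for a synthetic cohort
#'
#' @param task `"severity"` (three within-subject time points) or
#'   `"polarity"` (seven diagnostic classes across subjects).
#' @param subjects Subjects per class: for severity, the number of subjects
#'   (each contributes T0/T1/T2 sessions); for polarity, subjects per label.
#' @param session_length Seconds per session.
#' @param delta Class-separation multiplier, >= 0.
#' @param seed Integer seed.
#' @param episode_type Severity-task episode profile (affects psychometric
#'   items and is recorded in metadata).
#' @param subject_sd Named per-channel SD of subject random offsets; defaults
#'   give mild between-subject heterogeneity.
#' @param generalization_subjects Extra held-out subjects per class, marked
#'   `role = "generalization"` in the metadata.
#' @param confound `"class"` (default: class shifts are shared across
#'   subjects, so models can generalize) or `"subject"` (shifts are drawn per
#'   subject irrespective of class, so internal accuracy stays high while
#'   generalization collapses to chance).
#' @param hr_offset_s HR start delay passed to [generate_session()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(task = c("severity", "polarity"), subjects = 1L,
                          session_length = 3600, delta = 1, seed = 1L,
                          episode_type = "manic_BD",
                          subject_sd = c(ACC_X = 0.02, ACC_Y = 0.02, ACC_Z = 0.02,
                                         BVP = 0, EDA = 0.15, HR = 2, TEMP = 0.15),
                          generalization_subjects = 0L,
                          confound = c("class", "subject"),
                          hr_offset_s = 0) {
  task <- match.arg(task)
  confound <- match.arg(confound)
  if (delta < 0) stop_mw("class separation delta must be >= 0")
  if (subjects < 1) stop_mw("need at least one subject per class")
  structure(list(
    task = task, subjects = as.integer(subjects),
    session_length = session_length, delta = delta, seed = as.integer(seed),
    episode_type = episode_type, subject_sd = subject_sd,
    generalization_subjects = as.integer(generalization_subjects),
    confound = confound, hr_offset_s = hr_offset_s
  ), class = "cohort_config")
}

#' Generate a synthetic cohort of E4-style sessions
#'
#' Severity cohorts give every subject three sessions (T0 acute, T1 response,
#' T2 remission); polarity cohorts give one session per subject across the
#' seven diagnostic classes. Psychometric item scores are drawn from
#' label-conditioned ranges (acute mania reaches a YMRS total around 20+;
#' remission keeps both totals at 7 or below), so downstream
#' mutual-information analysis has a recoverable ground truth. Fully
#' deterministic given the config.
#'
#' @param config A [cohort_config()].
#' @return An object of class `e4_cohort`: list with `sessions` (list of
#'   `e4_session`) and `metadata` (one row per session: subject, label, role,
#'   item scores).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- default_channel_specs(config$task)
  labels <- if (config$task == "severity") severity_labels() else polarity_labels()
  n_train <- config$subjects
  n_gen <- config$generalization_subjects

  make_subjects <- function(n, role, id0) {
    if (config$task == "severity") {
      data.frame(subject = sprintf("S%02d", id0 + seq_len(n) - 1),
                 class = NA_character_, role = role)
    } else {
      grid <- expand.grid(class = labels, idx = seq_len(n),
                          stringsAsFactors = FALSE)
      data.frame(subject = sprintf("S%02d", id0 + seq_len(nrow(grid)) - 1),
                 class = grid$class, role = role)
    }
  }
  subj <- rbind(make_subjects(n_train, "train", 1L),
                if (n_gen > 0) make_subjects(n_gen, "generalization",
                                             1L + n_train * ifelse(config$task == "severity", 1L, length(labels))))

  sessions <- list(); meta <- list()
  for (i in seq_len(nrow(subj))) {
    sid <- subj$subject[i]
    subj_seed <- derive_seed(config$seed + 13L * i, "session")
    offs <- with_seed(subj_seed, {
      sd <- config$subject_sd
      stats::setNames(stats::rnorm(length(sd), 0, sd), names(sd))
    })
    # subject-confounded variant: classes stay separable within a subject,
    # but the class-to-shift mapping is a subject-specific (non-identity)
    # relabeling, so nothing transfers to unseen subjects
    conf_perm <- NULL
    if (config$confound == "subject") {
      conf_perm <- with_seed(subj_seed + 1L, {
        repeat {
          p <- sample.int(length(labels))
          if (any(p != seq_along(labels))) break
        }
        p
      })
    }
    session_labels <- if (config$task == "severity") labels else subj$class[i]
    for (lb in session_labels) {
      sp_use <- specs
      delta_use <- config$delta
      off_use <- offs
      if (!is.null(conf_perm)) {
        sp_use <- lapply(specs, function(sp) {
          sp$class_shift[labels] <- sp$class_shift[labels][conf_perm]
          sp$class_scale[labels] <- sp$class_scale[labels][conf_perm]
          sp
        })
      }
      ses_id <- paste0(sid, "_", lb)
      s <- generate_session(
        specs = sp_use, length_s = config$session_length, label = lb,
        plan = artifact_plan(), seed = derive_seed(config$seed + 977L * i +
                                                     match(lb, labels), "session"),
        delta = delta_use, subject_offset = off_use, subject_id = sid,
        session_id = ses_id,
        time_point = if (config$task == "severity") lb else "single",
        episode_type = config$episode_type, hr_offset_s = config$hr_offset_s
      )
      sessions[[ses_id]] <- s
      meta[[ses_id]] <- data.frame(
        subject_id = sid, session_id = ses_id, label = lb,
        time_point = s$time_point, role = subj$role[i],
        episode_type = if (config$task == "severity") config$episode_type else lb,
        t(stats::setNames(s$ymrs, paste0("YMRS", 1:11))),
        t(stats::setNames(s$hdrs, paste0("HDRS", 1:17)))
      )
    }
  }
  structure(list(sessions = sessions,
                 metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
                 config = config),
            class = "e4_cohort")
}

#' @export
print.e4_cohort <- function(x, ...) {
  cat(sprintf("E4 cohort: %d sessions, %d subjects%s\n",
              length(x$sessions), length(unique(x$metadata$subject_id)),
              if (!is.null(x$config)) {
                sprintf(", task '%s', delta = %g", x$config$task, x$config$delta)
              } else ""))
  print(table(x$metadata$label, x$metadata$role))
  invisible(x)
}
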