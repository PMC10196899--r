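#' Downsample a channel to per-unit means
#'
#' Averages native-rate samples within consecutive time units of `mu`
#' seconds. Trailing samples that do not fill a whole unit are dropped.
#'
#' @param samples Numeric samples at the native rate.
#' @param rate Sampling rate in Hz.
#' @param mu Time unit in seconds (default 1).
#' @return One mean per complete unit.
#' @export
downsample <- function(samples, rate, mu = 1) {
  per <- rate * mu
  if (per < 1) stop_mw("rate x mu must be >= 1 sample per unit")
  n_units <- floor(length(samples) / per)
  if (n_units == 0) return(numeric())
  if (per == 1) return(samples[seq_len(n_units)])
  m <- matrix(samples[seq_len(n_units * per)], nrow = per)
  colMeans(m)
}

#' Align a session's channels to a common one-second grid
#'
#' Each channel is reduced to per-second means (a time unit of one second
#' across all channels; HR, already at 1 Hz, passes through unaveraged),
#' joined on the absolute seconds common to all seven channels, and the
#' seconds flagged by the validity mask are removed from every channel.
#'
#' @param session An `e4_session` with all seven modeled channels.
#' @param mask Optional `validity_mask` on the same grid; `NULL` keeps all.
#' @param mu Time unit in seconds; the pipeline default is 1.
#' @return An object of class `aligned_recording`: `seconds` (absolute,
#'   possibly gapped) and `matrix` (7 x n, rows in `E4_CHANNELS` order).
#' @export
align <- function(session, mask = NULL, mu = 1) {
  missing_ch <- setdiff(E4_CHANNELS, names(session$channels))
  if (length(missing_ch)) {
    stop_mw("channel '%s' missing; cannot align", missing_ch[1])
  }
  grid <- session_grid(session)
  if (mu != 1) {
    # coarser units shrink the grid to whole multiples of mu
    n_units <- floor(length(grid) / mu)
    if (n_units == 0) stop_mw("session shorter than one time unit")
    grid_units <- grid[1] + mu * (seq_len(n_units) - 1)
  } else {
    grid_units <- grid
  }
  mat <- matrix(NA_real_, length(E4_CHANNELS), length(grid_units),
                dimnames = list(E4_CHANNELS, NULL))
  for (nm in E4_CHANNELS) {
    ch <- session$channels[[nm]]
    # drop samples before the first grid second, then average within units
    skip <- round((grid[1] - ch$start_time) * ch$rate)
    usable <- ch$samples[(skip + 1):length(ch$samples)]
    means <- downsample(usable, ch$rate, mu)
    if (length(means) < length(grid_units)) {
      stop_mw("channel '%s' too short for the common grid", nm)
    }
    mat[nm, ] <- means[seq_along(grid_units)]
  }
  keep <- rep(TRUE, length(grid_units))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "validity_mask"))
    bad <- mask$seconds[!mask$valid]
    if (mu == 1) {
      keep <- !(grid_units %in% bad)
    } else {
      # a unit is dropped if any of its seconds is flagged
      keep <- vapply(grid_units, function(u) !any((u + 0:(mu - 1)) %in% bad), TRUE)
    }
  }
  if (!any(keep)) stop_mw("no valid seconds remain after filtering")
  structure(list(seconds = grid_units[keep],
                 matrix = mat[, keep, drop = FALSE],
                 mu = mu,
                 session_id = session$session_id,
                 subject_id = session$subject_id,
                 label = session$label),
            class = "aligned_recording")
}

#' @export
print.aligned_recording <- function(x, ...) {
  cat(sprintf("Aligned recording %s (label %s): 7 x %d valid units (mu = %g s)\n",
              x$session_id, x$label, ncol(x$matrix), x$mu))
  invisible(x)
}

# contiguous runs of consecutive seconds in a (possibly gapped) grid
contiguous_runs <- function(seconds, mu = 1) {
  if (length(seconds) == 0) return(list())
  brk <- c(0, which(diff(seconds) != mu), length(seconds))
  lapply(seq_len(length(brk) - 1), function(i) {
    seq.int(brk[i] + 1L, brk[i + 1L])
  })
}

#' Cut an aligned recording into fixed-length windows
#'
#' Consecutive non-overlapping windows of exactly `w` contiguous valid time
#' units. Windows never span a validity gap; trailing remainders are
#' discarded. Window lengths are powers of two from 1 to 2048 s.
#'
#' @param rec An `aligned_recording`.
#' @param w Window length in time units.
#' @return 3-d array n_segments x 7 x w (zero-row array, with a warning, if
#'   no contiguous run is long enough), with the source label and session
#'   kept in attributes `label`, `session_id`, `subject_id`.
#' @export
segment_windows <- function(rec, w = 32) {
  if (!w %in% 2^(0:11)) {
    stop_mw("window length w must be a power of 2 between 1 and 2048 seconds")
  }
  runs <- contiguous_runs(rec$seconds, rec$mu)
  pieces <- list()
  for (run in runs) {
    k <- floor(length(run) / w)
    if (k == 0) next
    for (j in seq_len(k)) {
      idx <- run[((j - 1) * w + 1):(j * w)]
      pieces[[length(pieces) + 1L]] <- rec$matrix[, idx, drop = FALSE]
    }
  }
  n <- length(pieces)
  if (n == 0) {
    warning(sprintf("no contiguous run of %d units in %s; zero segments",
                    w, rec$session_id))
    seg <- array(numeric(), dim = c(0, 7, w))
  } else {
    seg <- array(NA_real_, dim = c(n, 7, w),
                 dimnames = list(NULL, E4_CHANNELS, NULL))
    for (i in seq_len(n)) seg[i, , ] <- pieces[[i]]
  }
  attr(seg, "label") <- rec$label
  attr(seg, "session_id") <- rec$session_id
  attr(seg, "subject_id") <- rec$subject_id
  seg
}

#' Fit and apply the train-set min-max normalizer
#'
#' `fit_normalizer` computes per-channel global minima and maxima across all
#' training segments; `apply_normalizer` rescales segments to
#' (x - min) / (max - min). Training data land in [0, 1]; validation and
#' test values may fall outside and are not clipped. A channel constant in
#' the training set is mapped to 0 everywhere (with a message).
#'
#' @param segments n x 7 x w array.
#' @param params List with `min` and `max` per-channel vectors.
#' @return `fit_normalizer`: the params list; `apply_normalizer`: the
#'   rescaled array.
#' @export
fit_normalizer <- function(segments) {
  if (dim(segments)[1] == 0) stop_mw("cannot fit normalizer on empty train set")
  mins <- apply(segments, 2, min)
  maxs <- apply(segments, 2, max)
  if (any(maxs == mins)) {
    message("normalizer: channel(s) ",
            paste(E4_CHANNELS[maxs == mins], collapse = ", "),
            " constant in train; mapped to 0")
  }
  list(min = stats::setNames(mins, E4_CHANNELS),
       max = stats::setNames(maxs, E4_CHANNELS))
}

#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(segments, params) {
  rng <- params$max - params$min
  out <- segments
  for (c in seq_along(rng)) {
    if (rng[c] == 0) {
      out[, c, ] <- 0
    } else {
      out[, c, ] <- (segments[, c, ] - params$min[c]) / rng[c]
    }
  }
  out
}

stack_segments <- function(seg_list) {
  seg_list <- Filter(function(s) dim(s)[1] > 0, seg_list)
  if (!length(seg_list)) stop_mw("no segments supplied")
  w <- unique(vapply(seg_list, function(s) dim(s)[3], 0L))
  if (length(w) != 1) stop_mw("segments have inconsistent window lengths")
  n <- vapply(seg_list, function(s) dim(s)[1], 0L)
  seg <- array(NA_real_, dim = c(sum(n), 7, w),
               dimnames = list(NULL, E4_CHANNELS, NULL))
  labels <- character(sum(n)); sessions <- character(sum(n))
  subjects <- character(sum(n))
  at <- 0L
  for (s in seg_list) {
    idx <- at + seq_len(dim(s)[1])
    seg[idx, , ] <- s
    labels[idx] <- attr(s, "label")
    sessions[idx] <- attr(s, "session_id")
    subjects[idx] <- attr(s, "subject_id")
    at <- at + dim(s)[1]
  }
  list(segments = seg, labels = labels, sessions = sessions,
       subjects = subjects)
}

#' Build balanced train/validation/test partitions from labeled segments
#'
#' Twenty segments per class are drawn at random into a held-out test set,
#' never seen during training or validation. The remaining segments are
#' split 80/20 into train and validation at the segment level; both are
#' balanced across classes by down-sampling to the smallest class count.
#' Per-channel min-max normalization parameters are fitted on the train
#' partition only and applied to all partitions.
#'
#' @param seg_list List of segment arrays from [segment_windows()], or a
#'   single pre-stacked list with `segments`/`labels` elements.
#' @param test_per_class Held-out test segments per class (default 20).
#' @param val_frac Fraction of the remainder assigned to validation (0.2).
#' @param seed Integer seed making the selection reproducible.
#' @return An object of class `segment_dataset`: normalized `segments`,
#'   `labels`, `partition` factor (train/validation/test), `norm_params`,
#'   bookkeeping vectors and the seed.
#' @export
make_partitions <- function(seg_list, test_per_class = 20, val_frac = 0.2,
                            seed = 1L) {
  pool <- if (is.list(seg_list) && !is.null(seg_list$segments)) seg_list
          else stack_segments(seg_list)
  labels <- pool$labels
  classes <- sort(unique(labels))
  counts <- table(labels)
  short <- names(counts)[counts < test_per_class + 1]
  if (length(short)) {
    stop_mw("class '%s' supplies only %d segments; need at least %d",
            short[1], counts[[short[1]]], test_per_class + 1)
  }
  with_seed(seed, {
    part <- rep(NA_character_, length(labels))
    for (cl in classes) {
      idx <- which(labels == cl)
      test_idx <- sample(idx, test_per_class)
      part[test_idx] <- "test"
      rest <- setdiff(idx, test_idx)
      n_val <- round(val_frac * length(rest))
      val_idx <- sample(rest, n_val)
      part[val_idx] <- "validation"
      part[setdiff(rest, val_idx)] <- "train"
    }
    # balance train and validation by down-sampling to the smallest class
    for (p in c("train", "validation")) {
      sizes <- table(labels[part == p])
      m <- min(sizes)
      for (cl in classes) {
        idx <- which(part == p & labels == cl)
        if (length(idx) > m) {
          drop <- sample(idx, length(idx) - m)
          part[drop] <- "unused"
        }
      }
    }
    norm <- fit_normalizer(pool$segments[part == "train", , , drop = FALSE])
    structure(list(
      segments = apply_normalizer(pool$segments, norm),
      labels = labels,
      partition = factor(part, levels = c("train", "validation", "test", "unused")),
      sessions = pool$sessions, subjects = pool$subjects,
      norm_params = norm, seed = as.integer(seed),
      w = dim(pool$segments)[3]
    ), class = "segment_dataset")
  })
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("Segment dataset: %d segments of 7 x %d (seed %d)\n",
              dim(x$segments)[1], x$w, x$seed))
  print(table(x$labels, x$partition))
  invisible(x)
}

partition_xy <- function(ds, part) {
  idx <- which(ds$partition == part)
  list(x = ds$segments[idx, , , drop = FALSE], y = ds$labels[idx], idx = idx)
}

#' Build a subject-level generalization set
#'
#' Segments from held-out subjects (zero subject overlap with the training
#' cohort), normalized with the training normalizer and balanced per class
#' by down-sampling to the smallest class count.
#'
#' @param seg_list Segment arrays from the held-out subjects' recordings.
#' @param dataset The `segment_dataset` whose normalizer and label set apply.
#' @param seed Seed for the balancing draw.
#' @return List with normalized `x` and labels `y`.
#' @export
make_generalization_set <- function(seg_list, dataset, seed = 1L) {
  pool <- if (is.list(seg_list) && !is.null(seg_list$segments)) seg_list
          else stack_segments(seg_list)
  if (length(intersect(unique(pool$subjects), unique(dataset$subjects)))) {
    stop_mw("generalization subjects overlap the training cohort")
  }
  extra <- setdiff(unique(pool$labels), unique(dataset$labels))
  if (length(extra)) {
    stop_mw("label '%s' present in generalization set but absent in training",
            extra[1])
  }
  with_seed(seed, {
    m <- min(table(pool$labels))
    keep <- unlist(lapply(sort(unique(pool$labels)), function(cl) {
      idx <- which(pool$labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }))
    list(x = apply_normalizer(pool$segments[keep, , , drop = FALSE],
                              dataset$norm_params),
         y = pool$labels[keep])
  })
}
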