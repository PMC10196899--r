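#' Construct an E4-style session object
#'
#' Container for one wearable recording: per-channel sample streams with
#' their own start time (epoch seconds) and sampling rate, the interbeat
#' interval (IBI) event list (metadata only, never modeled), and the clinical
#' metadata attached to the session: class label, time point, and the YMRS
#' (11 items) and HDRS (17 items) psychometric scores.
#'
#' @param session_id,subject_id Identifier strings.
#' @param label Class label for supervised tasks.
#' @param time_point One of `"T0"`, `"T1"`, `"T2"`, `"single"`.
#' @param channels Named list; each element has `start_time`, `rate`,
#'   `samples`. Names must come from `names(E4_RATES)`.
#' @param ibi Data frame with columns `offset`, `interval` (seconds).
#' @param ymrs,hdrs Integer item scores within the instrument ranges.
#' @return An object of class `e4_session`.
#' @export
e4_session <- function(session_id, subject_id, label,
                       time_point = "single", channels, ibi = NULL,
                       ymrs = rep(0L, 11), hdrs = rep(0L, 17)) {
  bad <- setdiff(names(channels), names(E4_RATES))
  if (length(bad)) stop_mw("unknown channel name '%s'", bad[1])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch$rate) || ch$rate <= 0) {
      stop_mw("channel '%s' has non-positive sampling rate", nm)
    }
  }
  if (length(ymrs) != 11 || any(ymrs < 0) || any(ymrs > YMRS_ITEM_MAX)) {
    stop_mw("ymrs must be 11 item scores within the instrument ranges")
  }
  if (length(hdrs) != 17 || any(hdrs < 0) || any(hdrs > HDRS_ITEM_MAX)) {
    stop_mw("hdrs must be 17 item scores within the instrument ranges")
  }
  structure(list(
    session_id = session_id, subject_id = subject_id, label = label,
    time_point = time_point, channels = channels,
    ibi = ibi %||% data.frame(offset = numeric(), interval = numeric()),
    ymrs = as.integer(ymrs), hdrs = as.integer(hdrs)
  ), class = "e4_session")
}

#' @export
print.e4_session <- function(x, ...) {
  cat(sprintf("E4 session %s (subject %s, label %s, time point %s)\n",
              x$session_id, x$subject_id, x$label, x$time_point))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-6s %6.0f Hz  %8d samples  (%.0f s)\n", nm, ch$rate,
                length(ch$samples), length(ch$samples) / ch$rate))
  }
  cat(sprintf("  IBI: %d events; YMRS total %d, HDRS total %d\n",
              nrow(x$ibi), sum(x$ymrs), sum(x$hdrs)))
  invisible(x)
}

REQUIRED_FILES <- c(ACC = "ACC.csv", EDA = "EDA.csv", TEMP = "TEMP.csv",
                    BVP = "BVP.csv", HR = "HR.csv")

fmt6 <- function(x) formatC(signif(x, 6), format = "g", digits = 6)
# header lines (start time, rate) keep full precision: epoch seconds would
# lose their offset at 6 significant digits
fmt_hdr <- function(x) sprintf("%.10g", x)

#' Write a session to an E4-style archive directory
#'
#' One directory per session, mirroring the de-facto E4 export: per-channel
#' text file whose first row is the channel start time (epoch seconds) and
#' second row the sampling rate, followed by the samples; the three
#' acceleration axes share a single 3-column `ACC.csv` stored as integer
#' counts at 1/64 g per count; `IBI.csv` holds the start time then
#' (offset, interval) rows; `session.json` carries the clinical metadata.
#' Samples are written with 6 significant digits. Byte output is
#' deterministic for a fixed session.
#'
#' @param session An `e4_session`.
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "e4_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ch <- session$channels
  acc_names <- c("ACC_X", "ACC_Y", "ACC_Z")
  if (all(acc_names %in% names(ch))) {
    counts <- sapply(acc_names, function(a) {
      as.integer(round(ch[[a]]$samples * ACC_COUNTS_PER_G))
    })
    writeLines(c(fmt_hdr(ch$ACC_X$start_time), fmt_hdr(ch$ACC_X$rate),
                 apply(counts, 1, paste, collapse = ",")),
               file.path(path, "ACC.csv"))
  }
  for (nm in c("EDA", "TEMP", "BVP", "HR")) {
    if (!nm %in% names(ch)) next
    writeLines(c(fmt_hdr(ch[[nm]]$start_time), fmt_hdr(ch[[nm]]$rate),
                 fmt6(ch[[nm]]$samples)),
               file.path(path, paste0(nm, ".csv")))
  }
  ibi_rows <- if (nrow(session$ibi)) {
    paste(fmt6(session$ibi$offset), fmt6(session$ibi$interval), sep = ",")
  } else character()
  writeLines(c(fmt_hdr(ch[[1]]$start_time), ibi_rows), file.path(path, "IBI.csv"))
  meta <- list(session_id = session$session_id, subject_id = session$subject_id,
               label = session$label, time_point = session$time_point,
               ymrs = session$ymrs, hdrs = session$hdrs)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_channel_file <- function(file, n_cols = 1L) {
  lines <- readLines(file)
  if (length(lines) < 2) stop_mw("malformed header in %s: need 2 header lines", file)
  start_time <- suppressWarnings(as.numeric(lines[1]))
  rate <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(start_time)) stop_mw("malformed header in %s at line 1", file)
  if (is.na(rate)) stop_mw("malformed header in %s at line 2", file)
  body <- lines[-(1:2)]
  if (n_cols == 1L) {
    samples <- suppressWarnings(as.numeric(body))
    bad <- which(is.na(samples))
    if (length(bad)) stop_mw("malformed sample in %s at line %d", file, bad[1] + 2L)
    list(start_time = start_time, rate = rate, samples = samples)
  } else {
    parts <- strsplit(body, ",", fixed = TRUE)
    nc <- lengths(parts)
    if (any(nc != n_cols)) {
      stop_mw("malformed row in %s at line %d: expected %d columns",
              file, which(nc != n_cols)[1] + 2L, n_cols)
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = n_cols, byrow = TRUE)
    if (anyNA(m)) {
      stop_mw("malformed sample in %s at line %d", file,
              which(rowSums(is.na(m)) > 0)[1] + 2L)
    }
    list(start_time = start_time, rate = rate, samples = m)
  }
}

#' Read an E4-style session archive
#'
#' Inverse of [write_session()]. Acceleration counts are converted to g
#' (1/64 g per count). IBI is parsed but carried as metadata only; it is
#' never used by downstream modeling.
#'
#' @param path Archive directory.
#' @return An `e4_session`.
#' @export
read_session <- function(path) {
  for (nm in names(REQUIRED_FILES)) {
    if (!file.exists(file.path(path, REQUIRED_FILES[[nm]]))) {
      stop_mw("required channel '%s' missing from archive %s", nm, path)
    }
  }
  acc <- read_channel_file(file.path(path, "ACC.csv"), n_cols = 3L)
  channels <- list()
  for (i in 1:3) {
    channels[[c("ACC_X", "ACC_Y", "ACC_Z")[i]]] <- list(
      start_time = acc$start_time, rate = acc$rate,
      samples = acc$samples[, i] / ACC_COUNTS_PER_G
    )
  }
  for (nm in c("EDA", "TEMP", "BVP", "HR")) {
    channels[[nm]] <- read_channel_file(file.path(path, paste0(nm, ".csv")))
  }
  ibi <- data.frame(offset = numeric(), interval = numeric())
  ibi_file <- file.path(path, "IBI.csv")
  if (file.exists(ibi_file)) {
    lines <- readLines(ibi_file)
    if (length(lines) > 1) {
      parts <- strsplit(lines[-1], ",", fixed = TRUE)
      ibi <- data.frame(offset = as.numeric(vapply(parts, `[`, "", 1)),
                        interval = as.numeric(vapply(parts, `[`, "", 2)))
    }
  }
  meta_file <- file.path(path, "session.json")
  meta <- if (file.exists(meta_file)) {
    jsonlite::read_json(meta_file, simplifyVector = TRUE)
  } else {
    list(session_id = basename(path), subject_id = basename(path),
         label = "single", time_point = "single",
         ymrs = rep(0L, 11), hdrs = rep(0L, 17))
  }
  e4_session(session_id = meta$session_id, subject_id = meta$subject_id,
             label = meta$label, time_point = meta$time_point,
             channels = channels, ibi = ibi,
             ymrs = meta$ymrs, hdrs = meta$hdrs)
}

#' Validate a session archive
#'
#' Reports per-channel sample counts and checks that declared rate times
#' duration matches the sample count to within one sample (channels may end
#' at slightly different absolute times; the check uses each channel's own
#' span).
#'
#' @param path Archive directory.
#' @return Data frame with one row per channel: rate, samples, seconds.
#' @export
validate_session <- function(path) {
  s <- read_session(path)
  data.frame(
    channel = names(s$channels),
    rate = vapply(s$channels, function(ch) ch$rate, 0),
    samples = vapply(s$channels, function(ch) length(ch$samples), 0L),
    seconds = vapply(s$channels, function(ch) length(ch$samples) / ch$rate, 0),
    row.names = NULL
  )
}

#' Write / read cohort clinical metadata as a delimited table
#'
#' @param cohort An `e4_cohort` or its metadata data frame.
#' @param file Path of the tab-separated table.
#' @return `read_metadata` returns the metadata data frame.
#' @export
write_metadata <- function(cohort, file) {
  md <- if (inherits(cohort, "e4_cohort")) cohort$metadata else cohort
  utils::write.table(md, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a whole cohort as session archives plus a metadata table
#'
#' @param cohort An `e4_cohort`.
#' @param dir Output directory; one subdirectory per session.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) write_session(s, file.path(dir, s$session_id))
  write_metadata(cohort, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  sessions <- lapply(md$session_id, function(id) read_session(file.path(dir, id)))
  names(sessions) <- md$session_id
  structure(list(sessions = sessions, metadata = md, config = NULL),
            class = "e4_cohort")
}
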