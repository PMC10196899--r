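#' Plug-in mutual information between two discrete vectors
#'
#' MI = sum p(x, y) log( p(x, y) / (p(x) p(y)) ), in nats, from the joint
#' empirical frequency table. Non-negative, symmetric in its arguments, and
#' equal to the entropy H(y) when x determines y and vice versa.
#'
#' @param x,y Discrete vectors of equal length.
#' @return MI in nats.
#' @export
discrete_mi <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# equal-frequency binning; collapses duplicate quantile breaks
bin_equal_freq <- function(x, bins) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE)
  brk <- unique(qs)
  if (length(brk) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = brk, include.lowest = TRUE))
}

#' Mutual information between a channel summary and a scale item
#'
#' The channel is summarized per segment (default: per-segment mean of the
#' aligned, unnormalized channel), discretized by equal-frequency binning,
#' and related to the item score each segment inherits from its source
#' session.
#'
#' @param channel_summary Numeric per-segment channel summary.
#' @param item_scores Integer item score per segment.
#' @param bins Number of equal-frequency bins for the channel summary.
#' @return Raw MI in nats; 0 (with a message) when the item score is
#'   constant across segments.
#' @export
channel_item_mi <- function(channel_summary, item_scores, bins = 8) {
  if (length(unique(item_scores)) < 2) {
    message("item score constant across segments; MI = 0")
    return(0)
  }
  discrete_mi(bin_equal_freq(channel_summary, bins), item_scores)
}

# per-segment channel summaries for all sessions of the chosen pool
segment_summaries <- function(cohort, session_ids, w = 32, mu = 1,
                              qc = filter_config(),
                              summary = c("mean", "sd")) {
  summary <- match.arg(summary)
  fn <- if (summary == "mean") rowMeans else function(m) apply(m, 1, stats::sd)
  rows <- list(); items <- list()
  for (id in session_ids) {
    s <- cohort$sessions[[id]]
    seg <- segment_windows(align(s, apply_filter(s, qc), mu), w)
    if (dim(seg)[1] == 0) next
    sm <- t(apply(seg, 1, fn))  # n x 7
    colnames(sm) <- E4_CHANNELS
    rows[[id]] <- sm
    items[[id]] <- matrix(rep(c(s$ymrs, s$hdrs), each = dim(seg)[1]),
                          nrow = dim(seg)[1])
  }
  list(channels = do.call(rbind, rows),
       items = do.call(rbind, items))
}

item_names <- function() c(paste0("YMRS", 1:11), paste0("HDRS", 1:17))

#' Normalized mutual information between channels and psychometric items
#'
#' For every scale item (YMRS 1-11, HDRS 1-17) and every channel, the mutual
#' information between the per-segment channel summary and the item score is
#' computed, then scaled to [0, 1] per item by dividing by the maximum MI
#' across channels for that item (so every item row with nonzero association
#' contains at least one 1.0). Rows whose raw MI is zero everywhere stay
#' zero. The alternative symmetric normalization MI / sqrt(H(x) H(y)) is
#' available with `normalization = "symmetric"`.
#'
#' @param cohort An `e4_cohort`.
#' @param level `"intra"` (pool one subject's three time points) or
#'   `"between"` (pool across subjects).
#' @param subject Subject id for the intra level; default: first train subject.
#' @param w,mu,qc Preprocessing parameters (defaults 32 s windows, 1 s unit).
#' @param bins Equal-frequency bins for the channel summary.
#' @param summary Per-segment channel summary statistic.
#' @param normalization `"item_max"` (default) or `"symmetric"`.
#' @return Object of class `nmi_table`: 28 x 7 matrix plus the raw MI matrix
#'   in attribute `raw`.
#' @export
nmi_table <- function(cohort, level = c("intra", "between"), subject = NULL,
                      w = 32, mu = 1, qc = filter_config(), bins = 8,
                      summary = "mean",
                      normalization = c("item_max", "symmetric")) {
  level <- match.arg(level)
  normalization <- match.arg(normalization)
  md <- cohort$metadata
  ids <- if (level == "intra") {
    subject <- subject %||% md$subject_id[md$role == "train"][1]
    md$session_id[md$subject_id == subject]
  } else {
    md$session_id[md$role == "train"]
  }
  pool <- segment_summaries(cohort, ids, w, mu, qc, summary)
  items <- item_names()
  raw <- matrix(0, length(items), length(E4_CHANNELS),
                dimnames = list(items, E4_CHANNELS))
  for (i in seq_along(items)) {
    yi <- pool$items[, i]
    if (length(unique(yi)) < 2) {
      warning(sprintf("item %s constant in this pool; row left at zero", items[i]))
      next
    }
    for (j in seq_along(E4_CHANNELS)) {
      xb <- bin_equal_freq(pool$channels[, j], bins)
      raw[i, j] <- discrete_mi(xb, yi)
      if (normalization == "symmetric") {
        hx <- discrete_mi(xb, xb); hy <- discrete_mi(yi, yi)
        raw[i, j] <- if (hx > 0 && hy > 0) raw[i, j] / sqrt(hx * hy) else 0
      }
    }
  }
  norm <- raw
  if (normalization == "item_max") {
    for (i in seq_len(nrow(norm))) {
      mx <- max(raw[i, ])
      if (mx > 0) norm[i, ] <- raw[i, ] / mx
    }
  }
  structure(norm, raw = raw, level = level, normalization = normalization,
            class = c("nmi_table", "matrix"))
}

#' @export
print.nmi_table <- function(x, digits = 2, ...) {
  cat(sprintf("Channel-item normalized MI (%s level, %s normalization)\n",
              attr(x, "level"), attr(x, "normalization")))
  m <- matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
  print(round(m, digits))
  invisible(x)
}

#' Tile plot of a channel-item NMI table
#'
#' @param x An `nmi_table`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.nmi_table <- function(x, ...) {
  m <- t(matrix(as.numeric(x), nrow(x), ncol(x)))
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m[, rev(seq_len(ncol(m)))],
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  zlim = c(0, 1), ...)
  graphics::axis(1, seq_len(nrow(m)), colnames(x), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(ncol(m)), rev(rownames(x)), las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Write an NMI table as delimited text
#'
#' @param x An `nmi_table`.
#' @param file Output path (tab-separated, items as rows).
#' @export
write_nmi_table <- function(x, file) {
  m <- matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
  utils::write.table(data.frame(item = rownames(m), m, check.names = FALSE),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
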