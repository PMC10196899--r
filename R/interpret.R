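#' Per-channel permutation feature importance
#'
#' For each channel (or channel group), the channel's values are scrambled
#' across test segments while all other channels stay intact, and the drop
#' in test accuracy relative to the unperturbed baseline is recorded:
#' positive importance means scrambling the channel hurts the model. By
#' default whole segments of the channel are shuffled between test segments
#' (preserving within-segment temporal structure); per-timestep scrambling
#' is available via `granularity = "timestep"`. The three acceleration axes
#' are additionally reported as one jointly scrambled "ACC" group, since the
#' model consumes seven channels but motor activity is one sensor.
#'
#' @param model A fitted `bilstm`.
#' @param x Test segments, n x 7 x w.
#' @param y Test labels.
#' @param repeats Permutations per channel (mean and SD reported).
#' @param granularity `"segment"` (default) or `"timestep"`.
#' @param groups Named list of channel groups to scramble jointly, in
#'   addition to the seven single channels. Default adds `ACC`.
#' @param seed Integer seed.
#' @return Object of class `importance_table`: data frame with channel,
#'   mean delta accuracy, SD, repeats; baseline accuracy in an attribute.
#' @export
permutation_importance <- function(model, x, y, repeats = 10,
                                   granularity = c("segment", "timestep"),
                                   groups = list(ACC = c("ACC_X", "ACC_Y", "ACC_Z")),
                                   seed = 1L) {
  granularity <- match.arg(granularity)
  y <- as.character(y)
  baseline <- mean(predict(model, x) == y)
  n <- dim(x)[1]; w <- dim(x)[3]
  units <- c(as.list(stats::setNames(E4_CHANNELS, E4_CHANNELS)), groups)
  bad <- setdiff(unlist(units), E4_CHANNELS)
  if (length(bad)) stop_mw("unknown channel '%s'", bad[1])
  rows <- with_seed(seed, {
    lapply(names(units), function(u) {
      chans <- match(units[[u]], E4_CHANNELS)
      deltas <- vapply(seq_len(repeats), function(r) {
        xp <- x
        if (granularity == "segment") {
          perm <- sample.int(n)
          xp[, chans, ] <- x[perm, chans, , drop = FALSE]
        } else {
          for (ch in chans) {
            flat <- as.vector(x[, ch, ])
            xp[, ch, ] <- array(flat[sample.int(length(flat))], dim = c(n, w))
          }
        }
        baseline - mean(predict(model, xp) == y)
      }, 0)
      data.frame(channel = u, delta_accuracy = mean(deltas),
                 sd = stats::sd(deltas), repeats = repeats)
    })
  })
  out <- do.call(rbind, rows)
  structure(out, baseline = baseline, seed = seed,
            class = c("importance_table", "data.frame"))
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("Permutation importance (baseline accuracy %.2f%%, %d repeats)\n",
              100 * attr(x, "baseline"), x$repeats[1]))
  df <- as.data.frame(x)
  df$delta_accuracy <- sprintf("%+.3f", df$delta_accuracy)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bar plot of permutation importances
#'
#' Bars show the change in accuracy upon scrambling each channel; positive
#' bars mean the channel matters.
#'
#' @param x An `importance_table`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.importance_table <- function(x, ...) {
  graphics::barplot(x$delta_accuracy, names.arg = x$channel, las = 2,
                    ylab = expression(Delta ~ "accuracy"),
                    col = ifelse(x$delta_accuracy >= 0, "steelblue", "firebrick"),
                    ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Kendall coefficient of concordance for channel rankings
#'
#' Agreement of m rankings of n objects (here: channel-importance rankings
#' across classification tasks), with the standard correction for ties:
#' W = 12 S / (m^2 (n^3 - n) - m T), where S is the sum of squared
#' deviations of rank sums and T the tie correction. W = 1 for identical
#' rankings, near 0 for independent ones.
#'
#' @param scores m x n matrix: one row per task, one column per channel.
#'   Rows are converted to ranks with average ranks for ties. Pass ranks
#'   directly with `ranked = TRUE`.
#' @param ranked Set `TRUE` if `scores` already holds ranks.
#' @return W in [0, 1].
#' @export
kendall_w <- function(scores, ranked = FALSE) {
  scores <- as.matrix(scores)
  m <- nrow(scores); n <- ncol(scores)
  if (m < 2) stop_mw("Kendall W needs at least 2 rankings (tasks)")
  if (n < 2) stop_mw("Kendall W needs at least 2 objects (channels)")
  ranks <- if (ranked) scores else t(apply(scores, 1, rank))
  R <- colSums(ranks)
  S <- sum((R - mean(R))^2)
  ties <- sum(apply(ranks, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }))
  denom <- m^2 * (n^3 - n) - m * ties
  if (denom <= 0) return(NA_real_)
  12 * S / denom
}

#' Channel-importance agreement across tasks
#'
#' Stacks the importance tables of several tasks (single channels only, not
#' grouped entries) and computes the Kendall W of the channel rankings
#' implied by their permutation importances.
#'
#' @param tables List of `importance_table` objects.
#' @return List with the m x 7 delta-accuracy matrix and `W`.
#' @export
importance_agreement <- function(tables) {
  mat <- t(vapply(tables, function(tb) {
    df <- as.data.frame(tb)
    df <- df[df$channel %in% E4_CHANNELS, ]
    stats::setNames(df$delta_accuracy, df$channel)[E4_CHANNELS]
  }, numeric(length(E4_CHANNELS))))
  colnames(mat) <- E4_CHANNELS
  list(deltas = mat, W = kendall_w(mat))
}
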