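# Shared fixtures, all generated in code.

# short clean session
tiny_session <- function(length_s = 120, label = "T0", seed = 1, ...) {
  generate_session(length_s = length_s, label = label, seed = seed, ...)
}

# a plan exercising every plantable rule
full_plan <- function(length_s = 200) {
  artifact_plan(rule_id = 1:4,
                start_second = c(20, 60, 100, 150),
                duration_seconds = c(5, 4, 8, 6))
}

# direct segment arrays (bypassing the generator) for fast classifier tests:
# K classes, one or more informative channels shifted per class
make_arrays <- function(n_per_class, w = 16, K = 3, channels = 5,
                        shift = 0.4, seed = 1, constant_channel = NULL) {
  set.seed(seed)
  n <- n_per_class * K
  x <- array(stats::runif(n * 7 * w), dim = c(n, 7, w),
             dimnames = list(NULL, E4_CHANNELS, NULL))
  y <- rep(paste0("C", seq_len(K)), each = n_per_class)
  for (k in seq_len(K)) {
    idx <- which(y == paste0("C", k))
    for (ch in channels) {
      x[idx, ch, ] <- x[idx, ch, ] + (k - (K + 1) / 2) * shift
    }
  }
  if (!is.null(constant_channel)) x[, constant_channel, ] <- 0.5
  perm <- sample.int(n)
  list(x = x[perm, , , drop = FALSE], y = y[perm])
}

# small trained model + held-out test arrays on a 3-class problem where only
# the EDA channel is informative; cached per test file
fit_small_model <- function(n_train = 45, n_test = 30, w = 12, shift = 0.8,
                            seed = 42, channels = which(E4_CHANNELS == "EDA"),
                            constant_channel = NULL) {
  tr <- make_arrays(n_train / 3 * 2, w, channels = channels, shift = shift,
                    seed = seed, constant_channel = constant_channel)
  va <- make_arrays(10, w, channels = channels, shift = shift,
                    seed = seed + 1, constant_channel = constant_channel)
  te <- make_arrays(n_test / 3, w, channels = channels, shift = shift,
                    seed = seed + 2, constant_channel = constant_channel)
  fit <- bilstm(tr$x, tr$y, validation = list(x = va$x, y = va$y),
                hidden_units = 16, max_epochs = 40, patience = 6,
                seed = seed)
  list(fit = fit, test = te)
}

# assemble an e4_cohort-shaped object from hand-built sessions
as_cohort <- function(sessions) {
  meta <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(subject_id = s$subject_id, session_id = s$session_id,
               label = s$label, time_point = s$time_point, role = "train",
               t(stats::setNames(s$ymrs, paste0("YMRS", 1:11))),
               t(stats::setNames(s$hdrs, paste0("HDRS", 1:17))))
  }))
  structure(list(sessions = stats::setNames(sessions,
                                            vapply(sessions, `[[`, "", "session_id")),
                 metadata = meta, config = NULL),
            class = "e4_cohort")
}
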