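#' Preprocess a set of sessions into labeled segments
#'
#' Runs the full preprocessing chain per session: quality-control filter,
#' alignment to the common time grid, and fixed-length windowing.
#'
#' @param sessions List of `e4_session` objects.
#' @param w Window length in time units.
#' @param mu Time unit in seconds.
#' @param config A [filter_config()].
#' @return List of segment arrays (one per session).
#' @export
preprocess_sessions <- function(sessions, w = 32, mu = 1,
                                config = filter_config()) {
  lapply(sessions, function(s) {
    mask <- apply_filter(s, config)
    segment_windows(align(s, mask, mu), w)
  })
}

task_sessions <- function(cohort, role, subject = NULL) {
  md <- cohort$metadata
  keep <- md$role == role
  if (!is.null(subject)) keep <- keep & md$subject_id == subject
  cohort$sessions[md$session_id[keep]]
}

fit_task_model <- function(seg_list, test_per_class, val_frac, seed, ...) {
  ds <- make_partitions(seg_list, test_per_class = test_per_class,
                        val_frac = val_frac, seed = derive_seed(seed, "partition"))
  tr <- partition_xy(ds, "train")
  va <- partition_xy(ds, "validation")
  model <- bilstm(tr$x, tr$y, validation = list(x = va$x, y = va$y),
                  seed = derive_seed(seed, "model"), ...)
  te <- partition_xy(ds, "test")
  list(dataset = ds, model = model,
       report = evaluate_model(model, te$x, te$y))
}

#' Intra-individual severity task: acute vs response vs remission
#'
#' Trains one model per subject on the 3-class task over that subject's
#' three consecutive sessions (T0 acute, T1 response, T2 remission), reports
#' balanced held-out test metrics, and optionally scores generalization on a
#' clinically matched unseen subject's sessions.
#'
#' @param cohort An `e4_cohort` from [generate_cohort()] or [read_cohort()].
#' @param subject Subject id to model; default: first training-role subject.
#' @param generalization_subject Held-out subject id, or `NULL` to use the
#'   first generalization-role subject (if any).
#' @param w,mu Window length and time unit (defaults 32 s and 1 s).
#' @param test_per_class,val_frac Partition parameters.
#' @param qc A [filter_config()].
#' @param seed Integer seed fanned out to partitioning/model/generalization.
#' @param ... Passed to [bilstm()] (hidden_units, max_epochs, ...).
#' @return Object of class `task_result`: `report`, `generalization` (or
#'   `NULL`), `model`, `dataset`, `task`, `subject`.
#' @export
run_severity_task <- function(cohort, subject = NULL,
                              generalization_subject = NULL,
                              w = 32, mu = 1, test_per_class = 20,
                              val_frac = 0.2, qc = filter_config(),
                              seed = 1L, ...) {
  md <- cohort$metadata
  subject <- subject %||% md$subject_id[md$role == "train"][1]
  sess <- task_sessions(cohort, "train", subject)
  tps <- vapply(sess, function(s) s$time_point, "")
  missing_tp <- setdiff(severity_labels(), tps)
  if (length(missing_tp)) {
    stop_mw("subject %s lacks time point %s", subject, missing_tp[1])
  }
  seg <- preprocess_sessions(sess, w, mu, qc)
  fit <- fit_task_model(seg, test_per_class, val_frac, seed, ...)
  gen_report <- NULL
  gen_ids <- unique(md$subject_id[md$role == "generalization"])
  generalization_subject <- generalization_subject %||%
    (if (length(gen_ids)) gen_ids[1] else NULL)
  if (!is.null(generalization_subject)) {
    gsess <- task_sessions(cohort, "generalization", generalization_subject)
    gseg <- preprocess_sessions(gsess, w, mu, qc)
    gset <- make_generalization_set(gseg, fit$dataset,
                                    seed = derive_seed(seed, "generalization"))
    gen_report <- evaluate_model(fit$model, gset$x, gset$y)
  }
  structure(c(fit, list(generalization = gen_report, task = "severity",
                        subject = subject, w = w, mu = mu, seed = seed)),
            class = "task_result")
}

#' Inter-individual polarity task: seven diagnosis/state classes
#'
#' Trains a single model across subjects on the 7-class task (manic BD,
#' depressed BD, mixed BD, depressed MDD, euthymic BD, euthymic MDD, healthy
#' controls) and optionally scores generalization on held-out subjects.
#'
#' @inheritParams run_severity_task
#' @return Object of class `task_result`.
#' @export
run_polarity_task <- function(cohort, w = 32, mu = 1, test_per_class = 20,
                              val_frac = 0.2, qc = filter_config(),
                              seed = 1L, ...) {
  md <- cohort$metadata
  sess <- task_sessions(cohort, "train")
  labs <- unique(vapply(sess, function(s) s$label, ""))
  missing_lb <- setdiff(polarity_labels(), labs)
  if (length(missing_lb) && all(labs %in% polarity_labels())) {
    stop_mw("label '%s' missing from the cohort", missing_lb[1])
  }
  seg <- preprocess_sessions(sess, w, mu, qc)
  fit <- fit_task_model(seg, test_per_class, val_frac, seed, ...)
  gen_report <- NULL
  if (any(md$role == "generalization")) {
    gsess <- task_sessions(cohort, "generalization")
    gseg <- preprocess_sessions(gsess, w, mu, qc)
    gset <- make_generalization_set(gseg, fit$dataset,
                                    seed = derive_seed(seed, "generalization"))
    gen_report <- evaluate_model(fit$model, gset$x, gset$y)
  }
  structure(c(fit, list(generalization = gen_report, task = "polarity",
                        subject = NA_character_, w = w, mu = mu, seed = seed)),
            class = "task_result")
}

#' Relabel a cohort by subject identity
#'
#' Turns any cohort into an identity task (e.g., distinguishing the healthy
#' controls from one another) by replacing each session's class label with
#' its subject id.
#'
#' @param cohort An `e4_cohort`.
#' @return The relabeled cohort.
#' @export
relabel_by_subject <- function(cohort) {
  for (i in seq_along(cohort$sessions)) {
    cohort$sessions[[i]]$label <- cohort$sessions[[i]]$subject_id
  }
  cohort$metadata$label <- cohort$metadata$subject_id
  cohort
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("Task '%s'%s (w = %d, mu = %g)\n", x$task,
              if (!is.na(x$subject)) paste0(", subject ", x$subject) else "",
              x$w, x$mu))
  cat("\nInternal test set:\n"); print(x$report)
  if (!is.null(x$generalization)) {
    cat("\nGeneralization (unseen subjects):\n"); print(x$generalization)
  }
  invisible(x)
}

#' Sweep window length (and time unit) against validation accuracy
#'
#' Re-runs preprocessing, partitioning and training for every combination of
#' `w_values` and `mu_values`, recording validation accuracy. Combinations
#' whose window exceeds any class's available contiguous data are skipped
#' with a warning.
#'
#' @param cohort An `e4_cohort`.
#' @param w_values Window lengths, a subset of 2^(0:11) seconds.
#' @param mu_values Time units in seconds.
#' @param task `"severity"` or `"polarity"`.
#' @param subject Severity-task subject.
#' @param seed Integer seed.
#' @param ... Passed to the task runner (e.g. `hidden_units`, `max_epochs`).
#' @return Data frame: mu, w, validation accuracy, test accuracy, seed;
#'   attribute `best` holds the best-performing row.
#' @export
sweep_window <- function(cohort, w_values = 2^(3:7), mu_values = 1,
                         task = c("severity", "polarity"), subject = NULL,
                         seed = 1L, ...) {
  task <- match.arg(task)
  bad_w <- setdiff(w_values, 2^(0:11))
  if (length(bad_w)) stop_mw("w = %s is not a power of 2 in [1, 2048]", bad_w[1])
  rows <- list()
  for (mu in mu_values) for (w in w_values) {
    res <- tryCatch({
      if (task == "severity") {
        run_severity_task(cohort, subject = subject, w = w, mu = mu,
                          seed = seed, ...)
      } else {
        run_polarity_task(cohort, w = w, mu = mu, seed = seed, ...)
      }
    }, error = function(e) {
      warning(sprintf("w = %d, mu = %g skipped: %s", w, mu, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    h <- res$model$history
    rows[[length(rows) + 1L]] <- data.frame(
      mu = mu, w = w,
      val_accuracy = h$val_accuracy[which.min(h$val_loss)],
      test_accuracy = res$report$accuracy, seed = seed)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out)) {
    attr(out, "best") <- out[which.max(out$val_accuracy), ]
  }
  out
}
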