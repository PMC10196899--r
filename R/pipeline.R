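#' Configuration for an end-to-end pipeline run
#'
#' @param input Either a [cohort_config()] (synthetic cohort generated at run
#'   time) or a directory of session archives written by [write_cohort()].
#' @param task `"severity"`, `"polarity"` or `"hc_identity"`.
#' @param qc A [filter_config()].
#' @param mu,w Time unit (s) and window length (time units).
#' @param test_per_class,val_frac Partition parameters.
#' @param model Named list of [bilstm()] arguments (hidden_units, ...).
#' @param analyses Character subset of `c("importance", "nmi", "sweep")`.
#' @param sweep_w Window lengths for the sweep analysis, if enabled.
#' @param seed Global seed; fanned out to each stochastic stage through a
#'   fixed derivation so stages can be re-run in isolation.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, task = c("severity", "polarity", "hc_identity"),
                       qc = filter_config(), mu = 1, w = 32,
                       test_per_class = 20, val_frac = 0.2,
                       model = list(), analyses = c("importance", "nmi"),
                       sweep_w = 2^(4:6), seed = 1L) {
  task <- match.arg(task)
  if (is.character(input) && !dir.exists(input)) {
    stop_mw("input directory '%s' does not exist", input)
  }
  structure(list(input = input, task = task, qc = qc, mu = mu, w = w,
                 test_per_class = test_per_class, val_frac = val_frac,
                 model = model, analyses = analyses, sweep_w = sweep_w,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(unclass(config)), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

#' Run the full pipeline from a single configuration
#'
#' Generates or ingests the cohort, applies the quality-control filter,
#' aligns and windows the recordings, trains and evaluates the classifier,
#' and runs the enabled analyses (permutation importance, channel-item NMI,
#' window sweep). Every output file is written under `out_dir` and listed
#' with a checksum in `manifest.json`; re-running an identical config
#' reproduces identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Object of class `pipeline_run`: the task result, analyses and
#'   manifest, invisibly. Artifacts on disk: `qc_<session>.tsv` masks,
#'   `drop_report.json`, `eval_report.json`, `generalization_report.json`,
#'   `importance.json`, `nmi_intra.tsv`/`nmi_between.tsv`, `sweep.tsv`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  result <- tryCatch({
    cohort <- if (inherits(config$input, "cohort_config")) {
      generate_cohort(config$input)
    } else {
      read_cohort(config$input)
    }
    if (config$task == "hc_identity") cohort <- relabel_by_subject(cohort)

    stage <- "qc"
    drops <- list()
    for (s in cohort$sessions) {
      mask <- apply_filter(s, config$qc)
      utils::write.table(mask_table(mask),
                         file.path(out_dir, paste0("qc_", s$session_id, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      dr <- drop_report(mask)
      drops[[s$session_id]] <- list(dropped_pct = dr$dropped_pct,
                                    per_rule = as.list(dr$per_rule))
    }
    jsonlite::write_json(drops, file.path(out_dir, "drop_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "model"
    runner_args <- c(list(cohort, w = config$w, mu = config$mu,
                          test_per_class = config$test_per_class,
                          val_frac = config$val_frac, qc = config$qc,
                          seed = config$seed), config$model)
    res <- if (config$task == "severity") {
      do.call(run_severity_task, runner_args)
    } else {
      do.call(run_polarity_task, runner_args)
    }
    jsonlite::write_json(report_to_list(res$report),
                         file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(res$generalization)) {
      jsonlite::write_json(report_to_list(res$generalization),
                           file.path(out_dir, "generalization_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    analyses <- list()
    if ("importance" %in% config$analyses) {
      stage <- "importance"
      te <- partition_xy(res$dataset, "test")
      imp <- permutation_importance(res$model, te$x, te$y,
                                    seed = derive_seed(config$seed, "importance"))
      analyses$importance <- imp
      jsonlite::write_json(
        c(list(baseline = attr(imp, "baseline")), as.list(as.data.frame(imp))),
        file.path(out_dir, "importance.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if ("nmi" %in% config$analyses && config$task != "hc_identity") {
      stage <- "nmi"
      level <- if (config$task == "severity") "intra" else "between"
      nmi <- nmi_table(cohort, level = level, w = config$w, mu = config$mu,
                       qc = config$qc)
      analyses$nmi <- nmi
      write_nmi_table(nmi, file.path(out_dir, paste0("nmi_", level, ".tsv")))
    }
    if ("sweep" %in% config$analyses) {
      stage <- "sweep"
      task_arg <- if (config$task == "severity") "severity" else "polarity"
      sw <- do.call(sweep_window,
                    c(list(cohort, w_values = config$sweep_w, mu_values = config$mu,
                           task = task_arg, seed = config$seed), config$model))
      analyses$sweep <- sw
      utils::write.table(sw, file.path(out_dir, "sweep.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    list(cohort = cohort, result = res, analyses = analyses)
  }, error = function(e) {
    stop_mw("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    config_hash = config_hash(config), seed = config$seed,
    task = config$task, w = config$w, mu = config$mu,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(c(result, list(manifest = manifest, out_dir = out_dir)),
                      class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run (%s) -> %s\n", x$manifest$task, x$out_dir))
  print(x$result)
  invisible(x)
}
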