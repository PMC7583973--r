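#' Write the run report
#'
#' Serializes the results of [run_af_pipeline()] into a deterministic JSON
#' report (per-method diagnostic blocks, confusion counts, interpretable-time
#' and activity blocks, seed and configuration echo) plus CSV side tables.
#' Identical inputs produce byte-identical files.
#'
#' @param run An `af_run` from [run_af_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path of the JSON report.
#' @export
run_report <- function(run, out_dir) {
  if (!inherits(run, "af_run")) {
    stop("run_report needs the result of run_af_pipeline(); got: ",
         paste(class(run), collapse = "/"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  block <- function(m) {
    if (is.null(m)) return(NULL)
    list(sensitivity = m$sensitivity, specificity = m$specificity,
         ppv = m$ppv, npv = m$npv, auc = m$auc,
         counts = m$counts[c("tp", "fp", "fn", "tn", "n")])
  }
  method_block <- function(strat) {
    if (is.null(strat)) return(NULL)
    list(pooled = block(strat$pooled), active = block(strat$active),
         resting = block(strat$resting), sizes = as.list(strat$sizes))
  }
  report <- list(
    seed = run$cohort_summary$seed,
    cohort = list(n_patients = run$cohort_summary$n_patients,
                  kinds = as.list(run$cohort_summary$kinds),
                  n_periods = run$cohort_summary$n_periods,
                  n_gated = run$cohort_summary$n_gated),
    interpretable_time = run$interpretable[c(
      "n", "n_meets_80", "pct_meets_80", "pooled_recording_h",
      "pooled_interpretable_h", "pooled_fraction_pct", "mean_fraction",
      "sd_fraction")],
    activity = list(active_fraction_pct = run$activity$active_fraction_pct),
    methods = list(
      nrmssd = list(threshold = run$calibration$threshold,
                    youden_j = run$calibration$youden_j,
                    test = method_block(run$nrmssd$test),
                    pooled = method_block(run$nrmssd$pooled)),
      knn = if (!is.null(run$mi)) method_block(run$mi$knn),
      dnn_head = if (!is.null(run$mi)) method_block(run$mi$head)
    ),
    probe_accuracy = if (!is.null(run$mi)) run$mi$probe$accuracy,
    crossvalidation = if (!is.null(run$cv)) {
      list(folds = run$cv$folds, mean = as.list(run$cv$mean),
           sd = as.list(run$cv$sd))
    }
  )
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  data.table::fwrite(run$interpretable_patients,
                     file.path(out_dir, "interpretable_time.csv"))
  invisible(path)
}

#' Check a run report against the shipped schema
#'
#' Verifies that a report JSON contains the required top-level blocks and
#' fields listed in the schema file shipped with the package
#' (`inst/extdata/report-schema.json`).
#'
#' @param path Path to a `report.json` written by [run_report()].
#' @return `TRUE` invisibly, or an error naming the missing fields.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "afwear")
  )
  rep <- jsonlite::read_json(path)
  missing <- setdiff(unlist(schema$required), names(rep))
  it_missing <- setdiff(unlist(schema$interpretable_time_required),
                        names(rep$interpretable_time))
  bad <- c(missing, if (length(it_missing)) paste0("interpretable_time.", it_missing))
  if (length(bad)) {
    stop("report is missing required fields: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
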