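#' Confusion counts over evaluated periods
#'
#' Standard 2x2 counts of predicted vs gold-standard AF over the evaluated
#' periods (pairs with `NA` in either vector are dropped, e.g. periods
#' excluded by the quality gate or a flutter-exclusion policy).
#'
#' @param pred Logical predictions.
#' @param truth Logical ground truth.
#' @return An object of class `af_confusion`: list `tp`, `fp`, `fn`, `tn`,
#'   `n`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth))
  ok <- !is.na(pred) & !is.na(truth)
  pred <- pred[ok]; truth <- truth[ok]
  structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                 fn = sum(!pred & truth), tn = sum(!pred & !truth),
                 n = length(pred)),
            class = "af_confusion")
}

#' @export
print.af_confusion <- function(x, ...) {
  cat(sprintf("af_confusion: tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' Diagnostic-accuracy metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, and (when continuous scores are supplied) the AUC of
#' the ROC. Ratios with a zero denominator are reported as `NA` (missing),
#' never as 0 or 1.
#'
#' @param counts An `af_confusion` from [confusion()].
#' @param scores Optional continuous scores for AUC.
#' @param truth Ground truth matching `scores` (required with `scores`).
#' @return An object of class `af_metrics`: list `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `auc`, `counts`.
#' @export
metrics_from_confusion <- function(counts, scores = NULL, truth = NULL) {
  stopifnot(inherits(counts, "af_confusion"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  auc <- NA_real_
  if (!is.null(scores)) {
    stopifnot(!is.null(truth))
    ok <- !is.na(scores) & !is.na(truth)
    if (sum(truth[ok]) > 0 && sum(!truth[ok]) > 0) {
      auc <- roc_curve(scores[ok], truth[ok])$auc
    }
  }
  structure(list(
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp),
    ppv = ratio(counts$tp, counts$tp + counts$fp),
    npv = ratio(counts$tn, counts$tn + counts$fn),
    auc = auc, counts = counts
  ), class = "af_metrics")
}

#' @export
print.af_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("af_metrics: Se %s, Sp %s, PPV %s, NPV %s, AUC %s (n=%d)\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc),
              x$counts$n))
  invisible(x)
}

#' One-call diagnostic metrics from prediction vectors
#'
#' @param pred Logical predictions.
#' @param truth Logical ground truth.
#' @param scores Optional continuous scores for AUC.
#' @return An `af_metrics`.
#' @export
diagnostic_metrics <- function(pred, truth, scores = NULL) {
  metrics_from_confusion(confusion(pred, truth), scores = scores,
                         truth = truth)
}

#' Activity-stratified diagnostic metrics
#'
#' Computes the metric suite separately on active and resting periods (the
#' two strata partition the evaluated periods) and on the pooled set.
#'
#' @param periods Period table with `active` and `af_positive` columns.
#' @param pred Logical predictions, parallel to the rows of `periods`.
#' @param scores Optional continuous scores for stratum AUCs.
#' @return List with `af_metrics` entries `pooled`, `active`, `resting`
#'   (empty strata yield `NULL` and are flagged in `sizes`) plus a `sizes`
#'   vector.
#' @export
stratify_by_activity <- function(periods, pred, scores = NULL) {
  stopifnot(is.data.frame(periods), nrow(periods) == length(pred),
            all(c("active", "af_positive") %in% names(periods)))
  strat <- function(mask) {
    if (!any(mask)) return(NULL)
    diagnostic_metrics(pred[mask], periods$af_positive[mask],
                       scores = if (!is.null(scores)) scores[mask])
  }
  list(pooled = strat(rep(TRUE, nrow(periods))),
       active = strat(periods$active),
       resting = strat(!periods$active),
       sizes = c(pooled = nrow(periods), active = sum(periods$active),
                 resting = sum(!periods$active)))
}

#' Cohort interpretable-time report
#'
#' Groups patients by whether their interpretable-time fraction meets the
#' 80% clinical-monitoring gate and summarizes recording and interpretable
#' hours, pooled and per group.
#'
#' @param summaries Per-patient table from [cohort_interpretable()] (columns
#'   `recording_h`, `interpretable_h`, `fraction`, `meets_80`).
#' @return List with cohort counts, pooled hours, the pooled interpretable
#'   fraction in percent, the mean/SD of per-patient fractions, and per-group
#'   (`below_80`, `meets_80`) statistics.
#' @export
cohort_interpretable_summary <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0,
            all(c("recording_h", "interpretable_h", "fraction", "meets_80")
                %in% names(summaries)))
  grp <- function(mask) {
    list(n = sum(mask),
         recording_h = sum(summaries$recording_h[mask]),
         interpretable_h = sum(summaries$interpretable_h[mask]),
         mean_fraction = if (any(mask)) mean(summaries$fraction[mask]) else NA_real_)
  }
  list(
    n = nrow(summaries),
    n_meets_80 = sum(summaries$meets_80),
    pct_meets_80 = 100 * mean(summaries$meets_80),
    pooled_recording_h = sum(summaries$recording_h),
    pooled_interpretable_h = sum(summaries$interpretable_h),
    pooled_fraction_pct = 100 * sum(summaries$interpretable_h) /
      sum(summaries$recording_h),
    mean_fraction = mean(summaries$fraction),
    sd_fraction = sd(summaries$fraction),
    groups = list(below_80 = grp(!summaries$meets_80),
                  meets_80 = grp(summaries$meets_80))
  )
}

#' Cohen's kappa inter-rater agreement
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' label sequences, with expected agreement `p_e` from the marginal label
#' frequencies; handles any number of categories and is symmetric in its
#' arguments.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return Kappa in `[-1, 1]` (1 for identical sequences; `NaN` if both
#'   raters are constant and identical-margin, where chance agreement is 1).
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  (p_o - p_e) / (1 - p_e)
}

#' Weighted mean of an integer score distribution
#'
#' Mean of a discrete score from its count distribution, e.g. the mean
#' CHA2DS2-VASc score of a cohort from the per-score patient counts.
#'
#' @param counts Non-negative counts per score class.
#' @param scores Score values; defaults to `0, 1, ...` matching `counts`.
#' @return `sum(scores * counts) / sum(counts)`.
#' @export
weighted_mean_score <- function(counts, scores = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(scores), all(counts >= 0))
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("weighted_mean_score needs a non-empty count distribution")
  }
  sum(scores * counts) / sum(counts)
}

#' Percentage rounding as printed in clinical tables
#'
#' Rounds to one decimal with halves away from zero (the convention of the
#' diagnostic tables this package reports against), e.g. `pct1(77.15)` is
#' 77.2.
#'
#' @param x Numeric vector (already on the percent scale).
#' @return `x` rounded to one decimal.
#' @export
pct1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10
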