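#' Root mean square of successive differences
#'
#' `rmssd()` is the classic short-term heart-rate-variability statistic
#' `sqrt(mean((IBI[i+1] - IBI[i])^2))` in ms; `nrmssd()` divides it by the
#' mean IBI of the same beats, giving a dimensionless irregularity score that
#' is invariant to rescaling all intervals (and hence to heart rate). High
#' values indicate the irregularly irregular ventricular response of AF.
#'
#' These take a plain numeric IBI vector assumed free of gaps; windowed
#' computation with gap/quality handling lives in [cohort_periods()].
#'
#' @param ibi_ms Numeric vector of at least two inter-beat intervals (ms).
#' @return `rmssd()`: ms; `nrmssd()`: dimensionless.
#' @examples
#' rmssd(c(600, 800, 600, 800))   # 200
#' nrmssd(c(600, 800, 600, 800))  # 200/700
#' @export
rmssd <- function(ibi_ms) {
  if (!is.numeric(ibi_ms) || length(ibi_ms) < 2) {
    stop("rmssd needs at least 2 IBIs")
  }
  sqrt(mean(diff(ibi_ms)^2))
}

#' @rdname rmssd
#' @export
nrmssd <- function(ibi_ms) {
  rmssd(ibi_ms) / mean(ibi_ms)
}

#' Recruitment-ordered patient split
#'
#' Splits a cohort into a training cohort holding the first
#' `ceiling(train_fraction * n)` recruited patients and a testing cohort
#' holding the rest. The split is patient-disjoint by construction: every
#' five-minute period of a patient falls on one side only.
#'
#' @param x An `af_cohort` or a manifest data.frame with `patient_id` and
#'   `recruitment_index` columns.
#' @param train_fraction Fraction of patients in the training cohort.
#' @return A list with character vectors `train` and `test` of patient ids.
#' @export
split_by_recruitment <- function(x, train_fraction = 0.8) {
  manifest <- if (inherits(x, "af_cohort")) cohort_manifest(x) else x
  stopifnot(is.data.frame(manifest),
            all(c("patient_id", "recruitment_index") %in% names(manifest)),
            train_fraction > 0, train_fraction <= 1,
            !anyDuplicated(manifest$recruitment_index))
  ids <- manifest$patient_id[order(manifest$recruitment_index)]
  n_train <- ceiling(train_fraction * length(ids))
  list(train = ids[seq_len(n_train)],
       test = if (n_train < length(ids)) ids[(n_train + 1):length(ids)] else character(0))
}

#' Receiver operating characteristic curve
#'
#' Builds the ROC of a continuous score against binary truth under the
#' convention "predict positive when `score >= threshold`". One operating
#' point is produced per unique score (ties grouped), preceded by the
#' all-negative point at threshold `Inf`. AUC is computed by the trapezoidal
#' rule, which equals the Mann-Whitney U statistic scaled by `n1 * n0`.
#'
#' @param scores Numeric scores (higher = more AF-like); `NA` pairs dropped.
#' @param labels Logical (or 0/1) ground truth.
#' @return An object of class `af_roc`: list with `thresholds` (descending),
#'   `tpr`, `fpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_curve needs both positive and negative labels")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(cumsum(y), grp, max)
  fp <- tapply(cumsum(!y), grp, max)
  thresholds <- s[!duplicated(s)]
  tpr <- as.numeric(tp) / n_pos
  fpr <- as.numeric(fp) / n_neg
  fx <- c(0, fpr); fy <- c(0, tpr)
  auc <- sum(diff(fx) * (head(fy, -1) + tail(fy, -1)) / 2)
  structure(list(thresholds = c(Inf, thresholds), tpr = fy, fpr = fx,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "af_roc")
}

#' @export
print.af_roc <- function(x, ...) {
  cat(sprintf("af_roc: %d thresholds, AUC = %.4f (%d pos / %d neg)\n",
              length(x$thresholds) - 1L, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden's J operating point
#'
#' Picks the score threshold maximizing Youden's J = sensitivity +
#' specificity - 1 = TPR - FPR over the finite ROC thresholds. Ties are
#' broken toward the higher threshold, favouring specificity.
#'
#' @param roc An `af_roc` from [roc_curve()].
#' @return A list (`threshold`, `youden_j`, `sensitivity`, `specificity`).
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "af_roc"))
  finite <- is.finite(roc$thresholds)
  j <- roc$tpr[finite] - roc$fpr[finite]
  best <- which.max(j)  # thresholds descending => first max = highest threshold
  list(threshold = roc$thresholds[finite][best], youden_j = j[best],
       sensitivity = roc$tpr[finite][best],
       specificity = 1 - roc$fpr[finite][best])
}

#' Calibrate the nRMSSD decision threshold on the training cohort
#'
#' Pools all gated five-minute periods of the training patients, builds the
#' ROC of nRMSSD against the gold-standard AF label and selects the Youden-J
#' operating point. One pooled threshold is learned (not per patient) and
#' later applied unchanged to the testing cohort.
#'
#' @param periods Period table from [cohort_periods()] (gated, i.e. after
#'   [filter_interpretable()]); rows with `NA` nRMSSD or `NA` truth are
#'   dropped.
#' @param train_ids Patient ids of the training cohort, e.g. from
#'   [split_by_recruitment()].
#' @return An object of class `af_calibration`: list with `threshold`,
#'   `youden_j`, `train_patient_ids`, `n_train_periods` and the training
#'   `roc`.
#' @export
calibrate_nrmssd <- function(periods, train_ids) {
  stopifnot(is.data.frame(periods),
            all(c("patient_id", "nrmssd", "af_positive") %in% names(periods)))
  tr <- periods[periods$patient_id %in% train_ids &
                  !is.na(periods$nrmssd) & !is.na(periods$af_positive), ]
  if (nrow(tr) == 0) stop("no usable training periods")
  roc <- roc_curve(tr$nrmssd, tr$af_positive)
  yj <- youden_threshold(roc)
  structure(list(threshold = yj$threshold, youden_j = yj$youden_j,
                 train_patient_ids = sort(unique(tr$patient_id)),
                 n_train_periods = nrow(tr), roc = roc),
            class = "af_calibration")
}

#' @export
print.af_calibration <- function(x, ...) {
  cat(sprintf(
    "af_calibration: nRMSSD threshold %.4f (Youden J %.3f, %d periods, %d patients)\n",
    x$threshold, x$youden_j, x$n_train_periods, length(x$train_patient_ids)))
  invisible(x)
}

#' Classify periods by the nRMSSD threshold
#'
#' Predicts AF for a period when its nRMSSD is at or above the calibrated
#' threshold (the boundary score counts as positive).
#'
#' @param scores Numeric nRMSSD values (or a period table with an `nrmssd`
#'   column).
#' @param threshold Decision threshold, or an `af_calibration`.
#' @return Logical predictions (`NA` where the score is `NA`).
#' @export
classify_nrmssd <- function(scores, threshold) {
  if (is.data.frame(scores)) scores <- scores$nrmssd
  if (inherits(threshold, "af_calibration")) threshold <- threshold$threshold
  stopifnot(is.numeric(scores), is.numeric(threshold), length(threshold) == 1)
  scores >= threshold
}
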