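#' Segment an IBI stream into successive five-minute periods
#'
#' Splits a recording into non-overlapping half-open windows
#' `[300k, 300(k+1))` anchored at recording start. A beat belongs to the
#' window containing its timestamp; the trailing partial window is discarded.
#'
#' @param x An `af_patient` record, or a data.frame of beats with columns
#'   `t_s`, `ibi_ms` (and optionally `quality`, `activity`).
#' @param duration_s Recording length; required when `x` is a plain
#'   data.frame.
#'
#' @return A data.frame with one row per period (`patient_id`,
#'   `window_start_s`, `n_beats`) and a list column `beats` holding each
#'   window's beat rows. Windows without any beat are kept (empty `beats`).
#' @export
segment_periods <- function(x, duration_s = NULL) {
  if (inherits(x, "af_patient")) {
    samples <- x$samples
    duration_s <- x$duration_s
    pid <- x$patient_id
  } else {
    samples <- x
    pid <- attr(x, "patient_id") %||% "patient"
    if (is.null(duration_s)) stop("duration_s is required for plain beat tables")
  }
  stopifnot(is.data.frame(samples), nrow(samples) > 0 || duration_s >= 0)
  k_max <- floor(duration_s / 300)
  if (k_max < 1) {
    return(data.frame(patient_id = character(0), window_start_s = numeric(0),
                      n_beats = integer(0)))
  }
  win <- floor(samples$t_s / 300)
  keep <- win < k_max & win >= 0
  idx <- split(which(keep), factor(win[keep], levels = 0:(k_max - 1)))
  out <- data.frame(patient_id = pid,
                    window_start_s = 300 * (0:(k_max - 1)),
                    n_beats = vapply(idx, length, 0L))
  out$beats <- lapply(idx, function(i) samples[i, , drop = FALSE])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Valid-IBI coverage of a five-minute period
#'
#' Coverage is the fraction of the 300 s window spanned by IBIs of retained
#' quality (`quality > 0`): `sum(ibi_ms/1000 over valid beats) / 300`, capped
#' at 1. Applied to a period table, returns one value per row.
#'
#' @param x A beats data.frame (columns `ibi_ms` and optionally `quality`;
#'   missing `quality` counts every beat as valid), or a period table from
#'   [segment_periods()].
#' @return Coverage fraction(s) in `[0, 1]`.
#' @export
compute_coverage <- function(x) {
  if (is.data.frame(x) && !is.null(x$beats)) {
    return(unname(vapply(x$beats, compute_coverage, 0)))
  }
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) return(0)
  q <- x$quality %||% rep(1L, nrow(x))
  min(1, sum(x$ibi_ms[q > 0]) / 1000 / 300)
}

#' Quality gate on five-minute periods
#'
#' Keeps periods whose valid-IBI coverage meets the analyzable-data cut-off
#' (80% by default); order is preserved and the boundary is inclusive.
#'
#' @param periods A period table with a `coverage` column (or with a `beats`
#'   list column, in which case coverage is computed on the fly).
#' @param min_coverage Gate threshold in `[0, 1]`.
#' @return The kept rows of `periods`.
#' @export
filter_interpretable <- function(periods, min_coverage = 0.8) {
  stopifnot(is.data.frame(periods), min_coverage >= 0, min_coverage <= 1)
  if (nrow(periods) == 0) return(periods)
  cov <- periods$coverage %||% compute_coverage(periods)
  periods[cov >= min_coverage, , drop = FALSE]
}

#' Interpretable-time summary for one recording
#'
#' Interpretable time is the total duration of five-minute periods passing
#' the quality gate; the fraction is taken relative to the full recording
#' length. A patient "meets the 80% gate" when that fraction is at least 0.8.
#'
#' @param x An `af_patient`, or the recording duration in seconds.
#' @param periods_kept Gated period table from [filter_interpretable()], or
#'   directly the number of kept periods.
#' @return A one-row data.frame (`patient_id`, `recording_h`,
#'   `interpretable_h`, `fraction`, `meets_80`).
#' @export
interpretable_time <- function(x, periods_kept) {
  if (inherits(x, "af_patient")) {
    duration_s <- x$duration_s
    pid <- x$patient_id
  } else {
    duration_s <- x
    pid <- "patient"
  }
  n_kept <- if (is.data.frame(periods_kept)) nrow(periods_kept) else periods_kept
  stopifnot(duration_s > 0, n_kept >= 0,
            n_kept <= floor(duration_s / 300))
  recording_h <- duration_s / 3600
  interpretable_h <- n_kept * 300 / 3600
  fraction <- interpretable_h / recording_h
  data.frame(patient_id = pid, recording_h = recording_h,
             interpretable_h = interpretable_h, fraction = fraction,
             meets_80 = fraction >= 0.8)
}

#' Activity label of five-minute periods
#'
#' A period is ACTIVE when any overlapping activity block (or any beat in the
#' window) is non-resting.
#'
#' @param window_start_s Vector of window starts (seconds).
#' @param profile Activity profile from [generate_activity_profile()].
#' @return Logical vector, `TRUE` for active periods.
#' @export
label_period_activity <- function(window_start_s, profile) {
  stopifnot(is.data.frame(profile))
  vapply(window_start_s, function(s) {
    idx <- which(profile$block_start_s < s + 300 &
                   profile$block_start_s + 300 > s)
    length(idx) > 0 && any(profile$active[idx])
  }, TRUE)
}

#' Ground-truth rhythm label of five-minute periods
#'
#' Assigns each window the rhythm occupying the majority of its time under
#' the gold-standard timeline. Exact ties go to the non-AF rhythm
#' (preference SINUS, then FLUTTER, then AF), a deliberately conservative
#' tie-break. `af_positive` is `TRUE` for AF-labelled windows; under
#' `flutter_policy = "exclude"` flutter-labelled windows get `NA` (dropped
#' from the AF-detection denominator), under the default `"non_af"` they
#' count as negatives.
#'
#' @param window_start_s Vector of window starts (seconds).
#' @param timeline Rhythm timeline data.frame (`start_s`, `end_s`, `rhythm`).
#' @param flutter_policy `"non_af"` (default) or `"exclude"`.
#' @return A data.frame (`rhythm_label`, `af_positive`).
#' @export
label_period_rhythm <- function(window_start_s, timeline,
                                flutter_policy = c("non_af", "exclude")) {
  flutter_policy <- match.arg(flutter_policy)
  stopifnot(is.data.frame(timeline), nrow(timeline) > 0)
  n <- length(window_start_s)
  # overlap of each window with each rhythm; column order encodes the
  # tie-break preference (non-AF first)
  lev <- c("SINUS", "FLUTTER", "AF")
  ov <- matrix(0, n, 3, dimnames = list(NULL, lev))
  for (k in seq_len(nrow(timeline))) {
    r <- as.character(timeline$rhythm[k])
    add <- pmax(0, pmin(timeline$end_s[k], window_start_s + 300) -
                  pmax(timeline$start_s[k], window_start_s))
    ov[, r] <- ov[, r] + add
  }
  if (any(rowSums(ov) < 300 - 1e-6)) {
    stop("window extends outside the rhythm timeline")
  }
  label <- lev[max.col(ov, ties.method = "first")]
  af_positive <- label == "AF"
  if (flutter_policy == "exclude") af_positive[label == "FLUTTER"] <- NA
  data.frame(rhythm_label = label, af_positive = af_positive)
}

#' Hourly activity index
#'
#' Percentage of five-minute blocks labelled ACTIVE within each hour of
#' recording (hours anchored at recording start; a trailing partial hour is
#' summarized over its available blocks).
#'
#' @param profile Activity profile from [generate_activity_profile()], or a
#'   pooled data.frame of several profiles stacked together.
#' @return A data.frame (`hour`, `active_pct`).
#' @export
activity_index_hourly <- function(profile) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0)
  hr <- floor(profile$block_start_s / 3600)
  agg <- tapply(profile$active, hr, function(a) 100 * mean(a))
  data.frame(hour = as.integer(names(agg)), active_pct = as.numeric(agg),
             row.names = NULL)
}

# per-window features honouring the pair-break rule (internal)
window_feats <- function(t_s, ibi_ms, quality) {
  valid <- quality > 0L
  cov <- min(1, sum(ibi_ms[valid]) / 1000 / 300)
  n <- length(t_s)
  if (n < 2L || sum(valid) < 2L) {
    return(list(coverage = cov, nrmssd = NA_real_, n_valid = sum(valid)))
  }
  contig <- abs(diff(t_s) - ibi_ms[-1L] / 1000) < 1e-6
  pair <- valid[-n] & valid[-1L] & contig
  if (!any(pair)) {
    return(list(coverage = cov, nrmssd = NA_real_, n_valid = sum(valid)))
  }
  d <- (ibi_ms[-1L] - ibi_ms[-n])[pair]
  member <- unique(c(which(pair), which(pair) + 1L))
  list(coverage = cov,
       nrmssd = sqrt(mean(d^2)) / mean(ibi_ms[member]),
       n_valid = sum(valid))
}

#' Build the full period table for a cohort
#'
#' Runs windowing, coverage, nRMSSD, activity and rhythm labelling for every
#' patient and stacks the result. nRMSSD successive differences are taken
#' only across beats that are retained (`quality > 0`) and time-contiguous
#' (no dropout gap or excluded beat between them).
#'
#' @param cohort An `af_cohort`.
#' @param min_coverage Optional gate; when given, only periods with
#'   `coverage >= min_coverage` are returned.
#' @param flutter_policy Passed to [label_period_rhythm()].
#' @return A data.frame with columns `patient_id`, `window_start_s`,
#'   `coverage`, `n_valid`, `nrmssd`, `active`, `rhythm_label`,
#'   `af_positive`.
#' @export
cohort_periods <- function(cohort, min_coverage = NULL,
                           flutter_policy = c("non_af", "exclude")) {
  stopifnot(inherits(cohort, "af_cohort"))
  flutter_policy <- match.arg(flutter_policy)
  per_patient <- lapply(cohort, function(p) {
    k_max <- floor(p$duration_s / 300)
    if (k_max < 1) return(NULL)
    starts <- 300 * (0:(k_max - 1))
    dt <- data.table::as.data.table(p$samples)
    dt[, win := floor(t_s / 300)]
    dt <- dt[win >= 0 & win < k_max]
    feat <- dt[, window_feats(t_s, ibi_ms, quality), by = win]
    full <- data.table::data.table(win = 0:(k_max - 1))
    feat <- feat[full, on = "win"]
    feat[is.na(coverage), `:=`(coverage = 0, n_valid = 0L)]
    active <- if (!is.null(p$profile)) {
      label_period_activity(starts, p$profile)
    } else {
      av <- dt[, any(activity == "ACTIVE"), by = win]
      out <- rep(FALSE, k_max)
      out[av$win + 1L] <- av$V1
      out
    }
    rl <- label_period_rhythm(starts, p$timeline, flutter_policy)
    data.frame(patient_id = p$patient_id, window_start_s = starts,
               coverage = feat$coverage, n_valid = feat$n_valid,
               nrmssd = feat$nrmssd, active = active,
               rhythm_label = rl$rhythm_label, af_positive = rl$af_positive)
  })
  out <- do.call(rbind, per_patient)
  rownames(out) <- NULL
  if (!is.null(min_coverage)) out <- filter_interpretable(out, min_coverage)
  out
}

#' Per-patient interpretable-time table for a cohort
#'
#' @param cohort An `af_cohort`.
#' @param min_coverage Quality-gate threshold for counting a period as
#'   interpretable.
#' @return A data.frame with one [interpretable_time()] row per patient.
#' @export
cohort_interpretable <- function(cohort, min_coverage = 0.8) {
  periods <- cohort_periods(cohort)
  do.call(rbind, lapply(cohort, function(p) {
    pp <- periods[periods$patient_id == p$patient_id, ]
    interpretable_time(p, sum(pp$coverage >= min_coverage))
  }))
}
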