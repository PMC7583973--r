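#' Run the full AF-detection analysis on a synthetic cohort
#'
#' End-to-end driver: generates a cohort, windows it into five-minute
#' periods, applies the 80% quality gate and interpretable-time accounting,
#' calibrates the nRMSSD threshold by Youden's J on the recruitment-ordered
#' training cohort and evaluates it on the testing cohort (overall and
#' stratified by physical activity), then — unless `mi = FALSE` — trains the
#' unsupervised mutual-information encoder, classifies test periods by
#' one-nearest neighbour in latent space, fits the supervised head, and runs
#' a linear-probe evaluation. All randomness derives from `config$seed`.
#'
#' @param config Cohort configuration ([sim_config()]).
#' @param min_coverage Quality-gate threshold on period coverage.
#' @param flutter_policy How flutter periods enter the AF denominator
#'   (see [label_period_rhythm()]).
#' @param train_fraction Recruitment-ordered training fraction for the
#'   nRMSSD calibration.
#' @param mi Run the representation-learning arm?
#' @param mi_cfg Encoder configuration ([mi_config()]).
#' @param mi_max_train Cap on balanced encoder-training periods.
#' @param cv_folds If > 0, additionally run this many folds of
#'   cross-validation of the 1-NN pipeline (encoder refit per fold).
#' @param cv_max_periods Cap on periods entering cross-validation.
#' @return A list of class `af_run` with elements `cohort_summary`,
#'   `interpretable`, `activity`, `calibration`, `nrmssd` (test-cohort and
#'   pooled metrics), and when requested `mi` (knn/head/probe results) and
#'   `cv`.
#' @export
run_af_pipeline <- function(config = sim_config(), min_coverage = 0.8,
                            flutter_policy = c("non_af", "exclude"),
                            train_fraction = 0.8, mi = TRUE,
                            mi_cfg = mi_config(seed = config$seed),
                            mi_max_train = 2500L, cv_folds = 0L,
                            cv_max_periods = 4000L) {
  flutter_policy <- match.arg(flutter_policy)
  cohort <- generate_cohort(config)
  manifest <- cohort_manifest(cohort)
  periods <- cohort_periods(cohort, flutter_policy = flutter_policy)

  # interpretable time, per patient and pooled
  summaries <- do.call(rbind, lapply(cohort, function(p) {
    pp <- periods[periods$patient_id == p$patient_id, ]
    interpretable_time(p, sum(pp$coverage >= min_coverage))
  }))
  interp <- cohort_interpretable_summary(summaries)

  # pooled activity profile
  profiles <- do.call(rbind, lapply(cohort, `[[`, "profile"))
  activity <- list(active_fraction_pct = 100 * mean(profiles$active),
                   hourly = activity_index_hourly(profiles))

  gated <- filter_interpretable(periods, min_coverage)
  usable <- gated[!is.na(gated$nrmssd) & !is.na(gated$af_positive), ]

  split <- split_by_recruitment(manifest, train_fraction)
  calib <- calibrate_nrmssd(usable, split$train)
  test_p <- usable[usable$patient_id %in% split$test, ]
  pred_test <- classify_nrmssd(test_p, calib)
  pred_all <- classify_nrmssd(usable, calib)
  nrmssd_res <- list(
    test = stratify_by_activity(test_p, pred_test, scores = test_p$nrmssd),
    pooled = stratify_by_activity(usable, pred_all, scores = usable$nrmssd)
  )

  out <- list(
    cohort_summary = list(
      n_patients = nrow(manifest), kinds = table(manifest$kind),
      n_periods = nrow(periods), n_gated = nrow(gated),
      n_usable = nrow(usable), seed = config$seed
    ),
    interpretable = interp, interpretable_patients = summaries,
    activity = activity, calibration = calib, split = split,
    nrmssd = nrmssd_res
  )

  if (mi) {
    eligible <- usable[usable$n_valid >= 2L * mi_cfg$min_half, ]
    sp <- random_split(nrow(eligible))
    bal <- oversample_balance(eligible$af_positive[sp$train])
    if (length(bal) > mi_max_train) bal <- sample(bal, mi_max_train)
    tr_rows <- sp$train[bal]
    need <- eligible[c(tr_rows, sp$test), ]
    seqs <- period_sequences(cohort, need)
    n_tr <- length(tr_rows)
    train_seqs <- seqs[seq_len(n_tr)]
    test_seqs <- seqs[n_tr + seq_along(sp$test)]
    test_rows <- eligible[sp$test, ]

    encoder <- train_encoder(train_seqs, mi_cfg)
    ztr <- embed_periods(encoder, train_seqs)
    zte <- embed_periods(encoder, test_seqs)
    ytr <- eligible$af_positive[tr_rows]

    knn <- knn_classify(zte, ztr, ytr, k = 1L)
    head_fit <- train_classifier_head(ztr, ytr, seed = mi_cfg$seed)
    prob <- predict_head(head_fit, zte)
    probe <- linear_probe(zte, test_rows$af_positive)

    out$mi <- list(
      encoder = encoder,
      knn = stratify_by_activity(test_rows, knn$pred, scores = knn$score),
      head = stratify_by_activity(test_rows, prob >= 0.5, scores = prob),
      probe = probe,
      n_train = n_tr, n_test = nrow(test_rows)
    )

    if (cv_folds > 0) {
      cv_rows <- if (nrow(eligible) > cv_max_periods) {
        sort(sample.int(nrow(eligible), cv_max_periods))
      } else {
        seq_len(nrow(eligible))
      }
      cv_seqs <- period_sequences(cohort, eligible[cv_rows, ])
      out$cv <- crossvalidate(
        cv_seqs, eligible$af_positive[cv_rows],
        mi_cv_pipeline(mi_cfg, mode = "knn", max_train = mi_max_train),
        folds = cv_folds
      )
    }
  }
  class(out) <- "af_run"
  out
}

#' @export
print.af_run <- function(x, ...) {
  cat(sprintf("af_run: %d patients, %d gated periods\n",
              x$cohort_summary$n_patients, x$cohort_summary$n_gated))
  cat(sprintf("  interpretable time: %.1f%% pooled (%.1f%% of patients >= 80%%)\n",
              x$interpretable$pooled_fraction_pct, x$interpretable$pct_meets_80))
  cat(sprintf("  nRMSSD threshold %.4f | test cohort: ", x$calibration$threshold))
  print(x$nrmssd$test$pooled)
  if (!is.null(x$mi)) {
    cat("  1-NN latent (test split): ")
    print(x$mi$knn$pooled)
    cat(sprintf("  linear probe accuracy: %.3f\n", x$mi$probe$accuracy))
  }
  invisible(x)
}
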