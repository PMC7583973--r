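#' Ten-fold cross-validation of a period classifier
#'
#' Partitions the periods into `folds` random folds, fits the supplied
#' pipeline on each training complement and evaluates on the held-out fold,
#' reporting the diagnostic-metric suite per fold with mean and SD across
#' folds.
#'
#' @param x Period-level inputs: a list (e.g. beat sequences) or a matrix /
#'   data.frame with one row per period.
#' @param labels Logical AF labels per period.
#' @param fit_predict Function `(train_x, train_y, test_x) -> list(pred,
#'   score)`; `score` may be `NULL`.
#' @param folds Number of folds.
#' @return An object of class `af_cv`: list with `fold_metrics` (data.frame,
#'   one row per fold), `mean` and `sd` (named metric vectors), `folds`.
#' @export
crossvalidate <- function(x, labels, fit_predict, folds = 10L) {
  labels <- as.logical(labels)
  n <- if (is.matrix(x) || is.data.frame(x)) nrow(x) else length(x)
  stopifnot(n == length(labels), folds >= 2, n >= folds)
  take <- function(obj, idx) {
    if (is.matrix(obj) || is.data.frame(obj)) obj[idx, , drop = FALSE]
    else obj[idx]
  }
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    res <- fit_predict(take(x, tr), labels[tr], take(x, te))
    m <- diagnostic_metrics(res$pred, labels[te], scores = res$score)
    rows[[f]] <- data.frame(fold = f, n_test = length(te),
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            ppv = m$ppv, npv = m$npv, auc = m$auc)
  }
  fm <- do.call(rbind, rows)
  metric_cols <- c("sensitivity", "specificity", "ppv", "npv", "auc")
  structure(list(
    fold_metrics = fm,
    mean = colMeans(fm[metric_cols], na.rm = TRUE),
    sd = vapply(fm[metric_cols], sd, 0, na.rm = TRUE),
    folds = folds
  ), class = "af_cv")
}

#' @export
print.af_cv <- function(x, ...) {
  cat(sprintf("af_cv: %d folds\n", x$folds))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  }
  invisible(x)
}

#' Cross-validation pipelines for the MI representation
#'
#' Builds `fit_predict` functions for [crossvalidate()] that mirror the two
#' evaluation modes of the representation learner: `"knn"` (1-nearest
#' neighbour in latent space) and `"head"` (supervised classifier head on
#' frozen features). With `refit_encoder = TRUE` (default) the unsupervised
#' encoder is re-trained inside every fold on that fold's training periods;
#' otherwise a pre-trained `encoder` embeds all periods. Training partitions
#' are oversampled to class balance; evaluation uses the unbalanced fold.
#'
#' @param mi_cfg Encoder configuration ([mi_config()]); used when refitting.
#' @param mode `"knn"` or `"head"`.
#' @param refit_encoder Re-train the encoder per fold?
#' @param encoder Pre-trained encoder (required when `refit_encoder = FALSE`).
#' @param max_train Cap on (balanced) training periods per fold, a
#'   computation knob.
#' @return A `fit_predict` function over lists of period beat sequences.
#' @export
mi_cv_pipeline <- function(mi_cfg = mi_config(), mode = c("knn", "head"),
                           refit_encoder = TRUE, encoder = NULL,
                           max_train = 1000L) {
  mode <- match.arg(mode)
  if (!refit_encoder && is.null(encoder)) {
    stop("a pre-trained encoder is required when refit_encoder = FALSE")
  }
  function(train_x, train_y, test_x) {
    bal <- oversample_balance(train_y)
    if (length(bal) > max_train) bal <- sample(bal, max_train)
    enc <- if (refit_encoder) train_encoder(train_x[bal], mi_cfg) else encoder
    ztr <- embed_periods(enc, train_x[bal])
    zte <- embed_periods(enc, test_x)
    if (mode == "knn") {
      knn_classify(zte, ztr, train_y[bal], k = 1L)
    } else {
      head_fit <- train_classifier_head(ztr, train_y[bal], seed = mi_cfg$seed)
      prob <- predict_head(head_fit, zte)
      list(pred = prob >= 0.5, score = prob)
    }
  }
}
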