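#' Oversample the minority class to balance a training set
#'
#' Replicates randomly selected minority-class items (sampling with
#' replacement) until both classes have equal counts. Meant for training
#' partitions only; evaluation always uses the unbalanced original data.
#'
#' @param labels Logical class labels.
#' @return Integer indices into `labels` (original order first, then the
#'   replicated minority draws); subset your data with them.
#' @export
oversample_balance <- function(labels) {
  labels <- as.logical(labels)
  stopifnot(!anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == n_neg) return(seq_along(labels))
  minority <- which(labels == (n_pos < n_neg))
  extra <- sample(minority, abs(n_pos - n_neg), replace = TRUE)
  c(seq_along(labels), extra)
}

#' Random train/validation/test split of periods
#'
#' Period-level random split (data-level, not patient-level) into
#' train/validation/test partitions; the test partition keeps the original
#' class ratio in expectation since assignment ignores labels. Set
#' `by_patient` to a vector of patient ids for a leakage-aware patient-level
#' split instead (all periods of a patient land in one partition).
#'
#' @param n Number of periods (or a period table, in which case its row count
#'   is used).
#' @param fractions Length-3 fractions for train/validation/test; must sum
#'   to 1.
#' @param by_patient Optional patient id per period for patient-level
#'   splitting (default off).
#' @return List of integer index vectors `train`, `val`, `test` — disjoint
#'   and exhaustive.
#' @export
random_split <- function(n, fractions = c(0.8, 0.1, 0.1), by_patient = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, n >= 3)
  if (is.null(by_patient)) {
    perm <- sample.int(n)
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    list(train = sort(perm[seq_len(n_tr)]),
         val = sort(perm[n_tr + seq_len(n_va)]),
         test = sort(perm[(n_tr + n_va + 1):n]))
  } else {
    stopifnot(length(by_patient) == n)
    ids <- sample(unique(by_patient))
    n_tr <- floor(fractions[1] * length(ids))
    n_va <- floor(fractions[2] * length(ids))
    grp <- rep("test", length(ids))
    grp[seq_len(n_tr)] <- "train"
    grp[n_tr + seq_len(n_va)] <- "val"
    assign <- stats::setNames(grp, ids)[as.character(by_patient)]
    list(train = which(assign == "train"), val = which(assign == "val"),
         test = which(assign == "test"))
  }
}

#' k-nearest-neighbour classification in latent space
#'
#' Labels each query embedding with the majority label of its `k` nearest
#' labelled reference embeddings under Euclidean distance (`k = 1` by
#' default, as used for unsupervised classification of periods). Also
#' returns a continuous distance-margin score — nearest non-AF distance minus
#' nearest AF distance — usable for ROC analysis, since hard 1-NN labels
#' carry no ranking.
#'
#' @param query Numeric matrix `m x D` of query embeddings.
#' @param reference Numeric matrix `n x D` of labelled reference embeddings.
#' @param ref_labels Logical AF labels of the reference rows.
#' @param k Number of neighbours (odd).
#' @return List with `pred` (logical length m) and `score` (numeric; higher
#'   means more AF-like).
#' @export
knn_classify <- function(query, reference, ref_labels, k = 1L) {
  query <- as.matrix(query); reference <- as.matrix(reference)
  ref_labels <- as.logical(ref_labels)
  stopifnot(ncol(query) == ncol(reference),
            nrow(reference) == length(ref_labels), k >= 1,
            any(ref_labels), any(!ref_labels))
  d2 <- outer(rowSums(query^2), rep(1, nrow(reference))) +
    outer(rep(1, nrow(query)), rowSums(reference^2)) -
    2 * tcrossprod(query, reference)
  d2 <- pmax(d2, 0)
  pred <- if (k == 1L) {
    ref_labels[max.col(-d2, ties.method = "first")]
  } else {
    apply(d2, 1, function(dr) {
      nb <- ref_labels[order(dr)[seq_len(k)]]
      mean(nb) > 0.5
    })
  }
  d_af <- apply(d2[, ref_labels, drop = FALSE], 1, min)
  d_non <- apply(d2[, !ref_labels, drop = FALSE], 1, min)
  list(pred = pred, score = sqrt(d_non) - sqrt(d_af))
}

#' Supervised classifier head on frozen embeddings
#'
#' Fits a small feed-forward network (single hidden layer, via
#' \code{\link[nnet]{nnet}}) on the frozen latent features using annotated
#' periods; outputs an AF probability with the decision taken at 0.5.
#'
#' @param embeddings Numeric matrix `n x D` of frozen latent features.
#' @param labels Logical AF labels.
#' @param size Hidden units.
#' @param decay Weight decay.
#' @param maxit Maximum optimizer iterations.
#' @param seed Seed for the random weight initialisation.
#' @return An object of class `af_head`.
#' @export
train_classifier_head <- function(embeddings, labels, size = 16L,
                                  decay = 1e-3, maxit = 200L, seed = 1L) {
  embeddings <- as.matrix(embeddings)
  labels <- as.logical(labels)
  stopifnot(nrow(embeddings) == length(labels), !anyNA(labels))
  set.seed(seed)
  fit <- nnet::nnet(x = embeddings, y = as.numeric(labels), size = size,
                    decay = decay, maxit = maxit, entropy = TRUE,
                    trace = FALSE, MaxNWts = 100000L)
  structure(list(fit = fit, d = ncol(embeddings)), class = "af_head")
}

#' @rdname train_classifier_head
#' @param head A trained `af_head`.
#' @param newdata Numeric matrix of embeddings to score.
#' @return `predict_head()`: numeric AF probabilities.
#' @export
predict_head <- function(head, newdata) {
  stopifnot(inherits(head, "af_head"))
  as.numeric(predict(head$fit, as.matrix(newdata)))
}

#' Linear-probe evaluation of an embedding
#'
#' Fits a logistic regression on a random subset of the embeddings and
#' reports held-out accuracy — a standard measure of how linearly separable
#' the classes are in the learned latent space.
#'
#' @param embeddings Numeric matrix `n x D`.
#' @param labels Logical labels.
#' @param train_fraction Fraction used to fit the probe.
#' @return List with `accuracy`, `n_train`, `n_test`.
#' @export
linear_probe <- function(embeddings, labels, train_fraction = 0.7) {
  embeddings <- as.matrix(embeddings)
  labels <- as.logical(labels)
  n <- nrow(embeddings)
  stopifnot(n == length(labels), n >= 10)
  idx <- sample.int(n, floor(train_fraction * n))
  df <- data.frame(y = labels, embeddings)
  fit <- suppressWarnings(glm(y ~ ., data = df[idx, ], family = binomial()))
  prob <- suppressWarnings(predict(fit, df[-idx, ], type = "response"))
  pred <- prob >= 0.5
  list(accuracy = mean(pred == labels[-idx]),
       n_train = length(idx), n_test = n - length(idx))
}
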