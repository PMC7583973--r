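test_that("period encoding is quality-orthogonal, masked and truncated", {
  enc <- encode_period(c(800, 800, 600), quality = c(1L, 2L, 0L), Q = 4, L = 5)
  # beats with equal IBI but different quality occupy orthogonal coordinates
  expect_equal(sum(enc$X[1, ] * enc$X[2, ]), 0)
  expect_equal(enc$n_valid, 2)          # quality-0 beat masked out
  expect_equal(enc$mask, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(enc$X[1, 2], 0.8)        # IBIs stored in seconds

  same_q <- encode_period(rep(700, 4), quality = rep(2L, 4), Q = 4, L = 4)
  expect_true(all(same_q$X[, -3] == 0)) # all vectors in one block

  long <- encode_period(rep(700, 20), quality = rep(3L, 20), Q = 4, L = 8)
  expect_equal(long$n_valid, 8)
  expect_true(all(long$mask))
})

test_that("oversampling balances classes by replication only", {
  y <- rep(c(TRUE, FALSE), c(10, 90))
  withr::with_seed(3, idx <- oversample_balance(y))
  expect_length(idx, 180)
  expect_equal(sum(y[idx]), 90)
  expect_equal(sum(!y[idx]), 90)
  expect_true(all(seq_along(y) %in% idx))          # originals kept
  balanced <- rep(c(TRUE, FALSE), 25)
  expect_equal(oversample_balance(balanced), 1:50)  # no-op when balanced
  i1 <- withr::with_seed(5, oversample_balance(y))
  i2 <- withr::with_seed(5, oversample_balance(y))
  expect_identical(i1, i2)
})

test_that("random splits are disjoint, exhaustive and keep the class ratio", {
  withr::with_seed(4, sp <- random_split(100))
  expect_length(sp$train, 80)
  expect_length(sp$val, 10)
  expect_length(sp$test, 10)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)

  # over many seeds the test-partition class ratio matches the original
  y <- rep(c(TRUE, FALSE), c(30, 70))
  withr::with_seed(6, {
    ratios <- replicate(300, mean(y[random_split(100)$test]))
  })
  expect_equal(mean(ratios), 0.3, tolerance = 0.02)

  # patient-level mode keeps all of a patient's periods together
  pid <- rep(letters[1:10], each = 10)
  withr::with_seed(7, spp <- random_split(100, by_patient = pid))
  for (part in spp) {
    expect_length(intersect(unique(pid[part]),
                            unique(pid[setdiff(1:100, part)])), 0)
  }
})

test_that("InfoNCE loss matches its closed-form limits", {
  z1 <- matrix(rnorm(8), 1, 8)
  expect_equal(mi_contrastive_loss(z1, z1), 0)          # single candidate

  zsame <- matrix(1, 8, 4)                               # identical rows
  expect_equal(mi_contrastive_loss(zsame, zsame), log(8))

  zeye <- diag(6)                                        # matched orthogonal pairs
  expect_lt(mi_contrastive_loss(zeye, zeye, temperature = 0.02), 1e-8)
  l_hot <- mi_contrastive_loss(zeye, zeye, temperature = 1)
  expect_gt(l_hot, 0)
  expect_lt(l_hot, log(6))                               # bounded by log B
})

test_that("encoder training reduces the contrastive loss and is reproducible", {
  withr::with_seed(8, {
    seqs <- c(
      lapply(1:90, function(i) {
        b <- generate_af_ibis(300)
        data.frame(ibi_ms = b$ibi_ms, quality = 3L)
      }),
      lapply(1:90, function(i) {
        b <- generate_sinus_ibis(300)
        data.frame(ibi_ms = b$ibi_ms, quality = 3L)
      })
    )
  })
  cfg <- mi_config(H = 16, D = 16, epochs = 4, batch_size = 32, seed = 2)
  enc <- train_encoder(seqs, cfg)
  lh <- enc$loss_history
  expect_lt(mean(tail(lh, 5)), mean(head(lh, 2)))

  z1 <- embed_periods(enc, seqs[1:10])
  enc2 <- train_encoder(seqs, cfg)
  expect_identical(z1, embed_periods(enc2, seqs[1:10]))
  expect_equal(rowSums(z1^2), rep(1, 10), tolerance = 1e-9)

  # AF and sinus periods become linearly separable in the latent space
  z <- embed_periods(enc, seqs)
  y <- rep(c(TRUE, FALSE), each = 90)
  withr::with_seed(9, pr <- linear_probe(z, y))
  expect_gte(pr$accuracy, 0.9)

  expect_error(train_encoder(list(), cfg), "empty")
})

test_that("1-NN matches brute-force nearest neighbour search", {
  withr::with_seed(10, {
    for (rep in 1:5) {
      d <- 6
      ref <- matrix(rnorm(200 * d), ncol = d)
      y <- runif(200) > 0.5
      q <- matrix(rnorm(50 * d), ncol = d)
      got <- knn_classify(q, ref, y)
      brute <- apply(q, 1, function(v) {
        y[which.min(colSums((t(ref) - v)^2))]
      })
      expect_equal(got$pred, brute)
    }
  })
  # query equal to a reference point takes that reference's label
  ref <- rbind(c(0, 0), c(5, 5))
  got <- knn_classify(rbind(c(5, 5), c(0.4, 0.4)), ref, c(FALSE, TRUE))
  expect_equal(got$pred, c(TRUE, FALSE))
  # margin score is positive for AF-side queries, negative otherwise
  expect_gt(got$score[1], 0)
  expect_lt(got$score[2], 0)
})

test_that("classifier head fits separable embeddings and fails permuted labels", {
  withr::with_seed(11, toy <- toy_embeddings(60, d = 6, sep = 5))
  head_fit <- train_classifier_head(toy$z, toy$y, seed = 1)
  acc <- mean((predict_head(head_fit, toy$z) >= 0.5) == toy$y)
  expect_gte(acc, 0.99)

  # permuted labels: held-out accuracy near the class prior
  withr::with_seed(12, {
    yperm <- sample(toy$y)
    fit2 <- train_classifier_head(toy$z[1:80, ], yperm[1:80], seed = 1)
    acc2 <- mean((predict_head(fit2, toy$z[81:120, ]) >= 0.5) == yperm[81:120])
  })
  expect_lt(acc2, 0.75)

  p1 <- predict_head(train_classifier_head(toy$z, toy$y, seed = 3), toy$z)
  p2 <- predict_head(train_classifier_head(toy$z, toy$y, seed = 3), toy$z)
  expect_identical(p1, p2)
})

test_that("cross-validation partitions the data and reports fold dispersion", {
  withr::with_seed(13, toy <- toy_embeddings(50, d = 4, sep = 6))
  seen <- integer(0)
  all_af <- function(train_x, train_y, test_x) {
    seen <<- c(seen, nrow(test_x))
    list(pred = rep(TRUE, nrow(test_x)), score = NULL)
  }
  withr::with_seed(14, cv <- crossvalidate(toy$z, toy$y, all_af, folds = 10))
  expect_equal(sum(seen), 100)                    # folds partition the data
  expect_true(all(cv$fold_metrics$sensitivity == 1))
  expect_true(all(cv$fold_metrics$specificity == 0))
  expect_equal(unname(cv$sd["sensitivity"]), 0)   # identical folds -> SD 0

  knn_fp <- function(train_x, train_y, test_x) {
    knn_classify(test_x, train_x, train_y)
  }
  withr::with_seed(15, cv2 <- crossvalidate(toy$z, toy$y, knn_fp, folds = 5))
  expect_gte(cv2$mean[["sensitivity"]], 0.95)
  expect_true(all(is.finite(unlist(cv2$sd))))
})
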