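#' Training configuration for the mutual-information encoder
#'
#' Desk-scale defaults for the unsupervised representation learner: a one-layer
#' width-3 temporal convolution over quality-orthogonal beat vectors
#' (`H` filters, ReLU), masked mean pooling, and a linear projection to a
#' `D`-dimensional unit-norm embedding, trained with the InfoNCE bound using
#' cosine similarity at temperature `temperature`. Training is CPU-only and
#' deterministic under `seed`.
#'
#' @param Q Quality buckets (must match the cohort's `q_levels`).
#' @param L Maximum beats per period; longer periods are truncated.
#' @param H Convolution filters.
#' @param D Embedding dimension.
#' @param temperature InfoNCE softmax temperature.
#' @param epochs,batch_size,lr Optimisation schedule (Adam).
#' @param min_half Minimum beats required in each half around the random
#'   split point; shorter periods are skipped for training.
#' @param seed RNG seed covering initialisation, batching and split points.
#' @return A list of class `mi_config`.
#' @export
mi_config <- function(Q = 4L, L = 600L, H = 48L, D = 64L, temperature = 0.1,
                      epochs = 12L, batch_size = 128L, lr = 3e-3,
                      min_half = 10L, seed = 1L) {
  stopifnot(Q >= 2, L >= 2, H >= 1, D >= 1, temperature > 0, epochs >= 1,
            batch_size >= 2, lr > 0, min_half >= 1)
  structure(list(Q = as.integer(Q), L = as.integer(L), H = as.integer(H),
                 D = as.integer(D), temperature = temperature,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 min_half = as.integer(min_half), seed = as.integer(seed)),
            class = "mi_config")
}

#' InfoNCE contrastive bound between paired embeddings
#'
#' For a batch of B embedding pairs (first half, second half of the same
#' five-minute period), computes the InfoNCE loss: the cross-entropy of
#' identifying each row's true partner among the B candidates by cosine
#' similarity scaled by `1/temperature`. Minimising it maximises a lower
#' bound on the mutual information between the two halves. The loss is 0 for
#' a single pair, equals `log(B)` when all similarities coincide, and tends
#' to 0 for perfectly matched, mutually orthogonal pairs at low temperature.
#'
#' @param za,zb Numeric matrices `B x D` of paired embeddings (rows are
#'   cosine-normalized internally).
#' @param temperature Softmax temperature (> 0).
#' @return Scalar loss (>= 0).
#' @export
mi_contrastive_loss <- function(za, zb, temperature = 0.1) {
  za <- as.matrix(za); zb <- as.matrix(zb)
  stopifnot(nrow(za) == nrow(zb), ncol(za) == ncol(zb), temperature > 0)
  za <- za / pmax(sqrt(rowSums(za^2)), 1e-12)
  zb <- zb / pmax(sqrt(rowSums(zb^2)), 1e-12)
  infonce(za, zb, temperature, grad = FALSE)$loss
}

# core InfoNCE on unit-norm rows; optionally returns gradients wrt za/zb
infonce <- function(za, zb, temperature, grad = TRUE) {
  b <- nrow(za)
  s <- tcrossprod(za, zb) / temperature
  mx <- apply(s, 1, max)
  lse <- mx + log(rowSums(exp(s - mx)))
  loss <- mean(lse - diag(s))
  if (!grad) return(list(loss = loss))
  p <- exp(s - lse)                      # row-softmax
  ds <- (p - diag(b)) / b
  list(loss = loss,
       dza = ds %*% zb / temperature,
       dzb = crossprod(ds, za) / temperature)
}

# ---- encoder internals -----------------------------------------------------

init_encoder_params <- function(cfg) {
  q3 <- 3L * cfg$Q
  list(W1 = matrix(rnorm(q3 * cfg$H, 0, sqrt(2 / q3)), q3, cfg$H),
       b1 = numeric(cfg$H),
       W2 = matrix(rnorm(cfg$H * cfg$D, 0, sqrt(1 / cfg$H)), cfg$H, cfg$D),
       b2 = numeric(cfg$D))
}

# concatenate each position with its neighbours (zero-padded) -> n x 3Q
conv_cat <- function(M) {
  n <- nrow(M)
  if (n == 1L) {
    z <- matrix(0, 1L, ncol(M))
    return(cbind(z, M, z))
  }
  cbind(rbind(0, M[-n, , drop = FALSE]), M, rbind(M[-1L, , drop = FALSE], 0))
}

encoder_forward <- function(par, mats, keep_cache = TRUE) {
  n_vec <- vapply(mats, nrow, 0L)
  stopifnot(all(n_vec >= 1L))
  call_ <- do.call(rbind, lapply(mats, conv_cat))
  group <- rep(seq_along(mats), n_vec)
  a <- call_ %*% par$W1
  a <- a + matrix(par$b1, nrow(a), length(par$b1), byrow = TRUE)
  apos <- a > 0
  a[!apos] <- 0
  pool <- rowsum(a, group) / n_vec
  p <- pool %*% par$W2
  p <- p + matrix(par$b2, nrow(p), length(par$b2), byrow = TRUE)
  nrm <- pmax(sqrt(rowSums(p^2)), 1e-8)
  z <- p / nrm
  cache <- if (keep_cache) {
    list(call_ = call_, apos = apos, group = group, n_vec = n_vec,
         pool = pool, z = z, nrm = nrm)
  }
  list(z = z, cache = cache)
}

encoder_backward <- function(par, cache, dz) {
  z <- cache$z
  dp <- (dz - z * rowSums(dz * z)) / cache$nrm
  db2 <- colSums(dp)
  dw2 <- crossprod(cache$pool, dp)
  dpool <- dp %*% t(par$W2)
  dh <- dpool[cache$group, , drop = FALSE] / cache$n_vec[cache$group]
  dh[!cache$apos] <- 0
  list(W1 = crossprod(cache$call_, dh), b1 = colSums(dh),
       W2 = dw2, b2 = db2)
}

adam_step <- function(par, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Train the unsupervised mutual-information encoder
#'
#' Trains the sequence encoder without labels. Each optimisation step draws a
#' batch of periods, samples for each one a split point uniformly over its
#' beats (both halves at least `min_half` beats), embeds the two halves, and
#' minimises the InfoNCE loss of matching first halves to their own second
#' halves within the batch — maximising mutual information between IBI values
#' separated by a random time point inside the five-minute period. The
#' returned encoder is a deterministic inference-mode function of its inputs.
#'
#' @param periods A list of period beat sequences (data.frames with `ibi_ms`
#'   and `quality`, e.g. from [period_sequences()]).
#' @param config An [mi_config()].
#' @return An object of class `mi_encoder` holding the weights, the config
#'   and the per-batch training `loss_history`.
#' @export
train_encoder <- function(periods, config = mi_config()) {
  if (length(periods) == 0) stop("empty training set")
  set.seed(config$seed)
  mats <- lapply(periods, function(p) {
    beat_matrix(p$ibi_ms, p$quality, config$Q, config$L)
  })
  n_valid <- vapply(mats, nrow, 0L)
  mats <- mats[n_valid >= 2L * config$min_half]
  if (length(mats) < config$batch_size) {
    stop("too few periods with at least 2*min_half valid beats")
  }
  par <- init_encoder_params(config)
  zero <- lapply(par, function(x) x * 0)
  state <- list(m = zero, v = zero)
  loss_history <- numeric(0)
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(length(mats))
    n_batches <- floor(length(mats) / config$batch_size)
    for (bi in seq_len(n_batches)) {
      take <- perm[((bi - 1L) * config$batch_size + 1L):(bi * config$batch_size)]
      xa <- xb <- vector("list", length(take))
      for (j in seq_along(take)) {
        M <- mats[[take[j]]]
        n <- nrow(M)
        s <- if (n == 2L * config$min_half) config$min_half else {
          sample(config$min_half:(n - config$min_half), 1L)
        }
        xa[[j]] <- M[seq_len(s), , drop = FALSE]
        xb[[j]] <- M[(s + 1L):n, , drop = FALSE]
      }
      fa <- encoder_forward(par, xa)
      fb <- encoder_forward(par, xb)
      nce <- infonce(fa$z, fb$z, config$temperature)
      ga <- encoder_backward(par, fa$cache, nce$dza)
      gb <- encoder_backward(par, fb$cache, nce$dzb)
      grads <- Map(`+`, ga, gb)
      t_step <- t_step + 1L
      upd <- adam_step(par, grads, state, config$lr, t_step)
      par <- upd$par
      state <- upd$state
      loss_history <- c(loss_history, nce$loss)
    }
  }
  structure(list(W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
                 config = config, loss_history = loss_history),
            class = "mi_encoder")
}

#' @export
print.mi_encoder <- function(x, ...) {
  cat(sprintf(
    "mi_encoder: %d conv filters -> D=%d, %d training batches (final loss %.3f)\n",
    x$config$H, x$config$D, length(x$loss_history),
    tail(x$loss_history, 1)))
  invisible(x)
}

#' Embed five-minute periods with a trained encoder
#'
#' Deterministic inference: encodes each period's full (quality-gated,
#' truncated) beat sequence to a unit-norm latent vector. Periods with no
#' valid beat map to the zero vector.
#'
#' @param encoder A trained [train_encoder()] object.
#' @param periods List of period beat sequences as in [train_encoder()].
#' @param batch_size Forward-pass batch size (memory knob only).
#' @return A numeric matrix `length(periods) x D`.
#' @export
embed_periods <- function(encoder, periods, batch_size = 256L) {
  stopifnot(inherits(encoder, "mi_encoder"))
  cfg <- encoder$config
  par <- encoder[c("W1", "b1", "W2", "b2")]
  mats <- lapply(periods, function(p) {
    beat_matrix(p$ibi_ms, p$quality, cfg$Q, cfg$L)
  })
  out <- matrix(0, length(mats), cfg$D)
  nonempty <- which(vapply(mats, nrow, 0L) > 0L)
  for (chunk in split(nonempty, ceiling(seq_along(nonempty) / batch_size))) {
    fw <- encoder_forward(par, mats[chunk], keep_cache = FALSE)
    out[chunk, ] <- fw$z
  }
  out
}
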