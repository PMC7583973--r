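#' Quality-orthogonal encoding of a five-minute period
#'
#' Encodes a period's beat sequence for the representation learner. Each beat
#' becomes a Q-dimensional vector holding its IBI value (in seconds, fixed
#' global scale — no per-window standardization) in the coordinate block of
#' its quality bucket and zero elsewhere, so beats with different quality
#' scores are exactly orthogonal and noise can be discounted by the encoder.
#' Quality-0 (unusable) beats are masked out entirely; sequences longer than
#' `L` beats are truncated to the first `L`.
#'
#' @param ibi_ms IBI values in ms (or a beats data.frame with `ibi_ms` and
#'   `quality` columns).
#' @param quality Integer quality buckets in `0..Q-1`.
#' @param Q Number of quality buckets.
#' @param L Maximum sequence length.
#' @return An object of class `encoded_period`: list with `X` (an `L x Q`
#'   matrix, padded with zero rows), `mask` (logical length `L`) and
#'   `n_valid`.
#' @export
encode_period <- function(ibi_ms, quality = NULL, Q = 4L, L = 600L) {
  if (is.data.frame(ibi_ms)) {
    quality <- ibi_ms$quality
    ibi_ms <- ibi_ms$ibi_ms
  }
  stopifnot(is.numeric(ibi_ms), length(quality) == length(ibi_ms),
            Q >= 2, L >= 1, all(quality >= 0), all(quality < Q))
  keep <- quality > 0
  x <- ibi_ms[keep] / 1000
  q <- as.integer(quality[keep])
  if (length(x) > L) {
    x <- x[seq_len(L)]
    q <- q[seq_len(L)]
  }
  n <- length(x)
  X <- matrix(0, L, Q)
  if (n > 0) X[cbind(seq_len(n), q + 1L)] <- x
  structure(list(X = X, mask = seq_len(L) <= n, n_valid = n),
            class = "encoded_period")
}

# compact (valid beats only, truncated) matrix used internally by the encoder
beat_matrix <- function(ibi_ms, quality, Q, L) {
  keep <- quality > 0
  x <- ibi_ms[keep] / 1000
  q <- as.integer(quality[keep])
  if (length(x) > L) {
    x <- x[seq_len(L)]
    q <- q[seq_len(L)]
  }
  M <- matrix(0, length(x), Q)
  if (length(x)) M[cbind(seq_along(x), q + 1L)] <- x
  M
}

#' Extract per-period beat sequences from a cohort
#'
#' Pulls, for each row of a period table, the raw `(ibi_ms, quality)`
#' sequence of that five-minute window, in the form consumed by
#' [train_encoder()] and [embed_periods()].
#'
#' @param cohort An `af_cohort`.
#' @param periods A period table (rows referencing `patient_id` and
#'   `window_start_s`).
#' @return A list, parallel to the rows of `periods`, of data.frames with
#'   columns `ibi_ms` and `quality`.
#' @export
period_sequences <- function(cohort, periods) {
  stopifnot(inherits(cohort, "af_cohort"), is.data.frame(periods))
  by_id <- stats::setNames(cohort, vapply(cohort, `[[`, "", "patient_id"))
  out <- vector("list", nrow(periods))
  for (pid in unique(periods$patient_id)) {
    rows <- which(periods$patient_id == pid)
    s <- by_id[[pid]]$samples
    win <- floor(s$t_s / 300)
    for (r in rows) {
      w <- periods$window_start_s[r] / 300
      idx <- which(win == w)
      out[[r]] <- data.frame(ibi_ms = s$ibi_ms[idx], quality = s$quality[idx])
    }
  }
  out
}
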