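#' Apply the wearable quality/dropout model to a beat train
#'
#' Turns an ideal beat train into what the device would deliver: each beat
#' receives a discrete quality bucket in `0..Q-1` (0 = unusable), dropout
#' bursts delete contiguous runs of beats entirely, and physical activity
#' degrades the signal. Three mechanisms act during ACTIVE blocks: the
#' quality-0 probability is multiplied by `active_multiplier`, retained beats
#' are downgraded one bucket with probability
#' `min(0.9, 0.25 * (active_multiplier - 1))`, beats ending up in the
#' lowest retained bucket get a motion-artifact jitter on their detected beat
#' time (which perturbs the two adjacent IBIs consistently, mimicking
#' misplaced pulse-wave detections), and pulses are missed outright with
#' probability `min(0.3, active_miss_coef * (active_multiplier - 1))` — a
#' missed pulse merges its interval into the next detected beat, doubling
#' that IBI and flagging it quality 1. A per-patient log-normal frailty factor
#' scales the quality-0 probability so that interpretable-time fractions are
#' heterogeneous across a cohort.
#'
#' @param beats A data.frame with columns `t_s`, `ibi_ms` (e.g. from
#'   [generate_sinus_ibis()]).
#' @param profile Activity profile from [generate_activity_profile()].
#' @param params Quality parameters from [quality_params()].
#' @param frailty Optional fixed frailty multiplier; drawn from
#'   `rlnorm(1, 0, params$frailty_sdlog)` when `NULL`.
#'
#' @return A data.frame (`t_s`, `ibi_ms`, `quality`, `activity`) with
#'   `activity` a factor in `RESTING`/`ACTIVE` and the attribute `"frailty"`.
#' @export
apply_quality_model <- function(beats, profile, params = quality_params(),
                                frailty = NULL) {
  stopifnot(is.data.frame(beats), all(c("t_s", "ibi_ms") %in% names(beats)),
            is.data.frame(profile))
  if (is.null(frailty)) frailty <- rlnorm(1, 0, params$frailty_sdlog)
  stopifnot(frailty > 0)
  n <- nrow(beats)
  qmax <- params$q_levels - 1L
  if (n == 0) {
    out <- data.frame(t_s = numeric(0), ibi_ms = numeric(0),
                      quality = integer(0),
                      activity = factor(character(0), levels = ACTIVITY_LEVELS))
    attr(out, "frailty") <- frailty
    return(out)
  }

  block <- pmin(findInterval(beats$t_s, profile$block_start_s), nrow(profile))
  block[block < 1L] <- 1L
  active <- profile$active[block]

  p0 <- pmin(1, params$base_q0_prob * frailty *
               ifelse(active, params$active_multiplier, 1))
  bad <- runif(n) < p0
  quality <- integer(n)
  n_good <- sum(!bad)
  if (n_good > 0) {
    quality[!bad] <- sample.int(qmax, n_good, replace = TRUE,
                                prob = params$good_quality_probs)
  }

  # activity-driven quality downgrade (never below bucket 1 for retained beats)
  down_p <- min(0.9, 0.25 * (params$active_multiplier - 1))
  down <- active & !bad & quality > 1L & runif(n) < down_p
  quality[down] <- quality[down] - 1L

  t_s <- beats$t_s
  ibi <- beats$ibi_ms
  # isolated motion artifact: jitter on the detected beat time of low-quality
  # active beats, perturbing the two adjacent IBIs consistently
  if (params$artifact_sd_ms > 0) {
    aff <- which(active & quality == 1L & seq_len(n) > 1L & seq_len(n) < n)
    if (length(aff)) {
      delta <- rnorm(length(aff), 0, params$artifact_sd_ms)
      nb <- pmin(ibi[aff], ibi[aff + 1L])
      delta <- pmin(pmax(delta, -0.3 * nb), 0.3 * nb)
      d_full <- numeric(n)
      d_full[aff] <- delta
      t_s <- t_s + d_full / 1000
      ibi <- ibi + d_full - c(0, d_full[-n])
    }
  }

  # tracker-lock episodes: in an occasional active five-minute block the
  # pulse tracker loses the pulse wave and coasts, emitting near-regular
  # intervals regardless of the true rhythm for most of the block. Locked
  # runs are re-timed onto an even grid between their anchor beats and
  # flagged quality 1; clean gaps between runs keep a minority of honestly
  # detected beats.
  locked <- rep(FALSE, n)
  if (params$lock_block_prob > 0 && any(active)) {
    blocks <- unique(block[active])
    locked_blocks <- blocks[runif(length(blocks)) < params$lock_block_prob]
    changed <- rep(FALSE, n)
    for (bk in locked_blocks) {
      rows <- which(block == bk & active)
      if (length(rows) < 6L) next
      i <- rows[1L]
      last <- rows[length(rows)]
      repeat {
        run_len <- 1L + stats::rgeom(1L, 1 / params$lock_run_beats)
        i0 <- max(2L, i)
        i1 <- min(n - 1L, last, i + run_len - 1L)
        if (i1 >= i0 + 1L) {
          a <- t_s[i0 - 1L]; b <- t_s[i1 + 1L]
          m <- i1 - i0 + 1L
          step <- (b - a) / (m + 1L)
          jit <- rnorm(m, 0, min(params$artifact_sd_ms / 1000, 0.2 * step))
          jit <- pmin(pmax(jit, -0.3 * step), 0.3 * step)
          t_s[i0:i1] <- a + step * seq_len(m) + jit
          quality[i0:i1][quality[i0:i1] > 1L] <- 1L
          locked[i0:i1] <- TRUE
          changed[i0:(min(n, i1 + 1L))] <- TRUE
        }
        gap_len <- 1L + stats::rgeom(1L, 1 / params$lock_gap_beats)
        i <- i1 + 1L + gap_len
        if (i > last) break
      }
    }
    ch <- which(changed & seq_len(n) > 1L)
    ibi[ch] <- (t_s[ch] - t_s[ch - 1L]) * 1000
  }

  # missed pulse-wave detections: the missed beat's interval is absorbed by
  # the next detected beat (IBI doubles); the absorbing beat is low quality.
  # Tracker-locked stretches are exempt: there the tracker emits its own
  # regular beat train rather than skipping pulses.
  miss_p <- min(0.3, params$active_miss_coef * (params$active_multiplier - 1))
  if (miss_p > 0) {
    miss <- active & !locked & quality > 0L & runif(n) < miss_p
    miss[n] <- FALSE
    if (any(miss)) {
      ind <- seq_len(n)
      tmp <- ind
      tmp[miss] <- n + 1L  # sentinel; suffix-min gives the next kept beat
      nxt <- rev(cummin(rev(tmp)))
      merged <- as.vector(rowsum(ibi, nxt))
      keep <- !miss
      absorbed <- tabulate(nxt, nbins = n)[keep] > 1L
      t_s <- t_s[keep]; quality <- quality[keep]; active <- active[keep]
      ibi <- merged
      quality[absorbed & quality > 1L] <- 1L
      n <- length(t_s)
    }
  }

  # dropout bursts delete contiguous runs of beats
  duration_s <- max(t_s)
  if (params$dropout_rate_per_h > 0) {
    n_bursts <- rpois(1, params$dropout_rate_per_h * duration_s / 3600)
    if (n_bursts > 0) {
      b_start <- runif(n_bursts, 0, duration_s)
      b_len <- rexp(n_bursts, 1 / params$dropout_mean_s)
      drop <- rep(FALSE, n)
      for (k in seq_len(n_bursts)) {
        drop <- drop | (t_s >= b_start[k] & t_s < b_start[k] + b_len[k])
      }
      keep <- !drop
      t_s <- t_s[keep]; ibi <- ibi[keep]
      quality <- quality[keep]; active <- active[keep]
    }
  }

  out <- data.frame(
    t_s = t_s, ibi_ms = ibi, quality = quality,
    activity = factor(ifelse(active, "ACTIVE", "RESTING"),
                      levels = ACTIVITY_LEVELS)
  )
  attr(out, "frailty") <- frailty
  out
}
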