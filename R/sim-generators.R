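#' Generate sinus-rhythm inter-beat intervals
#'
#' Simulates a sinus-rhythm beat train as a mean RR interval modulated by a
#' slow sinusoid plus white Gaussian jitter:
#' `IBI_i = meanRR + A * sin(2 * pi * f * t_i) + eps_i`, where `t_i` is the
#' time of the preceding pulse. The sinusoid stands for the autonomic RR
#' modulation (respiratory sinus arrhythmia and baroreflex/Mayer waves);
#' because successive beats sample it at nearby phases, the series has
#' positive lag-1 autocorrelation and a tight Poincare cluster, in contrast
#' to the diffuse AF cloud.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param mean_rr_ms Mean RR interval in ms, must lie in `[400, 1500]`.
#' @param rsa_amp_ms Modulation amplitude in ms.
#' @param rsa_freq_hz Modulation frequency in Hz (default 0.1).
#' @param jitter_sd_ms SD of the white jitter in ms.
#'
#' @return A data.frame with columns `t_s` (beat time, seconds from recording
#'   start, each beat being the endpoint of its interval) and `ibi_ms`.
#' @examples
#' beats <- generate_sinus_ibis(300, mean_rr_ms = 1000, rsa_amp_ms = 0,
#'                              jitter_sd_ms = 0)
#' nrow(beats)  # exactly 300 beats of 1000 ms
#' @export
generate_sinus_ibis <- function(duration_s, mean_rr_ms = 850, rsa_amp_ms = 30,
                                rsa_freq_hz = 0.1, jitter_sd_ms = 10) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (mean_rr_ms < 400 || mean_rr_ms > 1500) {
    stop("mean_rr_ms must lie in [400, 1500] ms")
  }
  stopifnot(rsa_amp_ms >= 0, rsa_freq_hz > 0, jitter_sd_ms >= 0)
  m <- .sinus_ibi_cpp(duration_s, mean_rr_ms, rsa_amp_ms, rsa_freq_hz,
                      jitter_sd_ms)
  data.frame(t_s = m[, "t_s"], ibi_ms = m[, "ibi_ms"])
}

#' Generate atrial-fibrillation inter-beat intervals
#'
#' Simulates AF as an i.i.d. gamma renewal process: IBIs are drawn
#' independently from a gamma distribution with the requested mean and
#' coefficient of variation (CV), reproducing the "irregularly irregular"
#' ventricular response -- a diffuse Poincare cloud with lag-1 serial
#' correlation near zero. `cv = 0` degenerates to a constant beat train.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param mean_rr_ms Mean RR interval in ms.
#' @param cv Coefficient of variation of the IBIs; must be >= 0 (default 0.22).
#'
#' @return A data.frame with columns `t_s` and `ibi_ms` as in
#'   [generate_sinus_ibis()].
#' @export
generate_af_ibis <- function(duration_s, mean_rr_ms = 700, cv = 0.22) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (mean_rr_ms <= 0) stop("mean_rr_ms must be positive")
  if (cv < 0) stop("cv must be >= 0")
  draw <- function(n) {
    if (cv == 0) rep(mean_rr_ms, n)
    else {
      shape <- 1 / cv^2
      pmax(rgamma(n, shape = shape, rate = shape / mean_rr_ms), 150)
    }
  }
  ibi <- draw(ceiling(duration_s * 1000 / mean_rr_ms * 1.1) + 32L)
  t <- cumsum(ibi) / 1000
  while (t[length(t)] <= duration_s) {
    extra <- draw(256L)
    ibi <- c(ibi, extra)
    t <- c(t, t[length(t)] + cumsum(extra) / 1000)
  }
  keep <- t <= duration_s + 1e-9
  data.frame(t_s = t[keep], ibi_ms = ibi[keep])
}

#' Generate atrial-flutter inter-beat intervals
#'
#' Simulates atrial flutter as a fixed atrial cycle conducted at an integer
#' ratio (e.g. 2:1, 3:1): `IBI = ratio * cycle + jitter`. The conduction ratio
#' switches at Poisson-distributed event times; every switch changes the ratio
#' to a different member of `ratios` (when more than one is available). Within
#' a fixed-ratio stretch the rhythm is regular and fast, so its nRMSSD falls
#' below sinus rhythm's.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param atrial_cycle_ms Atrial cycle length in ms.
#' @param ratios Non-empty set of integer conduction ratios.
#' @param switch_rate_per_h Poisson rate of ratio switches per hour.
#' @param jitter_sd_ms SD of the per-beat jitter in ms.
#'
#' @return A data.frame with columns `t_s` and `ibi_ms`; the attribute
#'   `"ratio_segments"` holds a data.frame (`start_s`, `end_s`, `ratio`) of
#'   the conduction-ratio episodes actually used.
#' @export
generate_flutter_ibis <- function(duration_s, atrial_cycle_ms = 250,
                                  ratios = c(2L, 3L, 4L), switch_rate_per_h = 6,
                                  jitter_sd_ms = 5) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (length(ratios) == 0) stop("ratios must be a non-empty set")
  stopifnot(atrial_cycle_ms > 0, switch_rate_per_h >= 0, jitter_sd_ms >= 0)

  # switch event times (Poisson process over the recording)
  switches <- numeric(0)
  if (switch_rate_per_h > 0) {
    t <- 0
    rate_s <- switch_rate_per_h / 3600
    repeat {
      t <- t + rexp(1, rate_s)
      if (t >= duration_s) break
      switches <- c(switches, t)
    }
  }
  bounds <- c(0, switches, duration_s)
  ratio <- ratios[[if (length(ratios) == 1L) 1L else sample.int(length(ratios), 1L)]]

  t_cur <- 0
  t_all <- ibi_all <- vector("list", length(bounds) - 1L)
  seg_ratio <- integer(length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    seg_ratio[k] <- ratio
    end <- bounds[k + 1L]
    mean_ibi <- ratio * atrial_cycle_ms
    n_est <- ceiling((end - t_cur) * 1000 / mean_ibi) + 8L
    ibi <- pmax(mean_ibi + rnorm(n_est, 0, jitter_sd_ms), 150)
    tt <- t_cur + cumsum(ibi) / 1000
    keep <- tt <= end + 1e-9
    tt <- tt[keep]; ibi <- ibi[keep]
    t_all[[k]] <- tt; ibi_all[[k]] <- ibi
    if (length(tt)) t_cur <- tt[length(tt)]
    if (length(ratios) > 1L) {
      others <- ratios[ratios != ratio]
      ratio <- others[[if (length(others) == 1L) 1L else sample.int(length(others), 1L)]]
    }
  }
  out <- data.frame(t_s = unlist(t_all), ibi_ms = unlist(ibi_all))
  out <- out[out$t_s <= duration_s + 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ratio_segments") <- data.frame(
    start_s = bounds[-length(bounds)], end_s = bounds[-1L], ratio = seg_ratio
  )
  out
}

#' Generate a ground-truth rhythm timeline
#'
#' Builds the gold-standard rhythm segmentation of a recording. Sinus-only
#' patients get a single SINUS segment and persistent-AF patients a single AF
#' segment. Paroxysmal-AF patients alternate sinus and AF bouts with
#' exponential durations (at least one AF bout is guaranteed); flutter
#' patients alternate sinus and flutter episodes in the same way. The initial
#' state is drawn with probability proportional to its mean bout length
#' (the stationary renewal start).
#'
#' @param duration_s Recording length in seconds.
#' @param patient_kind One of `"sinus"`, `"af_persistent"`, `"af_paroxysmal"`,
#'   `"flutter"`.
#' @param bouts Bout-length parameters from [bout_params()].
#'
#' @return A data.frame (`start_s`, `end_s`, `rhythm`) whose segments are
#'   non-overlapping, sorted and contiguous from 0 to `duration_s`.
#' @export
generate_rhythm_timeline <- function(duration_s,
                                     patient_kind = c("sinus", "af_persistent",
                                                      "af_paroxysmal", "flutter"),
                                     bouts = bout_params()) {
  stopifnot(duration_s > 0)
  patient_kind <- match.arg(patient_kind)
  one <- function(rhythm) data.frame(start_s = 0, end_s = duration_s,
                                     rhythm = rhythm)
  if (patient_kind == "sinus") return(one("SINUS"))
  if (patient_kind == "af_persistent") return(one("AF"))

  episodic <- if (patient_kind == "af_paroxysmal") "AF" else "FLUTTER"
  mean_ep_s <- 60 * if (patient_kind == "af_paroxysmal") {
    bouts$af_bout_mean_min
  } else {
    bouts$flutter_bout_mean_min
  }
  mean_sinus_s <- 60 * bouts$sinus_bout_mean_min

  build <- function(start_state) {
    state <- start_state
    t <- 0
    seg <- list()
    while (t < duration_s) {
      len <- rexp(1, 1 / if (state == episodic) mean_ep_s else mean_sinus_s)
      end <- min(t + len, duration_s)
      seg[[length(seg) + 1L]] <- data.frame(start_s = t, end_s = end,
                                            rhythm = state)
      t <- end
      state <- if (state == episodic) "SINUS" else episodic
    }
    do.call(rbind, seg)
  }
  start_state <- if (runif(1) < mean_ep_s / (mean_ep_s + mean_sinus_s)) {
    episodic
  } else {
    "SINUS"
  }
  tl <- build(start_state)
  if (!any(tl$rhythm == episodic)) tl <- build(episodic)
  rownames(tl) <- NULL
  tl
}

#' Generate a diurnal activity profile on five-minute blocks
#'
#' Assigns each five-minute block of the recording an ACTIVE/RESTING state.
#' The per-block activity probability follows a two-peak diurnal intensity
#' (an after-breakfast peak and an afternoon peak, hours measured from
#' recording start) scaled so that the marginal expected ACTIVE fraction
#' equals `params$active_fraction`.
#'
#' @param duration_s Recording length in seconds.
#' @param params Activity parameters from [activity_params()].
#'
#' @return A data.frame (`block_start_s`, `active`) with one row per
#'   five-minute block (block starts are multiples of 300 s; a trailing
#'   partial block is included so every beat has an activity state).
#' @export
generate_activity_profile <- function(duration_s, params = activity_params()) {
  stopifnot(duration_s > 0)
  n_blocks <- ceiling(duration_s / 300)
  block_start <- (seq_len(n_blocks) - 1) * 300
  if (params$active_fraction == 0) {
    return(data.frame(block_start_s = block_start, active = FALSE))
  }
  h <- (block_start + 150) / 3600
  g <- rep(1, n_blocks)
  for (k in seq_along(params$peak_offset_h)) {
    g <- g + params$peak_weight[k] *
      exp(-(h - params$peak_offset_h[k])^2 / (2 * params$peak_sd_h[k]^2))
  }
  p <- pmin(1, params$active_fraction * g / mean(g))
  data.frame(block_start_s = block_start, active = runif(n_blocks) < p)
}
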